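#' Paired competition / no-competition simulation for one posterior draw
#'
#' Runs the season twice with identical inputs except the competition
#' coefficient, which is set to the draw's value in the first run and to 0 in
#' the second (the counterfactual of independent populations). By the model's
#' asymmetry the albopictus components of the two runs are identical.
#'
#' @param dataset a [site_year_dataset()].
#' @param theta named parameter vector (a competition-model posterior draw).
#' @param species_params,init,forcing passed to [simulate_season()].
#' @return list with `competition` and `independent` trajectories.
#' @export
counterfactual_pair <- function(dataset, theta,
                                species_params = default_species_params(),
                                init = initial_state(), forcing = NULL) {
  if (is.null(forcing)) forcing <- build_forcing(dataset, species_params)
  theta0 <- theta
  theta0[["c"]] <- 0
  list(
    competition = simulate_season(dataset, theta, species_params,
                                  init = init, forcing = forcing),
    independent = simulate_season(dataset, theta0, species_params,
                                  init = init, forcing = forcing)
  )
}

#' Relative reduction of Cx. pipiens abundance due to competition
#'
#' `(mean A_indep - mean A_comp) / mean A_indep`, where the means are the
#' average daily pipiens adult females over the evaluation window (default:
#' the trapping window, first to last session date; optionally the full
#' simulated season). Returns `NA` when the independent-model mean is zero.
#'
#' @param traj_comp,traj_indep trajectories on the same date grid.
#' @param window `"trapping"` (default) or `"season"`.
#' @param dataset required for `window = "trapping"`.
#' @return fraction (1 = complete suppression; negative would mean increase).
#' @export
relative_reduction <- function(traj_comp, traj_indep, dataset = NULL,
                               window = c("trapping", "season")) {
  window <- match.arg(window)
  if (length(traj_comp$dates) != length(traj_indep$dates) ||
      any(traj_comp$dates != traj_indep$dates)) {
    stop("trajectories are on different date grids")
  }
  keep <- rep(TRUE, length(traj_comp$dates))
  if (window == "trapping") {
    if (is.null(dataset)) stop("dataset needed for the trapping window")
    keep <- traj_comp$dates >= min(dataset$sessions$date) &
      traj_comp$dates <= max(dataset$sessions$date)
  }
  mi <- mean(traj_indep$states[keep, "pip_A"])
  mc <- mean(traj_comp$states[keep, "pip_A"])
  if (mi == 0) return(NA_real_)
  (mi - mc) / mi
}

#' Onset date of competition effects
#'
#' The first date at which the relative difference between the pipiens adult
#' females predicted without and with competition exceeds the threshold
#' (default 10%): smallest `d` with `A_indep(d) > 0` and
#' `(A_indep(d) - A_comp(d)) / A_indep(d) > threshold`. `NA` if never.
#'
#' @param traj_comp,traj_indep trajectories on the same date grid.
#' @param threshold relative-difference threshold, default 0.10.
#' @return a `Date`, or `NA` if the threshold is never exceeded.
#' @export
onset_date <- function(traj_comp, traj_indep, threshold = 0.10) {
  if (length(traj_comp$dates) != length(traj_indep$dates) ||
      any(traj_comp$dates != traj_indep$dates)) {
    stop("trajectories are on different date grids")
  }
  ai <- traj_indep$states[, "pip_A"]
  ac <- traj_comp$states[, "pip_A"]
  hit <- ai > 0 & (ai - ac) / ai > threshold
  if (!any(hit)) return(as.Date(NA))
  traj_comp$dates[which(hit)[1]]
}

#' Posterior summary of competition effects for one site-year
#'
#' For a thinned set of competition-model posterior draws, simulates the
#' counterfactual pair, computes the relative reduction and onset date per
#' draw, and summarises: median and 2.5/97.5% quantiles of the reduction, and
#' the median onset date over draws where an onset occurs.
#'
#' @param dataset a [site_year_dataset()].
#' @param chain competition-model `mcmc_chain`.
#' @param n_draws number of thinned posterior draws, default 100.
#' @param species_params,init model constants.
#' @param onset_threshold see [onset_date()].
#' @return list of class `effect_result`.
#' @export
competition_effects <- function(dataset, chain, n_draws = 100,
                                species_params = default_species_params(),
                                init = initial_state(),
                                onset_threshold = 0.10) {
  post <- posterior_samples(chain)
  idx <- unique(round(seq(1, nrow(post), length.out = n_draws)))
  forcing <- build_forcing(dataset, species_params)
  red <- numeric(length(idx))
  onset <- rep(as.Date(NA), length(idx))
  for (j in seq_along(idx)) {
    theta <- post[idx[j], ]
    pair <- counterfactual_pair(dataset, theta, species_params,
                                init = init, forcing = forcing)
    red[j] <- relative_reduction(pair$competition, pair$independent,
                                 dataset = dataset)
    onset[j] <- onset_date(pair$competition, pair$independent,
                           threshold = onset_threshold)
  }
  q <- stats::quantile(red, probs = c(0.025, 0.5, 0.975), na.rm = TRUE)
  has_onset <- !is.na(onset)
  structure(
    list(
      site = dataset$site_id, year = dataset$year,
      reduction = red, onset = onset,
      reduction_median = unname(q[2]),
      reduction_q2.5 = unname(q[1]), reduction_q97.5 = unname(q[3]),
      onset_median = if (any(has_onset)) {
        stats::median(onset[has_onset])
      } else {
        as.Date(NA)
      },
      onset_threshold = onset_threshold, n_draws = length(idx)
    ),
    class = "effect_result"
  )
}

#' @export
print.effect_result <- function(x, ...) {
  cat(sprintf(
    "<effect_result> site %s year %d: reduction median %.1f%% (95%%: %.1f-%.1f%%), onset %s\n",
    x$site, x$year, 100 * x$reduction_median, 100 * x$reduction_q2.5,
    100 * x$reduction_q97.5, as.character(x$onset_median)
  ))
  invisible(x)
}
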