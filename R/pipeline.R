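#' Fit both models (competition and independent) to one site-year
#'
#' Runs two random-walk Metropolis-Hastings calibrations against the same
#' capture data: the full model with five free parameters and the simplified
#' independent-population model with the competition coefficient fixed to
#' zero (four free parameters). Computes DIC and AIC for both and classifies
#' the site-year by the DIC rule.
#'
#' @param dataset a [site_year_dataset()].
#' @param iterations,burnin chain settings (shared by both fits).
#' @param seed integer seed; the independent-model chain uses `seed + 1`.
#' @param priors prior bounds for the competition model (the independent
#'   model drops the `c` row).
#' @param threshold DIC classification threshold, default 4.
#' @param species_params,init model constants.
#' @return list of class `site_fit`: `chain_comp`, `chain_indep`,
#'   `selection` (a `selection_result`), `loglik_fn`, `site`, `year`,
#'   `seed`.
#' @export
fit_site_year <- function(dataset, iterations = 20000, burnin = 5000,
                          seed = 1, priors = default_priors(),
                          threshold = 4,
                          species_params = default_species_params(),
                          init = initial_state()) {
  loglik_fn <- make_loglik(dataset, species_params, init)
  priors_indep <- priors[priors$name != "c", ]

  chain_comp <- metropolis_hastings(loglik_fn, priors,
                                    iterations = iterations, burnin = burnin,
                                    seed = seed)
  chain_indep <- metropolis_hastings(loglik_fn, priors_indep,
                                     iterations = iterations, burnin = burnin,
                                     seed = seed + 1L)
  dic_c <- compute_dic(chain_comp, loglik_fn)
  dic_i <- compute_dic(chain_indep, loglik_fn)
  keep <- (burnin + 1):iterations
  aic_c <- compute_aic(max(chain_comp$loglik[keep]), nrow(priors))
  aic_i <- compute_aic(max(chain_indep$loglik[keep]), nrow(priors_indep))
  structure(
    list(
      chain_comp = chain_comp, chain_indep = chain_indep,
      selection = classify_site(dic_c$dic, dic_i$dic, aic_c, aic_i,
                                threshold = threshold),
      loglik_fn = loglik_fn,
      site = dataset$site_id, year = dataset$year, seed = seed
    ),
    class = "site_fit"
  )
}

#' @export
print.site_fit <- function(x, ...) {
  cat(sprintf("<site_fit> site %s year %d: ", x$site, x$year))
  print(x$selection)
  invisible(x)
}

#' Analyse a full study: fit, classify, delays and competition effects
#'
#' Per site-year: both model fits and the DIC classification; the
#' interspecific delay; and, for site-years classified as competition, the
#' posterior competition-effect summary. Site-years whose fit fails are
#' recorded with the error message and excluded from tables. Seeds are
#' derived per site from the master seed, so results are independent of
#' processing order.
#'
#' @param datasets list of [site_year_dataset()] objects.
#' @param iterations,burnin chain settings per fit.
#' @param seed master seed.
#' @param n_effect_draws posterior draws per effect summary.
#' @param threshold DIC threshold.
#' @param priors,species_params,init passed to [fit_site_year()].
#' @return list of class `study_analysis`: `fits`, `selection_table`
#'   (data.frame), `delays`, `effects`, `failures`.
#' @export
analyze_study <- function(datasets, iterations = 20000, burnin = 5000,
                          seed = 1, n_effect_draws = 100, threshold = 4,
                          priors = default_priors(),
                          species_params = default_species_params(),
                          init = initial_state()) {
  fits <- list()
  effects <- list()
  failures <- list()
  rows <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    key <- paste(d$site_id, d$year, sep = "_")
    site_seed <- (seed + 104729L * i) %% 2147483647L
    fit <- tryCatch(
      fit_site_year(d, iterations = iterations, burnin = burnin,
                    seed = site_seed, priors = priors, threshold = threshold,
                    species_params = species_params, init = init),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures[[key]] <- conditionMessage(fit)
      next
    }
    fits[[key]] <- fit
    sel <- fit$selection
    rows[[key]] <- data.frame(
      site = d$site_id, year = d$year,
      dic_comp = sel$dic_competition, dic_indep = sel$dic_independent,
      delta_dic = sel$delta_dic,
      aic_comp = sel$aic_competition, aic_indep = sel$aic_independent,
      classification = sel$classification
    )
    if (sel$classification == "competition") {
      effects[[key]] <- competition_effects(
        d, fit$chain_comp, n_draws = n_effect_draws,
        species_params = species_params, init = init
      )
    }
  }
  analyzed <- datasets[!paste(
    vapply(datasets, `[[`, "", "site_id"),
    vapply(datasets, `[[`, 0L, "year"), sep = "_"
  ) %in% names(failures)]
  structure(
    list(
      fits = fits,
      selection_table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      delays = study_delays(analyzed),
      effects = effects,
      failures = failures
    ),
    class = "study_analysis"
  )
}

#' Assemble the study report: classification counts, delays and effects
#'
#' Produces the classification table (counts and row percentages by year and
#' overall), delay summaries by year and by selected model, competition-effect
#' summaries, and the mean captures per session by classification and year.
#'
#' @param analysis a `study_analysis` (or compatible list with
#'   `selection_table`, `delays`, `effects`).
#' @param datasets the analysed datasets (needed for the captures-per-session
#'   table; optional).
#' @return list of class `study_report`.
#' @export
build_report <- function(analysis, datasets = NULL) {
  st <- analysis$selection_table
  if (is.null(st) || nrow(st) == 0) stop("no fitted site-years to report")
  tab_row <- function(rows, label) {
    n <- nrow(rows)
    nc <- sum(rows$classification == "competition")
    data.frame(
      group = label, n = n,
      competition = nc, competition_pct = 100 * nc / n,
      independent = n - nc, independent_pct = 100 * (n - nc) / n
    )
  }
  years <- sort(unique(st$year))
  classification_table <- do.call(rbind, c(
    list(tab_row(st, "All years")),
    lapply(years, function(y) tab_row(st[st$year == y, ], as.character(y)))
  ))

  delays <- merge(analysis$delays, st[c("site", "year", "classification")],
                  by = c("site", "year"), all.x = TRUE)
  delay_by_year <- delay_summary(delays, group = "year")
  delay_by_class <- if (length(unique(stats::na.omit(delays$classification))) >= 1) {
    delay_summary(delays[!is.na(delays$classification), ],
                  group = "classification")
  } else {
    NULL
  }

  effect_table <- if (length(analysis$effects) > 0) {
    do.call(rbind, lapply(analysis$effects, function(e) {
      data.frame(
        site = e$site, year = e$year,
        reduction_median = e$reduction_median,
        reduction_q2.5 = e$reduction_q2.5,
        reduction_q97.5 = e$reduction_q97.5,
        onset_date = as.character(e$onset_median)
      )
    }))
  } else {
    NULL
  }

  captures_table <- NULL
  if (!is.null(datasets)) {
    caps <- do.call(rbind, lapply(datasets, function(d) {
      data.frame(site = d$site_id, year = d$year,
                 species = d$sessions$species, count = d$sessions$count)
    }))
    caps <- merge(caps, st[c("site", "year", "classification")],
                  by = c("site", "year"))
    captures_table <- stats::aggregate(
      count ~ species + year + classification, data = caps, FUN = mean
    )
    names(captures_table)[names(captures_table) == "count"] <-
      "mean_count_per_session"
  }

  structure(
    list(
      classification_table = classification_table,
      delay_by_year = delay_by_year,
      delay_by_classification = delay_by_class,
      effect_table = effect_table,
      captures_table = captures_table,
      n_failures = length(analysis$failures)
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n============\n\nClassification (DIC rule):\n")
  print(x$classification_table, row.names = FALSE)
  cat("\nInterspecific delay by year (days):\n")
  print(x$delay_by_year$summary, row.names = FALSE)
  if (!is.null(x$delay_by_classification)) {
    cat("\nInterspecific delay by selected model (days):\n")
    print(x$delay_by_classification$summary, row.names = FALSE)
  }
  if (!is.null(x$effect_table)) {
    cat("\nCompetition effects (competition-classified sites):\n")
    print(x$effect_table, row.names = FALSE)
  }
  invisible(x)
}

#' Descriptive summary statistics of a capture study
#'
#' Species totals, the share of each species' captures by year, interspecific
#' delay means overall and per year, and the Welch two-sample t-test between
#' the first two years' delays. These are the descriptive statistics a
#' two-year, two-species trap study is usually summarised by, computed from
#' the capture tables alone (no model fitting).
#'
#' @param datasets list of [site_year_dataset()] objects.
#' @return list with `totals`, `share_by_year` (fraction of a species' total
#'   caught in each year), `delay_mean_days` (overall and per year) and
#'   `welch` (the `htest`, or `NULL`).
#' @export
study_summary_statistics <- function(datasets) {
  caps <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(year = d$year, species = d$sessions$species,
               count = d$sessions$count)
  }))
  totals <- tapply(caps$count, caps$species, sum)
  by_year <- tapply(caps$count, list(caps$species, caps$year), sum)
  by_year[is.na(by_year)] <- 0
  share <- sweep(by_year, 1, rowSums(by_year), "/")
  delays <- study_delays(datasets)
  ds <- delay_summary(delays, group = "year")
  means <- stats::setNames(ds$summary$mean, ds$summary$group)
  list(
    totals = totals,
    share_by_year = share,
    delay_mean_days = means,
    welch = ds$test
  )
}
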