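#' Raw cross-correlation of two weekly series at a given lag
#'
#' The unnormalised, uncentred cross-correlation
#' `rho_XY(tau) = sum_{t=1..m} X[t] * Y[t + tau]`, with `Y` taken as zero
#' outside its observed window. If the two series differ in length the shorter
#' is zero-padded at the end. Mean-centred variants are available via
#' `center = TRUE` for sensitivity checks only; the delay statistic uses the
#' raw form.
#'
#' @param X,Y `weekly_series` objects on the same weekly grid, or plain
#'   numeric vectors.
#' @param tau integer lag with `abs(tau) < m`.
#' @param center subtract each series' mean first (default FALSE).
#' @return scalar cross-correlation value.
#' @export
cross_correlation <- function(X, Y, tau, center = FALSE) {
  x <- if (inherits(X, "weekly_series")) X$values else as.numeric(X)
  y <- if (inherits(Y, "weekly_series")) Y$values else as.numeric(Y)
  m <- max(length(x), length(y))
  x <- c(x, rep(0, m - length(x)))
  y <- c(y, rep(0, m - length(y)))
  if (abs(tau) >= m) stop("lag |tau| must be smaller than the series length")
  if (center) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  t <- seq_len(m)
  ty <- t + tau
  ok <- ty >= 1 & ty <= m
  sum(x[ok] * y[ty[ok]])
}

#' Interspecific delay between weekly capture series
#'
#' The delay `T` is the integer week lag that maximises the raw
#' cross-correlation between the *Cx. pipiens* series `X` and the
#' *Ae. albopictus* series `Y`, searched over `tau` in
#' `[-(m - 1), m - 1]`. Positive `T` means the albopictus pattern trails the
#' pipiens pattern. Ties are broken toward the smallest `|tau|`, then toward
#' the positive lag (the documented biological orientation). If both series
#' are all-zero the delay is undefined and `NA` is returned (such site-years
#' are excluded from summaries).
#'
#' When the two `weekly_series` start in different ISO weeks they are aligned
#' on a common calendar grid (zero-padded) before the search.
#'
#' @param X pipiens `weekly_series` (or numeric vector).
#' @param Y albopictus `weekly_series` (or numeric vector).
#' @param center see [cross_correlation()].
#' @return list of class `delay_result`: `T_weeks`, `T_days = 7 * T_weeks`,
#'   `rho_max`, `m`.
#' @export
interspecific_delay <- function(X, Y, center = FALSE) {
  if (inherits(X, "weekly_series") && inherits(Y, "weekly_series")) {
    shift <- as.integer(round(as.numeric(Y$start - X$start) / 7))
    x <- X$values
    y <- Y$values
    if (shift > 0) y <- c(rep(0, shift), y)
    if (shift < 0) x <- c(rep(0, -shift), x)
  } else {
    x <- if (inherits(X, "weekly_series")) X$values else as.numeric(X)
    y <- if (inherits(Y, "weekly_series")) Y$values else as.numeric(Y)
  }
  m <- max(length(x), length(y))
  if (m < 2) stop("need series of length >= 2 weeks")
  x <- c(x, rep(0, m - length(x)))
  y <- c(y, rep(0, m - length(y)))
  if (all(x == 0) && all(y == 0)) {
    return(structure(list(T_weeks = NA_integer_, T_days = NA_integer_,
                          rho_max = NA_real_, m = m),
                     class = "delay_result"))
  }
  taus <- seq.int(-(m - 1L), m - 1L)
  rho <- vapply(taus, function(tt) cross_correlation(x, y, tt, center = center),
                numeric(1))
  best <- max(rho)
  cand <- taus[rho == best]
  cand <- cand[order(abs(cand), -cand)]
  T_weeks <- as.integer(cand[1])
  structure(list(T_weeks = T_weeks, T_days = 7L * T_weeks,
                 rho_max = best, m = m),
            class = "delay_result")
}

#' Compute interspecific delays for a collection of site-year datasets
#'
#' @param datasets list of [site_year_dataset()] objects.
#' @param fill weekly regridding of interior empty weeks, see
#'   [to_weekly_series()].
#' @return data.frame `site`, `year`, `T_weeks`, `T_days` (NA where the delay
#'   is undefined).
#' @export
study_delays <- function(datasets, fill = "interpolate") {
  rows <- lapply(datasets, function(d) {
    pip <- d$sessions[d$sessions$species == "pipiens", ]
    alb <- d$sessions[d$sessions$species == "albopictus", ]
    if (nrow(pip) < 2 || nrow(alb) < 2) {
      return(data.frame(site = d$site_id, year = d$year,
                        T_weeks = NA_integer_, T_days = NA_integer_))
    }
    res <- interspecific_delay(
      to_weekly_series(pip, fill = fill),
      to_weekly_series(alb, fill = fill)
    )
    data.frame(site = d$site_id, year = d$year,
               T_weeks = res$T_weeks, T_days = res$T_days)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise interspecific delays by group, with a Welch two-sample t-test
#'
#' Per-group mean, median, quartiles and 95% quantiles of the delay in days,
#' plus a Welch (unequal-variance) two-sample t-test between the first two
#' groups in group-label order when both contain at least 2 delays; with
#' fewer, the comparison is omitted with a warning.
#'
#' @param delays data.frame from [study_delays()] (rows with `NA` delay are
#'   dropped).
#' @param group name of the grouping column, default `"year"`.
#' @return list with `summary` (data.frame, units days) and `test`
#'   (`htest` from [stats::t.test()] or `NULL`).
#' @export
delay_summary <- function(delays, group = "year") {
  delays <- delays[!is.na(delays$T_days), , drop = FALSE]
  g <- factor(delays[[group]])
  qfun <- function(v) {
    q <- stats::quantile(v, probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
    data.frame(n = length(v), mean = mean(v), q2.5 = q[1], q25 = q[2],
               median = q[3], q75 = q[4], q97.5 = q[5], row.names = NULL)
  }
  summ <- do.call(rbind, lapply(levels(g), function(lev) {
    cbind(group = lev, qfun(delays$T_days[g == lev]))
  }))
  overall <- cbind(group = "all", qfun(delays$T_days))
  summ <- rbind(overall, summ)
  test <- NULL
  if (nlevels(g) >= 2) {
    a <- delays$T_days[g == levels(g)[1]]
    b <- delays$T_days[g == levels(g)[2]]
    if (length(a) >= 2 && length(b) >= 2 &&
        (stats::var(a) > 0 || stats::var(b) > 0)) {
      test <- stats::t.test(a, b, var.equal = FALSE)
    } else {
      warning("group with < 2 delays (or zero variance in both); t-test omitted")
    }
  }
  list(summary = summ, test = test)
}
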