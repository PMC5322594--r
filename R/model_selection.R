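#' Deviance Information Criterion of a fitted chain
#'
#' Classical (Spiegelhalter) form: with deviance `D = -2 log-likelihood`,
#' `DIC = Dbar + pD` where `Dbar` is the posterior-mean deviance and
#' `pD = Dbar - D(thetabar)` the effective number of parameters evaluated at
#' the posterior-mean parameter point.
#'
#' @param chain an `mcmc_chain` with at least 100 post-burn-in samples.
#' @param loglik_fn the same log-likelihood used to fit the chain (needed to
#'   evaluate the deviance at the posterior mean).
#' @return list with `dic`, `pD`, `Dbar`, `D_at_mean`.
#' @export
compute_dic <- function(chain, loglik_fn) {
  post <- posterior_samples(chain)
  if (nrow(post) < 100) stop("need at least 100 post-burn-in samples")
  ll <- chain$loglik[(chain$burnin + 1):nrow(chain$samples)]
  Dbar <- mean(-2 * ll)
  theta_bar <- stats::setNames(colMeans(post), colnames(post))
  D_at_mean <- -2 * loglik_fn(theta_bar)
  pD <- Dbar - D_at_mean
  list(dic = Dbar + pD, pD = pD, Dbar = Dbar, D_at_mean = D_at_mean)
}

#' Akaike Information Criterion
#'
#' @param max_loglik maximised log-likelihood (in MCMC practice, the largest
#'   log-likelihood visited by the chain).
#' @param n_params number of free parameters.
#' @return `-2 max_loglik + 2 n_params`.
#' @export
compute_aic <- function(max_loglik, n_params) {
  stopifnot(is.finite(max_loglik))
  -2 * max_loglik + 2 * n_params
}

#' Classify a site-year as competition vs independent populations
#'
#' The competition model is selected only when its DIC undercuts the
#' independent-population model's by strictly more than the threshold
#' (conservative default 4); ties and smaller differences keep the simpler
#' independent model.
#'
#' @param dic_competition,dic_independent DIC values of the two fits.
#' @param aic_competition,aic_independent optional AIC values, carried along
#'   for sensitivity analysis.
#' @param threshold minimum DIC advantage, default 4.
#' @return object of class `selection_result`.
#' @export
classify_site <- function(dic_competition, dic_independent,
                          aic_competition = NA_real_,
                          aic_independent = NA_real_, threshold = 4) {
  delta <- dic_independent - dic_competition
  structure(
    list(
      dic_competition = dic_competition, dic_independent = dic_independent,
      delta_dic = delta,
      aic_competition = aic_competition, aic_independent = aic_independent,
      delta_aic = aic_independent - aic_competition,
      classification = if (delta > threshold) "competition" else "independent",
      threshold = threshold
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %s (delta DIC = %.2f, threshold %g)\n",
    x$classification, x$delta_dic, x$threshold
  ))
  invisible(x)
}

#' Model-selection sensitivity table over scores and thresholds
#'
#' Re-classifies every fitted site-year under each combination of score
#' function (DIC or AIC difference, independent minus competition) and
#' threshold, and tabulates how many site-years select the competition model.
#'
#' @param fits list of `selection_result` objects (or of lists containing
#'   one under `$selection`).
#' @param scores character subset of `c("DIC", "AIC")`.
#' @param thresholds numeric thresholds, default `c(2, 4, 8)`.
#' @return data.frame with one row per (score, threshold): `n_competition`,
#'   `n_total`, `fraction_competition`.
#' @export
sensitivity_table <- function(fits, scores = c("DIC", "AIC"),
                              thresholds = c(2, 4, 8)) {
  if (length(fits) == 0) stop("no fits supplied")
  sel <- lapply(fits, function(f) if (inherits(f, "selection_result")) f else f$selection)
  rows <- expand.grid(score = scores, threshold = thresholds,
                      stringsAsFactors = FALSE)
  rows$n_total <- length(sel)
  rows$n_competition <- mapply(function(sc, th) {
    deltas <- vapply(sel, function(s) {
      if (sc == "DIC") s$delta_dic else s$delta_aic
    }, numeric(1))
    sum(deltas > th, na.rm = TRUE)
  }, rows$score, rows$threshold)
  rows$fraction_competition <- rows$n_competition / rows$n_total
  rows[order(rows$score, rows$threshold), ]
}
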