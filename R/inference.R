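#' Poisson log-likelihood of capture sessions given a trajectory
#'
#' Each 24-h trap session contributes a Poisson term with mean
#' `alpha_species x adult-females(session date)`; session counts are
#' conditionally independent. Predicted means are floored at `1e-10` so that a
#' deterministic prediction of exactly zero adults cannot produce `-Inf`
#' against a zero count (and yields a very unfavourable, but finite,
#' likelihood against a positive count).
#'
#' @param dataset a [site_year_dataset()].
#' @param traj a `mosq_trajectory` covering all session dates.
#' @param alpha_alb,alpha_pip daily capture rates.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(dataset, traj, alpha_alb, alpha_pip) {
  ses <- dataset$sessions
  idx <- match(ses$date, traj$dates)
  if (anyNA(idx)) stop("session date outside the simulated trajectory")
  A <- ifelse(ses$species == "albopictus",
              traj$states[idx, "alb_A"], traj$states[idx, "pip_A"])
  alpha <- ifelse(ses$species == "albopictus", alpha_alb, alpha_pip)
  lambda <- pmax(alpha * A, 1e-10)
  sum(stats::dpois(ses$count, lambda, log = TRUE))
}

#' Default uniform prior bounds for the free parameters
#'
#' Capture rates in `[0, 0.2]` (a 24-h BG trap session is assumed to catch at
#' most a fifth of the local adult females), density factors and competition
#' coefficient in `[0, 1e-2]` (per-larva daily mortality increments). Bounds
#' are wide relative to the synthetic-truth values and configurable.
#'
#' @param competition if `FALSE`, drop `c` (independent-population model,
#'   4 free parameters).
#' @return data.frame with columns `name`, `lower`, `upper`.
#' @export
default_priors <- function(competition = TRUE) {
  pr <- data.frame(
    name = c("alpha_alb", "alpha_pip", "rho_alb", "rho_pip", "c"),
    lower = c(0, 0, 0, 0, 0),
    upper = c(0.2, 0.2, 1e-2, 1e-2, 1e-2),
    stringsAsFactors = FALSE
  )
  if (!competition) pr <- pr[pr$name != "c", ]
  pr
}

#' Random-walk Metropolis-Hastings sampler with uniform priors
#'
#' Symmetric normal jumps; a proposal outside the prior box is rejected
#' without evaluating the likelihood; otherwise accepted with probability
#' `min(1, exp(delta log-likelihood))` (the uniform prior density cancels
#' inside its support). The chain starts at the prior midpoint, with seeded
#' uniform jitter retries if the likelihood there is `-Inf`.
#'
#' During burn-in the proposal is tuned in two ways (adaptive Metropolis in
#' the style of Haario et al. 2001): every 100 iterations a global scale
#' factor is nudged toward a 20-35% acceptance window, and from iteration 500
#' the jump covariance is refreshed every 250 iterations to
#' `2.38^2 / p` times the empirical covariance of the chain so far (plus a
#' small diagonal nugget), which aligns the jumps with the posterior's ridge
#' directions. All adaptation stops at the end of burn-in, so the retained
#' portion of the chain uses a fixed symmetric kernel and satisfies detailed
#' balance. Fully reproducible given `seed`.
#'
#' @param loglik_fn function(named numeric vector) -> log-likelihood.
#' @param priors data.frame with `name`, `lower`, `upper` (see
#'   [default_priors()]).
#' @param iterations,burnin chain length and burn-in (burnin < iterations).
#' @param jump_sd initial proposal standard deviations (recycled); default
#'   5% of each prior width.
#' @param seed integer RNG seed.
#' @param adapt adapt the jump scale and covariance during burn-in
#'   (default TRUE).
#' @return object of class `mcmc_chain`: `samples` (all iterations x
#'   parameters), `loglik`, `burnin`, `acceptance` (post-burn-in rate),
#'   `jump_sd` (final marginal jump sds), `priors`, `seed`.
#' @export
metropolis_hastings <- function(loglik_fn, priors, iterations = 20000,
                                burnin = 5000, jump_sd = NULL, seed = 1,
                                adapt = TRUE) {
  stopifnot(burnin < iterations, all(priors$lower < priors$upper))
  p <- nrow(priors)
  lower <- priors$lower; upper <- priors$upper
  width <- upper - lower
  if (is.null(jump_sd)) jump_sd <- 0.05 * width
  jump_sd <- rep_len(jump_sd, p)
  set.seed(seed)

  theta <- stats::setNames(lower + width / 2, priors$name)
  ll <- loglik_fn(theta)
  tries <- 0
  while (!is.finite(ll) && tries < 100) {
    theta <- stats::setNames(lower + width * stats::runif(p), priors$name)
    ll <- loglik_fn(theta)
    tries <- tries + 1
  }
  if (!is.finite(ll)) {
    stop("could not find a starting point with finite log-likelihood")
  }

  samples <- matrix(NA_real_, iterations, p,
                    dimnames = list(NULL, priors$name))
  logliks <- numeric(iterations)
  accepted <- logical(iterations)
  block_acc <- 0L
  scale <- 1
  nugget <- diag((1e-3 * width)^2, p)
  L <- diag(jump_sd, p) # lower Cholesky factor of the jump covariance

  for (i in seq_len(iterations)) {
    prop <- theta + scale * as.numeric(L %*% stats::rnorm(p))
    if (all(prop >= lower) && all(prop <= upper)) {
      ll_prop <- loglik_fn(stats::setNames(prop, priors$name))
      if (is.finite(ll_prop) &&
          log(stats::runif(1)) < (ll_prop - ll)) {
        theta <- stats::setNames(prop, priors$name)
        ll <- ll_prop
        accepted[i] <- TRUE
        block_acc <- block_acc + 1L
      }
    }
    samples[i, ] <- theta
    logliks[i] <- ll
    if (adapt && i <= burnin) {
      if (i %% 100 == 0) {
        rate <- block_acc / 100
        if (rate < 0.20) scale <- scale * 0.8
        if (rate > 0.35) scale <- scale * 1.25
        block_acc <- 0L
      }
      if (i >= 500 && i %% 250 == 0) {
        emp <- stats::cov(samples[seq_len(i), , drop = FALSE])
        L <- t(chol(2.38^2 / p * emp + nugget))
      }
    }
  }
  cov_jump <- scale^2 * tcrossprod(L)
  structure(
    list(
      samples = samples, loglik = logliks, burnin = burnin,
      acceptance = mean(accepted[(burnin + 1):iterations]),
      jump_sd = sqrt(diag(cov_jump)), priors = priors, seed = seed
    ),
    class = "mcmc_chain"
  )
}

#' Post-burn-in samples of a chain
#' @param chain an `mcmc_chain`.
#' @return matrix of retained samples.
#' @export
posterior_samples <- function(chain) {
  chain$samples[(chain$burnin + 1):nrow(chain$samples), , drop = FALSE]
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf(
    "<mcmc_chain> %d iterations (%d burn-in), %d parameters, acceptance %.2f\n",
    nrow(x$samples), x$burnin, ncol(x$samples), x$acceptance
  ))
  invisible(x)
}

#' Posterior summaries per parameter
#'
#' @param chain an `mcmc_chain` with at least 100 post-burn-in samples.
#' @return data.frame with mean, median and 2.5/25/75/97.5% quantiles per
#'   parameter.
#' @export
posterior_summary <- function(chain) {
  post <- posterior_samples(chain)
  if (nrow(post) < 100) stop("need at least 100 post-burn-in samples")
  qs <- t(apply(post, 2, stats::quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  data.frame(
    parameter = colnames(post),
    mean = colMeans(post),
    median = qs[, 3],
    q2.5 = qs[, 1], q25 = qs[, 2], q75 = qs[, 4], q97.5 = qs[, 5],
    row.names = NULL
  )
}

#' Export a chain to CSV (`iteration,<parameters...>,loglik`)
#' @param chain an `mcmc_chain`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_chain <- function(chain, path) {
  df <- data.frame(iteration = seq_len(nrow(chain$samples)), chain$samples,
                   loglik = chain$loglik)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the capture log-likelihood closure for one site-year
#'
#' Binds the dataset's precomputed forcing so each evaluation only runs the
#' compiled season simulation and the Poisson terms. The returned function
#' accepts a named vector with `alpha_alb`, `alpha_pip`, `rho_alb`,
#' `rho_pip` and optionally `c` (treated as 0 when absent: the
#' independent-population model).
#'
#' @param dataset a [site_year_dataset()].
#' @param species_params rate constants.
#' @param init initial state.
#' @return function(theta) -> log-likelihood.
#' @export
make_loglik <- function(dataset, species_params = default_species_params(),
                        init = initial_state()) {
  forcing <- build_forcing(dataset, species_params)
  ses <- dataset$sessions
  idx <- match(ses$date, forcing$dates)
  if (anyNA(idx)) stop("session date outside the simulation window")
  is_alb <- ses$species == "albopictus"
  counts <- ses$count
  init <- as.numeric(init)
  function(theta) {
    cc <- if ("c" %in% names(theta)) theta[["c"]] else 0
    states <- sim_core_cpp(
      forcing$forcing, init,
      theta[["rho_alb"]], theta[["rho_pip"]], cc,
      forcing$hatch_alb, forcing$hatch_pip
    )
    A <- ifelse(is_alb, states[idx, 5], states[idx, 9])
    alpha <- ifelse(is_alb, theta[["alpha_alb"]], theta[["alpha_pip"]])
    lambda <- pmax(alpha * A, 1e-10)
    sum(stats::dpois(counts, lambda, log = TRUE))
  }
}
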