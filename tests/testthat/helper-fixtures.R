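# Shared fixtures and independent oracles for the test suite.

# Constant-temperature site-year with a handful of placeholder sessions;
# useful for closed-form checks of the dynamics.
make_const_dataset <- function(temp_c, year = 2015, latitude = 46.07,
                               counts = c(1L, 1L, 1L, 1L)) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  temperature <- data.frame(date = dates, tmean_c = temp_c)
  sdates <- as.Date(sprintf("%d-%s", year, c("06-15", "07-15")))
  sessions <- data.frame(
    date = rep(sdates, each = 2),
    species = rep(c("albopictus", "pipiens"), 2),
    count = counts
  )
  site_year_dataset("CONST", year, sessions, temperature, latitude)
}

# Small, fast synthetic site-year (defaults: warm 2015-like scenario).
quick_sim <- function(seed = 1, c_true = 0, summer_mean = 25.5, ...) {
  truth <- parameter_vector(0.01, 0.01, 1e-3, 1e-3, c_true)
  simulate_dataset(scenario_config(summer_mean = summer_mean, truth = truth,
                                   seed = seed, ...))
}

# Independent daylength oracle: Spencer (1971) Fourier-series declination
# plus the civil sunrise/sunset hour angle. Deliberately a different
# declination formula from the one the package uses.
oracle_daylength <- function(latitude, date) {
  doy <- as.integer(strftime(as.Date(date), "%j"))
  g <- 2 * pi / 365 * (doy - 1)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  lat <- latitude * pi / 180
  x <- (sin(-0.833 * pi / 180) - sin(lat) * sin(decl)) / (cos(lat) * cos(decl))
  x <- pmin(1, pmax(-1, x))
  24 * acos(x) / pi
}

# Independent brute-force delay oracle: naive double-loop cross-correlation
# and exhaustive argmax with the tie-break smallest |tau| then positive tau.
oracle_delay <- function(x, y) {
  m <- max(length(x), length(y))
  x <- c(x, rep(0, m - length(x)))
  y <- c(y, rep(0, m - length(y)))
  best_rho <- -Inf
  best_tau <- NA_integer_
  for (tau in -(m - 1):(m - 1)) {
    rho <- 0
    for (t in 1:m) {
      if (t + tau >= 1 && t + tau <= m) rho <- rho + x[t] * y[t + tau]
    }
    better <- rho > best_rho ||
      (rho == best_rho && (abs(tau) < abs(best_tau) ||
                             (abs(tau) == abs(best_tau) && tau > best_tau)))
    if (better) {
      best_rho <- rho
      best_tau <- tau
    }
  }
  list(tau = best_tau, rho = best_rho)
}

# Batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# chain of scalar draws.
batch_se <- function(x, n_batches = 50) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

# Minimal hand-built trajectory object for observation-model tests.
make_fake_traj <- function(dates, alb_A = 0, pip_A = 0) {
  n <- length(dates)
  states <- matrix(0, n, 10)
  colnames(states) <- c(
    "alb_E", "alb_Ed", "alb_L", "alb_P", "alb_A",
    "pip_E", "pip_L", "pip_P", "pip_A", "pip_Ad"
  )
  states[, "alb_A"] <- alb_A
  states[, "pip_A"] <- pip_A
  structure(list(dates = as.Date(dates), states = states),
            class = "mosq_trajectory")
}

# Minimal hand-built chain object for summary/DIC tests.
make_fake_chain <- function(samples, loglik, burnin = 0) {
  structure(
    list(samples = samples, loglik = loglik, burnin = burnin,
         acceptance = 0.5, jump_sd = rep(1, ncol(samples)),
         priors = NULL, seed = 0),
    class = "mcmc_chain"
  )
}

# Rate constants with every mortality, fecundity and diapause channel shut
# off (for conservation checks).
conservative_params <- function() {
  p <- default_species_params()
  for (sp in names(p)) {
    p[[sp]]$egg$mu <- 0
    p[[sp]]$larva$mu <- 0
    p[[sp]]$pupa$mu <- 0
    p[[sp]]$adult$mu0 <- 0
    p[[sp]]$adult$heat_slope <- 0
    p[[sp]]$fecundity$f0 <- 0
    # logistic induction underflows to exactly 0 for any daylength > 0
    p[[sp]]$diapause$D_crit <- 0
    p[[sp]]$diapause$k <- 50
    p[[sp]]$diapause$release_rate <- 0
  }
  p
}
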