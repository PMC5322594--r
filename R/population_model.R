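# State vector layout (shared by the R reference stepper and the compiled
# core; order must not change):
#   1 alb_E   active albopictus eggs
#   2 alb_Ed  diapausing albopictus eggs (overwintering stage)
#   3 alb_L   albopictus larvae
#   4 alb_P   albopictus pupae
#   5 alb_A   albopictus adult females
#   6 pip_E   pipiens eggs
#   7 pip_L   pipiens larvae
#   8 pip_P   pipiens pupae
#   9 pip_A   pipiens adult females
#  10 pip_Ad  diapausing pipiens adult females (overwintering stage)
STATE_NAMES <- c(
  "alb_E", "alb_Ed", "alb_L", "alb_P", "alb_A",
  "pip_E", "pip_L", "pip_P", "pip_A", "pip_Ad"
)

FORCING_NAMES <- c(
  "alb_dE", "alb_dL", "alb_dP", "alb_muE", "alb_muL", "alb_muP", "alb_muA",
  "alb_fec", "alb_diap", "alb_trigger",
  "pip_dE", "pip_dL", "pip_dP", "pip_muE", "pip_muL", "pip_muP", "pip_muA",
  "pip_fec", "pip_diap", "pip_trigger",
  "comp_on"
)

#' Free-parameter vector for calibration
#'
#' The five calibrated parameters: two daily capture rates (fraction of adult
#' females caught per 24-h trap session), two intraspecific larval
#' density-dependence factors (per-capita extra daily larval mortality per
#' conspecific larva, encoding local breeding-site and food availability),
#' and the interspecific larval competition coefficient (extra daily
#' mortality of a *Cx. pipiens* larva per *Ae. albopictus* larva, active only
#' at daily mean temperatures of at least 15 deg C). The independent-model
#' variant fixes `c = 0`.
#'
#' @param alpha_alb,alpha_pip capture rates, >= 0.
#' @param rho_alb,rho_pip intraspecific density factors, >= 0.
#' @param c competition coefficient, >= 0.
#' @return named numeric vector of class `parameter_vector`.
#' @export
parameter_vector <- function(alpha_alb, alpha_pip, rho_alb, rho_pip, c = 0) {
  v <- c(
    alpha_alb = alpha_alb, alpha_pip = alpha_pip,
    rho_alb = rho_alb, rho_pip = rho_pip, c = c
  )
  if (any(v < 0)) stop("all model parameters must be >= 0")
  structure(v, class = c("parameter_vector", "numeric"))
}

#' Default initial state: overwintering stock on 1 March
#'
#' 100 diapausing eggs for *Ae. albopictus* and 100 diapausing adult females
#' for *Cx. pipiens*; all active stages empty. The overwintering stock is a
#' fixed constant, not a calibrated parameter.
#'
#' @param alb_eggs,pip_adults overwintering abundances.
#' @return named numeric state vector (length 10).
#' @export
initial_state <- function(alb_eggs = 100, pip_adults = 100) {
  s <- stats::setNames(numeric(10), STATE_NAMES)
  s["alb_Ed"] <- alb_eggs
  s["pip_Ad"] <- pip_adults
  s
}

#' Precompute daily forcing for a site-year
#'
#' Converts the temperature and photoperiod series of a dataset into the
#' per-day rate matrix the simulator consumes: development, mortality and
#' fecundity rates per species, diapause-induction fractions, the spring
#' release trigger (photoperiod lengthening, daylength above the critical
#' photoperiod, trailing 7-day mean temperature above the spring threshold)
#' and the 15 deg C competition gate. None of these depend on the calibrated
#' parameters, so the matrix is computed once per dataset and reused across
#' all likelihood evaluations.
#'
#' @param dataset a [site_year_dataset()].
#' @param species_params rate constants, see [default_species_params()].
#' @param start,end simulation window (Dates); defaults to 1 March of the
#'   dataset year through the end of temperature coverage.
#' @return list with `dates`, `forcing` (days x 21 matrix) and the two
#'   diapause release rates.
#' @export
build_forcing <- function(dataset, species_params = default_species_params(),
                          start = NULL, end = NULL) {
  if (is.null(start)) start <- as.Date(sprintf("%d-03-01", dataset$year))
  if (is.null(end)) end <- max(dataset$temperature$date)
  tser <- dataset$temperature
  if (start < min(tser$date) || end > max(tser$date)) {
    stop("temperature series does not cover the simulation window")
  }
  if (nrow(dataset$sessions) > 0 &&
      (min(dataset$sessions$date) < start || max(dataset$sessions$date) > end)) {
    stop("capture sessions fall outside the simulation window")
  }
  dates <- seq(start, end, by = "day")
  temp <- tser$tmean_c[match(dates, tser$date)]
  dl <- compute_photoperiod(dataset$latitude, dates)
  dl_prev <- compute_photoperiod(dataset$latitude, dates - 1)
  shortening <- dl < dl_prev
  # trailing 7-day mean temperature (uses the temperature series itself so the
  # first simulated days still get a proper window when coverage allows)
  t7 <- vapply(dates, function(d) {
    w <- tser$tmean_c[tser$date > d - 7 & tser$date <= d]
    mean(w)
  }, numeric(1))

  one_species <- function(p) {
    trig <- as.numeric(!shortening & dl > p$diapause$D_crit &
                         t7 > p$diapause$spring_temp)
    cbind(
      development_rate(temp, p$egg),
      development_rate(temp, p$larva),
      development_rate(temp, p$pupa),
      rep(p$egg$mu, length(temp)),
      rep(p$larva$mu, length(temp)),
      rep(p$pupa$mu, length(temp)),
      adult_mortality(temp, p$adult),
      fecundity_rate(temp, p$fecundity),
      diapause_fraction(dl, shortening, p$diapause),
      trig
    )
  }
  forcing <- cbind(
    one_species(species_params$albopictus),
    one_species(species_params$pipiens),
    as.numeric(temp >= 15)
  )
  colnames(forcing) <- FORCING_NAMES
  list(
    dates = dates, forcing = forcing, temp = temp,
    hatch_alb = species_params$albopictus$diapause$release_rate,
    hatch_pip = species_params$pipiens$diapause$release_rate
  )
}

# Competing-risks daily flow: N individuals exposed to exit rates `rates`
# leave with probability 1 - exp(-sum(rates)) and are apportioned across the
# exits proportionally to their rates. Guarantees non-negativity without
# clipping.
flow <- function(N, rates) {
  r <- sum(rates)
  if (r <= 0) return(c(N, rates * 0))
  out <- N * (1 - exp(-r))
  c(N - out, out * rates / r)
}

#' One daily step of the two-species stage-structured model (reference)
#'
#' Pure-R reference implementation of the daily update; the season simulator
#' uses an identical compiled core. Balance per stage: eggs gain
#' `fecundity x adults` and lose development plus mortality; larvae gain
#' hatched eggs and lose pupation, baseline mortality, intraspecific crowding
#' (`rho x L`) and — for *Cx. pipiens* only — interspecific competition
#' (`c x L_albopictus`, gated at 15 deg C); pupae gain pupation and lose
#' emergence plus mortality; adults gain emergents and lose adult mortality.
#' Newly laid *Ae. albopictus* eggs are routed to the diapausing-egg pool and
#' newly emerged *Cx. pipiens* females to the diapausing-adult pool in
#' proportion to the photoperiod-driven induction fraction; both pools
#' release in spring at the species' release rate while the trigger is on.
#' All per-capita rates combine additively before the `exp(-rate)` survival
#' conversion, so no compartment can go negative.
#'
#' @param state named numeric state vector (length 10, see
#'   [initial_state()]).
#' @param forcing_row one row of the matrix from [build_forcing()].
#' @param rho_alb,rho_pip,cc free dynamic parameters.
#' @param hatch_alb,hatch_pip diapause release rates (per day).
#' @return updated state vector.
#' @export
step_daily <- function(state, forcing_row, rho_alb, rho_pip, cc,
                       hatch_alb = 0.15, hatch_pip = 0.15) {
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("invalid state: NaN or negative component")
  }
  f <- forcing_row
  s <- state

  ## albopictus
  fE <- flow(s[["alb_E"]], c(f[["alb_dE"]], f[["alb_muE"]]))
  h <- if (f[["alb_trigger"]] > 0) hatch_alb else 0
  fEd <- flow(s[["alb_Ed"]], h)
  fL <- flow(s[["alb_L"]], c(f[["alb_dL"]], f[["alb_muL"]] + rho_alb * s[["alb_L"]]))
  fP <- flow(s[["alb_P"]], c(f[["alb_dP"]], f[["alb_muP"]]))
  eggs_alb <- f[["alb_fec"]] * s[["alb_A"]]
  alb_E <- fE[1] + (1 - f[["alb_diap"]]) * eggs_alb
  alb_Ed <- fEd[1] + f[["alb_diap"]] * eggs_alb
  alb_L <- fL[1] + fE[2] + fEd[2]
  alb_P <- fP[1] + fL[2]
  alb_A <- s[["alb_A"]] * exp(-f[["alb_muA"]]) + fP[2]

  ## pipiens (competition uses the beginning-of-day albopictus larvae)
  comp <- if (f[["comp_on"]] > 0) cc * s[["alb_L"]] else 0
  gE <- flow(s[["pip_E"]], c(f[["pip_dE"]], f[["pip_muE"]]))
  gL <- flow(s[["pip_L"]], c(f[["pip_dL"]],
                             f[["pip_muL"]] + rho_pip * s[["pip_L"]] + comp))
  gP <- flow(s[["pip_P"]], c(f[["pip_dP"]], f[["pip_muP"]]))
  hp <- if (f[["pip_trigger"]] > 0) hatch_pip else 0
  gAd <- flow(s[["pip_Ad"]], hp)
  em <- gP[2]
  pip_E <- gE[1] + f[["pip_fec"]] * s[["pip_A"]]
  pip_L <- gL[1] + gE[2]
  pip_P <- gP[1] + gL[2]
  pip_A <- s[["pip_A"]] * exp(-f[["pip_muA"]]) +
    (1 - f[["pip_diap"]]) * em + gAd[2]
  pip_Ad <- gAd[1] + f[["pip_diap"]] * em

  stats::setNames(
    c(alb_E, alb_Ed, alb_L, alb_P, alb_A, pip_E, pip_L, pip_P, pip_A, pip_Ad),
    STATE_NAMES
  )
}

#' Simulate a season of two-species dynamics
#'
#' Deterministic daily difference equations driven by the dataset's
#' temperature and photoperiod, from 1 March (overwintering stock only)
#' through the end of temperature coverage. The compiled core and the pure-R
#' stepper implement the identical update; `engine = "r"` exists for
#' verification.
#'
#' @param dataset a [site_year_dataset()].
#' @param theta a [parameter_vector()] (only `rho_alb`, `rho_pip`, `c` affect
#'   the dynamics; the capture rates enter the observation model).
#' @param species_params rate constants.
#' @param init initial state, default [initial_state()].
#' @param forcing optional precomputed [build_forcing()] result (reuse across
#'   likelihood evaluations).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return object of class `mosq_trajectory`: list with `dates` and `states`
#'   (days x 10 matrix of end-of-day abundances).
#' @export
simulate_season <- function(dataset, theta,
                            species_params = default_species_params(),
                            init = initial_state(), forcing = NULL,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(forcing)) forcing <- build_forcing(dataset, species_params)
  th <- as.numeric(theta[c("rho_alb", "rho_pip", "c")])
  if (engine == "cpp") {
    states <- sim_core_cpp(
      forcing$forcing, as.numeric(init), th[1], th[2], th[3],
      forcing$hatch_alb, forcing$hatch_pip
    )
  } else {
    n <- nrow(forcing$forcing)
    states <- matrix(0, n, 10)
    s <- init
    for (d in seq_len(n)) {
      s <- step_daily(s, forcing$forcing[d, ], th[1], th[2], th[3],
                      forcing$hatch_alb, forcing$hatch_pip)
      states[d, ] <- s
    }
  }
  colnames(states) <- STATE_NAMES
  structure(list(dates = forcing$dates, states = states),
            class = "mosq_trajectory")
}

#' Extract one species' adult-female series from a trajectory
#'
#' @param traj a `mosq_trajectory`.
#' @param species `"albopictus"` or `"pipiens"`.
#' @return numeric vector of daily adult-female abundances (active adults,
#'   excluding the diapausing pool).
#' @export
adult_females <- function(traj, species = c("albopictus", "pipiens")) {
  species <- match.arg(species)
  traj$states[, if (species == "albopictus") "alb_A" else "pip_A"]
}

#' @export
print.mosq_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mosq_trajectory> %d days (%s .. %s); peak adults: albopictus %.1f, pipiens %.1f\n",
    length(x$dates), min(x$dates), max(x$dates),
    max(x$states[, "alb_A"]), max(x$states[, "pip_A"])
  ))
  invisible(x)
}

#' Export a trajectory as a long-format CSV (`date,species,stage,abundance`)
#'
#' @param traj a `mosq_trajectory`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
export_trajectory <- function(traj, path) {
  sp <- ifelse(startsWith(STATE_NAMES, "alb"), "albopictus", "pipiens")
  stage <- sub("^(alb|pip)_", "", STATE_NAMES)
  df <- data.frame(
    date = rep(as.character(traj$dates), times = 10),
    species = rep(sp, each = length(traj$dates)),
    stage = rep(stage, each = length(traj$dates)),
    abundance = as.vector(traj$states)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
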