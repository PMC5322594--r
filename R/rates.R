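#' Default biological rate constants for both species
#'
#' Stage-structured daily rates for *Aedes albopictus* and *Culex pipiens*:
#' Briere temperature responses for immature development, constant baseline
#' stage mortalities with an added linear heat term for adults, a temperature
#' window for fecundity, and logistic photoperiod-driven diapause induction.
#' Values are package defaults chosen to honour the qualitative biology —
#' *Cx. pipiens* develops at cooler temperatures and suffers an adult heat
#' penalty that engages at a lower temperature than *Ae. albopictus*, which is
#' better adapted to warm conditions; *Cx. pipiens* overwinters as diapausing
#' adult females, *Ae. albopictus* as diapausing eggs. Every constant can be
#' overridden by passing a modified copy of this list to the simulators.
#'
#' Units: temperatures deg C, rates per day, fecundity female eggs per female
#' per day, photoperiods hours.
#'
#' @return nested list with elements `albopictus` and `pipiens`.
#' @export
default_species_params <- function() {
  list(
    albopictus = list(
      egg   = list(a = 1.1e-4, T_L = 10.5, T_U = 38, mu = 0.02),
      larva = list(a = 7.0e-5, T_L = 10.5, T_U = 38, mu = 0.04),
      pupa  = list(a = 2.8e-4, T_L = 10.5, T_U = 38, mu = 0.02),
      adult = list(mu0 = 0.04, T_H = 30, heat_slope = 0.008),
      fecundity = list(f0 = 4, T_low = 14, T_high = 36),
      diapause = list(D_crit = 13.0, k = 3, spring_temp = 11, release_rate = 0.15)
    ),
    pipiens = list(
      egg   = list(a = 1.6e-4, T_L = 7, T_U = 34, mu = 0.02),
      larva = list(a = 6.0e-5, T_L = 7, T_U = 34, mu = 0.03),
      pupa  = list(a = 3.0e-4, T_L = 7, T_U = 34, mu = 0.02),
      adult = list(mu0 = 0.035, T_H = 26, heat_slope = 0.015),
      fecundity = list(f0 = 5, T_low = 10, T_high = 32),
      diapause = list(D_crit = 13.5, k = 3, spring_temp = 11, release_rate = 0.15)
    )
  )
}

#' Briere temperature-dependent development rate
#'
#' `a * T * (T - T_L) * sqrt(T_U - T)` inside the thermal window
#' `(T_L, T_U)`, zero at and outside the thresholds. Unimodal with a single
#' interior maximum, the canonical shape for insect development rates.
#'
#' @param T temperature, deg C (vectorised).
#' @param stage_params list with `a`, `T_L`, `T_U`.
#' @return per-day development rate, >= 0.
#' @export
development_rate <- function(T, stage_params) {
  a <- stage_params$a; T_L <- stage_params$T_L; T_U <- stage_params$T_U
  r <- ifelse(T > T_L & T < T_U, a * T * (T - T_L) * sqrt(pmax(T_U - T, 0)), 0)
  pmax(r, 0)
}

#' Adult daily mortality rate with heat penalty
#'
#' Constant baseline `mu0` plus a linear penalty `heat_slope * (T - T_H)` for
#' temperatures above the species' heat-onset temperature `T_H`. The
#' *Cx. pipiens* default `T_H` is below the *Ae. albopictus* one, encoding the
#' lower heat tolerance of *Cx. pipiens* adults in summer.
#'
#' @param T temperature, deg C (vectorised).
#' @param adult_params list with `mu0`, `T_H`, `heat_slope`.
#' @return per-day mortality rate, >= `mu0`.
#' @export
adult_mortality <- function(T, adult_params) {
  adult_params$mu0 + adult_params$heat_slope * pmax(0, T - adult_params$T_H)
}

fecundity_rate <- function(T, fec_params) {
  ifelse(T > fec_params$T_low & T < fec_params$T_high, fec_params$f0, 0)
}

#' Photoperiod-driven diapause induction fraction
#'
#' Logistic in the shortfall of daylength below the critical photoperiod
#' `D_crit`: `1 / (1 + exp(-k * (D_crit - daylength)))` while photoperiod is
#' shortening (after the summer solstice), and exactly 0 while it is
#' lengthening — diapause is induced only by shortening days.
#'
#' @param daylength hours, in (0, 24) (vectorised).
#' @param shortening logical: is the photoperiod currently decreasing?
#' @param diapause_params list with `D_crit` (hours) and `k` (per hour).
#' @return fraction in \[0, 1\].
#' @export
diapause_fraction <- function(daylength, shortening, diapause_params) {
  frac <- 1 / (1 + exp(-diapause_params$k * (diapause_params$D_crit - daylength)))
  ifelse(shortening, frac, 0)
}

#' Interspecific competition mortality on Cx. pipiens larvae
#'
#' Extra per-capita daily mortality of *Cx. pipiens* larvae proportional to
#' the co-occurring *Ae. albopictus* larval abundance, gated off below 15 deg
#' C (competition weakens at cool temperatures): returns `c * L_albopictus`
#' when `T >= T_gate`, else 0.
#'
#' @param c competition coefficient (per albopictus larva per day), >= 0.
#' @param T daily mean temperature, deg C.
#' @param L_albopictus albopictus larval abundance, >= 0.
#' @param T_gate gate temperature, default 15 deg C.
#' @return per-day extra mortality rate.
#' @export
competition_mortality <- function(c, T, L_albopictus, T_gate = 15) {
  ifelse(T >= T_gate, c * L_albopictus, 0)
}
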