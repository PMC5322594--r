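#' Scenario configuration for synthetic site-years
#'
#' Describes one synthetic site-year: a seasonal sinusoidal temperature with
#' AR(1) noise targeting a given July-September mean (a cool year like 20.6
#' deg C or a warm year like 25.5 deg C), biweekly 24-h trap sessions from
#' late April to early November, and the true parameter values used both to
#' simulate the latent dynamics and to thin them into Poisson counts.
#'
#' @param site_id,year labels.
#' @param latitude degrees North (default 46.07, an Alpine-valley latitude).
#' @param summer_mean target July-September mean temperature, deg C. Default
#'   25.5 (warm year); use 20.6 for a cool year.
#' @param amplitude annual sinusoid amplitude, deg C.
#' @param peak_doy day of year of the temperature peak (default 208 = 27
#'   July).
#' @param ar_phi,ar_sd AR(1) daily noise autocorrelation and innovation sd.
#' @param cadence days between trap sessions (>= 7, default 14).
#' @param season_start,season_end trapping window within the year
#'   (month-day strings).
#' @param truth a [parameter_vector()] of true parameter values.
#' @param seed integer RNG seed for this dataset.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(site_id = "S1", year = 2015, latitude = 46.07,
                            summer_mean = 25.5, amplitude = 11,
                            peak_doy = 208, ar_phi = 0.7, ar_sd = 1.5,
                            cadence = 14, season_start = "04-25",
                            season_end = "11-05",
                            truth = parameter_vector(
                              alpha_alb = 0.01, alpha_pip = 0.01,
                              rho_alb = 1e-3, rho_pip = 1e-3, c = 0
                            ),
                            seed = 1) {
  stopifnot(cadence >= 7)
  structure(
    list(
      site_id = site_id, year = year, latitude = latitude,
      summer_mean = summer_mean, amplitude = amplitude, peak_doy = peak_doy,
      ar_phi = ar_phi, ar_sd = ar_sd, cadence = cadence,
      season_start = season_start, season_end = season_end,
      truth = truth, seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' Generate a synthetic daily temperature series
#'
#' `T(d) = mu + A cos(2 pi (d - d_peak) / 365) + AR(1) noise`, with the
#' annual mean `mu` solved in closed form so that the July-September mean of
#' the noiseless sinusoid equals the configured target (the AR(1) noise has
#' zero mean, so the target holds in expectation). Reproducible by seed.
#'
#' @param config a [scenario_config()].
#' @return data.frame `date`, `tmean_c` covering the whole calendar year.
#' @export
generate_temperature <- function(config) {
  dates <- seq(as.Date(sprintf("%d-01-01", config$year)),
               as.Date(sprintf("%d-12-31", config$year)), by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  sinus <- config$amplitude * cos(2 * pi * (doy - config$peak_doy) / 365)
  summer <- dates >= as.Date(sprintf("%d-07-01", config$year)) &
    dates <= as.Date(sprintf("%d-09-30", config$year))
  mu <- config$summer_mean - mean(sinus[summer])
  set.seed(config$seed)
  n <- length(dates)
  noise <- numeric(n)
  if (config$ar_sd > 0) {
    noise[1] <- stats::rnorm(1, 0, config$ar_sd / sqrt(1 - config$ar_phi^2))
    eps <- stats::rnorm(n - 1, 0, config$ar_sd)
    for (d in 2:n) noise[d] <- config$ar_phi * noise[d - 1] + eps[d - 1]
  }
  data.frame(date = dates, tmean_c = mu + sinus + noise)
}

#' Simulate one synthetic site-year dataset with known ground truth
#'
#' Generates the temperature series, runs the deterministic two-species model
#' under the scenario's true parameters, lays out 24-h trap sessions every
#' `cadence` days across the trapping window, and draws
#' `count ~ Poisson(alpha_species x adult females)` at each session for each
#' species.
#'
#' @param config a [scenario_config()].
#' @param species_params,init model constants.
#' @return list with `dataset` (a [site_year_dataset()]), `trajectory`
#'   (ground-truth `mosq_trajectory`) and `truth`.
#' @export
simulate_dataset <- function(config, species_params = default_species_params(),
                             init = initial_state()) {
  temperature <- generate_temperature(config)
  session_dates <- seq(
    as.Date(sprintf("%d-%s", config$year, config$season_start)),
    as.Date(sprintf("%d-%s", config$year, config$season_end)),
    by = config$cadence
  )
  empty <- data.frame(
    date = rep(session_dates, each = 2),
    species = rep(c("albopictus", "pipiens"), length(session_dates)),
    count = 0L
  )
  dataset <- site_year_dataset(config$site_id, config$year, empty,
                               temperature, config$latitude)
  traj <- simulate_season(dataset, config$truth, species_params, init = init)
  idx <- match(session_dates, traj$dates)
  lam_alb <- config$truth[["alpha_alb"]] * traj$states[idx, "alb_A"]
  lam_pip <- config$truth[["alpha_pip"]] * traj$states[idx, "pip_A"]
  # session-count draws use a separate stream so temperature and observation
  # noise are independently reproducible
  set.seed(config$seed + 1L)
  counts <- as.vector(rbind(stats::rpois(length(idx), lam_alb),
                            stats::rpois(length(idx), lam_pip)))
  dataset$sessions$count <- counts
  list(dataset = dataset, trajectory = traj, truth = config$truth)
}

#' Generate a labelled synthetic study
#'
#' A collection of site-years with known competition status:
#' `round(fraction_with_competition * n_sites)` sites receive a competition
#' coefficient drawn uniformly from `c_range` and the rest have `c = 0`.
#' Per-site seeds are derived deterministically from the template's master
#' seed.
#'
#' @param n_sites number of site-years, >= 1.
#' @param fraction_with_competition fraction in \[0, 1\]; the number of
#'   competition sites is `round(fraction * n_sites)` (half-up at .5).
#' @param template a [scenario_config()] used for every site (site id, c and
#'   seed are overridden per site).
#' @param c_range range of true competition coefficients for competition
#'   sites; the default `c(5e-4, 2.5e-3)` spans seasonal pipiens reductions
#'   of roughly 25-65% at the default population scale, the magnitude range
#'   reported for wild populations.
#' @return list of class `synthetic_study`: `sites` (list of
#'   [simulate_dataset()] results) and `labels` (data.frame
#'   `site,year,alpha_alb,alpha_pip,rho_alb,rho_pip,c,label`).
#' @export
generate_study <- function(n_sites, fraction_with_competition,
                           template = scenario_config(),
                           c_range = c(5e-4, 2.5e-3)) {
  stopifnot(n_sites >= 1, fraction_with_competition >= 0,
            fraction_with_competition <= 1)
  n_comp <- round(fraction_with_competition * n_sites)
  set.seed(template$seed)
  c_true <- c(stats::runif(n_comp, c_range[1], c_range[2]),
              rep(0, n_sites - n_comp))
  sites <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    cfg <- template
    cfg$site_id <- sprintf("S%02d", i)
    cfg$seed <- (template$seed + 7919L * i) %% 2147483647L
    cfg$truth[["c"]] <- c_true[i]
    sites[[i]] <- simulate_dataset(cfg)
    names(sites)[i] <- cfg$site_id
  }
  labels <- data.frame(
    site = names(sites),
    year = template$year,
    alpha_alb = vapply(sites, function(s) s$truth[["alpha_alb"]], 1),
    alpha_pip = vapply(sites, function(s) s$truth[["alpha_pip"]], 1),
    rho_alb = vapply(sites, function(s) s$truth[["rho_alb"]], 1),
    rho_pip = vapply(sites, function(s) s$truth[["rho_pip"]], 1),
    c = vapply(sites, function(s) s$truth[["c"]], 1),
    label = ifelse(c_true > 0, "competition", "independent"),
    row.names = NULL
  )
  structure(list(sites = sites, labels = labels), class = "synthetic_study")
}

#' Write a synthetic study in the capture/temperature CSV dialect
#'
#' Emits the same CSV formats [read_capture_table()] reads, plus a sidecar
#' ground-truth CSV (`site,year,alpha_alb,alpha_pip,rho_alb,rho_pip,c,label`).
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    capture = file.path(dir, "captures.csv"),
    temperature = file.path(dir, "temperature.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_capture_table(lapply(study$sites, `[[`, "dataset"),
                      paths["capture"], paths["temperature"])
  utils::write.csv(study$labels, paths["truth"], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
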