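#' Compute photoperiod (daylength) from solar geometry
#'
#' Daylength in hours for a given latitude and calendar date, using the
#' standard sunrise-equation model of Forsythe et al. (1995, Ecol. Model. 80)
#' with the civil sunrise/sunset definition: the day runs while the solar
#' centre is above -0.833 degrees (atmospheric refraction plus solar disc).
#' Agreement with ephemeris tables is within a few minutes at temperate
#' latitudes, which is ample for photoperiod-driven diapause modelling.
#'
#' @param latitude degrees North (negative = South); must satisfy
#'   `abs(latitude) < 66.5` (no polar day/night support).
#' @param date a `Date` vector.
#' @param horizon solar depression angle at sunrise/sunset, degrees below the
#'   geometric horizon. The default 0.8333 is the civil convention
#'   (atmospheric refraction plus the solar semi-diameter); 0 gives the
#'   purely geometric daylength, which is exactly complementary between
#'   hemispheres.
#' @return daylength in hours, same length as `date`, in (0, 24).
#' @examples
#' compute_photoperiod(46.07, as.Date("2015-06-21"))
#' @export
compute_photoperiod <- function(latitude, date, horizon = 0.8333) {
  if (abs(latitude) >= 66.5) {
    stop("polar latitudes (|latitude| >= 66.5) are not supported")
  }
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  # revolution angle and solar declination (Forsythe et al. 1995, CBM model)
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  decl <- asin(0.39795 * cos(theta))
  p <- horizon
  lat <- latitude * pi / 180
  x <- (sin(p * pi / 180) + sin(lat) * sin(decl)) / (cos(lat) * cos(decl))
  x <- pmin(1, pmax(-1, x))
  24 - (24 / pi) * acos(x)
}

#' Build a per-site-per-year dataset of capture sessions plus forcing series
#'
#' The central data record: one site-year's trap sessions for both species,
#' the site's daily mean temperature series, and the photoperiod series
#' computed from the site latitude.
#'
#' @param site_id character scalar.
#' @param year integer year label.
#' @param sessions data.frame with columns `date` (Date), `species`
#'   (`"albopictus"` or `"pipiens"`) and `count` (non-negative integer).
#' @param temperature data.frame with columns `date` (consecutive daily Dates)
#'   and `tmean_c` (finite daily mean temperature, deg C).
#' @param latitude degrees North, used to compute the photoperiod series on
#'   the temperature dates.
#' @return an object of class `site_year_dataset`.
#' @export
site_year_dataset <- function(site_id, year, sessions, temperature, latitude) {
  stopifnot(is.data.frame(sessions), is.data.frame(temperature))
  sessions$date <- as.Date(sessions$date)
  temperature$date <- as.Date(temperature$date)
  bad_sp <- setdiff(unique(sessions$species), c("albopictus", "pipiens"))
  if (length(bad_sp) > 0) {
    stop("unknown species label(s): ", paste(bad_sp, collapse = ", "))
  }
  if (any(sessions$count < 0)) stop("negative capture count")
  if (anyDuplicated(sessions[c("date", "species")])) {
    stop("duplicate (date, species) capture session")
  }
  dd <- diff(as.integer(temperature$date))
  if (length(dd) > 0 && any(dd != 1L)) {
    stop("temperature dates must be strictly consecutive daily values")
  }
  if (any(!is.finite(temperature$tmean_c))) stop("non-finite temperature")
  if (any(sessions$date < min(temperature$date)) ||
      any(sessions$date > max(temperature$date))) {
    stop("capture sessions fall outside temperature coverage")
  }
  sessions <- sessions[order(sessions$date, sessions$species), , drop = FALSE]
  rownames(sessions) <- NULL
  photoperiod <- data.frame(
    date = temperature$date,
    daylength = compute_photoperiod(latitude, temperature$date)
  )
  structure(
    list(
      site_id = as.character(site_id), year = as.integer(year),
      sessions = sessions, temperature = temperature,
      photoperiod = photoperiod, latitude = latitude
    ),
    class = "site_year_dataset"
  )
}

#' @export
print.site_year_dataset <- function(x, ...) {
  cat(sprintf(
    "<site_year_dataset> site %s, year %d: %d sessions (%d dates), %d temperature days\n",
    x$site_id, x$year, nrow(x$sessions), length(unique(x$sessions$date)),
    nrow(x$temperature)
  ))
  invisible(x)
}

#' Read a capture table into site-year datasets
#'
#' Ingests a CSV with columns `site,date,species,count` (dates ISO-8601,
#' species `albopictus`/`pipiens`) and a matching temperature CSV with columns
#' `site,date,tmean_c`, and assembles one [site_year_dataset()] per
#' (site, year) combination present in the capture table.
#'
#' @param capture_path path to the capture CSV.
#' @param temperature_path path to the daily temperature CSV.
#' @param latitude site latitude in degrees North (scalar, applied to all
#'   sites; the study region is compact enough for a single photoperiod).
#' @return a list of `site_year_dataset` objects, named `"<site>_<year>"`.
#' @export
read_capture_table <- function(capture_path, temperature_path, latitude = 46.07) {
  cap <- utils::read.csv(capture_path, stringsAsFactors = FALSE)
  need <- c("site", "date", "species", "count")
  if (!all(need %in% names(cap))) {
    stop("capture CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!cap$species %in% c("albopictus", "pipiens"))
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown species '%s' in capture table row %d", cap$species[bad[1]], bad[1]
    ))
  }
  bad <- which(cap$count < 0)
  if (length(bad) > 0) stop(sprintf("negative count in capture table row %d", bad[1]))
  if (anyDuplicated(cap[c("site", "date", "species")])) {
    stop("duplicate (site, date, species) rows in capture table")
  }
  cap$date <- as.Date(cap$date)
  tmp <- utils::read.csv(temperature_path, stringsAsFactors = FALSE)
  if (!all(c("site", "date", "tmean_c") %in% names(tmp))) {
    stop("temperature CSV must have columns: site, date, tmean_c")
  }
  tmp$date <- as.Date(tmp$date)
  cap$year <- as.integer(strftime(cap$date, "%Y"))
  keys <- unique(cap[c("site", "year")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    s <- keys$site[i]; y <- keys$year[i]
    rows <- cap$site == s & cap$year == y
    trows <- tmp$site == s & as.integer(strftime(tmp$date, "%Y")) == y
    if (!any(trows)) stop(sprintf("no temperature rows for site %s year %d", s, y))
    out[[i]] <- site_year_dataset(
      site_id = s, year = y,
      sessions = cap[rows, c("date", "species", "count")],
      temperature = tmp[trows, c("date", "tmean_c")],
      latitude = latitude
    )
    names(out)[i] <- paste(s, y, sep = "_")
  }
  out
}

#' Write site-year datasets back to the capture/temperature CSV dialect
#'
#' @param datasets list of `site_year_dataset` objects.
#' @param capture_path,temperature_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_capture_table <- function(datasets, capture_path, temperature_path) {
  cap <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(
      site = d$site_id, date = as.character(d$sessions$date),
      species = d$sessions$species, count = d$sessions$count
    )
  }))
  tmp <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(
      site = d$site_id, date = as.character(d$temperature$date),
      tmean_c = d$temperature$tmean_c
    )
  }))
  utils::write.csv(cap, capture_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(tmp, temperature_path, row.names = FALSE, quote = FALSE)
  invisible(c(capture_path, temperature_path))
}

iso_week_start <- function(date) {
  # Monday of the ISO week containing `date`
  wd <- as.integer(strftime(date, "%u")) # 1 = Monday .. 7 = Sunday
  date - (wd - 1L)
}

#' Regrid one species' capture sessions to a weekly series
#'
#' Builds a weekly abundance series from the ISO week of the first session to
#' the ISO week of the last. Weeks containing one or more sessions take the
#' session count (mean when several fall in the same week); interior empty
#' weeks are filled either by linear interpolation (default) or with zeros.
#'
#' @param sessions data.frame with columns `date` and `count` for a single
#'   species (at least 2 sessions).
#' @param fill `"interpolate"` (default) or `"zero"` for interior empty weeks.
#' @return an object of class `weekly_series`: list with `start` (Monday of
#'   the first week), `values` and `m` (length in weeks).
#' @export
to_weekly_series <- function(sessions, fill = c("interpolate", "zero")) {
  fill <- match.arg(fill)
  if (nrow(sessions) < 2) stop("need at least 2 sessions to build a weekly series")
  dates <- as.Date(sessions$date)
  start <- iso_week_start(min(dates))
  widx <- as.integer(floor(as.numeric(dates - start) / 7)) + 1L
  m <- max(widx)
  vals <- rep(NA_real_, m)
  agg <- tapply(sessions$count, widx, mean)
  vals[as.integer(names(agg))] <- as.numeric(agg)
  if (anyNA(vals)) {
    if (fill == "zero") {
      vals[is.na(vals)] <- 0
    } else {
      obs <- which(!is.na(vals))
      vals <- stats::approx(obs, vals[obs], xout = seq_len(m))$y
    }
  }
  structure(list(start = start, values = vals, m = m), class = "weekly_series")
}
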