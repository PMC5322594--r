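test_that("capture table reader assembles site-year datasets and round-trips", {
  dir <- withr::local_tempdir()
  cap <- file.path(dir, "cap.csv")
  tmp <- file.path(dir, "tmp.csv")
  writeLines(c(
    "site,date,species,count",
    "A,2015-06-01,albopictus,3",
    "A,2015-06-01,pipiens,5",
    "A,2015-06-15,albopictus,7",
    "A,2015-06-15,pipiens,2"
  ), cap)
  dates <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  write.csv(data.frame(site = "A", date = dates, tmean_c = 20), tmp,
            row.names = FALSE, quote = FALSE)

  ds <- read_capture_table(cap, tmp)
  expect_length(ds, 1)
  d <- ds[[1]]
  expect_s3_class(d, "site_year_dataset")
  expect_equal(nrow(d$sessions), 4)
  expect_equal(sum(d$sessions$count), 17)
  expect_equal(d$year, 2015)

  # writer -> reader round trip preserves counts and dates
  cap2 <- file.path(dir, "cap2.csv")
  tmp2 <- file.path(dir, "tmp2.csv")
  write_capture_table(ds, cap2, tmp2)
  ds2 <- read_capture_table(cap2, tmp2)
  expect_equal(ds2[[1]]$sessions$count, d$sessions$count)
  expect_equal(ds2[[1]]$sessions$date, d$sessions$date)
  expect_equal(ds2[[1]]$temperature$tmean_c, d$temperature$tmean_c)
})

test_that("capture table schema violations are hard errors naming the row", {
  dir <- withr::local_tempdir()
  tmp <- file.path(dir, "tmp.csv")
  dates <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  write.csv(data.frame(site = "A", date = dates, tmean_c = 20), tmp,
            row.names = FALSE, quote = FALSE)

  bad_species <- file.path(dir, "bad1.csv")
  writeLines(c("site,date,species,count",
               "A,2015-06-01,albopictus,3",
               "A,2015-06-08,aegypti,1"), bad_species)
  expect_error(read_capture_table(bad_species, tmp), "aegypti.*row 2")

  bad_count <- file.path(dir, "bad2.csv")
  writeLines(c("site,date,species,count",
               "A,2015-06-01,pipiens,-2"), bad_count)
  expect_error(read_capture_table(bad_count, tmp), "negative count.*row 1")

  dup <- file.path(dir, "bad3.csv")
  writeLines(c("site,date,species,count",
               "A,2015-06-01,pipiens,2",
               "A,2015-06-01,pipiens,4"), dup)
  expect_error(read_capture_table(dup, tmp), "duplicate")
})

test_that("photoperiod matches solar-geometry expectations and the oracle", {
  # equator: ~12.1 h all year (refraction makes it slightly over 12)
  expect_equal(compute_photoperiod(0, as.Date("2015-03-01")), 12.1,
               tolerance = 0.1 / 12.1)
  # temperate summer solstice
  expect_equal(compute_photoperiod(46.07, as.Date("2015-06-21")), 15.7,
               tolerance = 0.15 / 15.7)
  # hemispheric symmetry: exact for the geometric daylength; the civil
  # (refraction-corrected) daylength exceeds the complement slightly on
  # both sides of the equator
  dates <- as.Date("2015-01-01") + seq(0, 360, by = 30)
  for (lat in c(10, 30, 46.07, 60)) {
    geom <- compute_photoperiod(lat, dates, horizon = 0) +
      compute_photoperiod(-lat, dates, horizon = 0)
    expect_true(all(abs(geom - 24) < 1e-9))
    civil <- compute_photoperiod(lat, dates) + compute_photoperiod(-lat, dates)
    expect_true(all(civil >= 24 & civil < 24.8))
  }
  # independent-oracle agreement to +-0.2 h across latitudes and the year
  for (lat in c(-55, -30, 0, 23.5, 46.07, 60)) {
    expect_true(all(abs(compute_photoperiod(lat, dates) -
                          oracle_daylength(lat, dates)) < 0.2))
  }
  # smoothness at temperate latitude: < 0.1 h change per day
  year <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  dl <- compute_photoperiod(46.07, year)
  expect_lt(max(abs(diff(dl))), 0.1)
  # annual maximum at the June solstice for northern latitudes
  expect_equal(format(year[which.max(dl)], "%m"), "06")
  expect_error(compute_photoperiod(70, as.Date("2015-06-21")), "polar")
})

test_that("weekly regridding interpolates interior weeks and conserves sessions", {
  base <- as.Date("2015-06-01") # a Monday
  s <- data.frame(date = base + c(0, 14, 28), count = c(2, 6, 4))
  w <- to_weekly_series(s)
  expect_equal(w$values, c(2, 4, 6, 5, 4))
  expect_equal(w$m, 5)

  # zero-fill variant
  wz <- to_weekly_series(s, fill = "zero")
  expect_equal(wz$values, c(2, 0, 6, 0, 4))

  # weekly-spaced sessions: identity, no interpolation
  s7 <- data.frame(date = base + c(0, 7, 14), count = c(3, 1, 9))
  expect_equal(to_weekly_series(s7)$values, c(3, 1, 9))

  # several sessions in one ISO week are averaged
  s2 <- data.frame(date = base + c(0, 2, 7), count = c(2, 4, 10))
  expect_equal(to_weekly_series(s2)$values, c(3, 10))

  # weeks containing exactly one session reproduce the count exactly,
  # regardless of the weekday the series starts on
  set.seed(42)
  for (rep in 1:20) {
    offs <- sort(sample(0:60, 5))
    cnt <- rpois(5, 8)
    sr <- data.frame(date = base + sample(0:6, 1) + offs, count = cnt)
    wk0 <- mosqcomp:::iso_week_start(sr$date[1])
    sr <- sr[!duplicated(floor(as.numeric(sr$date - wk0) / 7)), ]
    wr <- to_weekly_series(sr)
    widx <- floor(as.numeric(sr$date - wk0) / 7) + 1
    expect_equal(wr$values[widx], sr$count)
  }

  expect_error(to_weekly_series(data.frame(date = base, count = 1)),
               "at least 2 sessions")
})

test_that("site_year_dataset validates its invariants", {
  dates <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  temp <- data.frame(date = dates, tmean_c = 20)
  ses <- data.frame(date = as.Date("2015-06-01"),
                    species = "pipiens", count = 1)
  expect_s3_class(site_year_dataset("A", 2015, ses, temp, 46), "site_year_dataset")
  expect_error(site_year_dataset("A", 2015, transform(ses, count = -1), temp, 46),
               "negative")
  expect_error(site_year_dataset("A", 2015, transform(ses, species = "aegypti"),
                                 temp, 46), "unknown species")
  gap <- temp[-100, ]
  expect_error(site_year_dataset("A", 2015, ses, gap, 46), "consecutive")
  out <- transform(ses, date = as.Date("2016-02-01"))
  expect_error(site_year_dataset("A", 2015, out, temp, 46), "outside")
})
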