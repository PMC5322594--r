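test_that("development rate is zero at thresholds and unimodal inside", {
  p <- default_species_params()
  for (sp in c("albopictus", "pipiens")) {
    for (stage in c("egg", "larva", "pupa")) {
      sp_par <- p[[sp]][[stage]]
      expect_identical(development_rate(sp_par$T_L, sp_par), 0)
      expect_identical(development_rate(sp_par$T_U, sp_par), 0)
      expect_identical(development_rate(sp_par$T_L - 5, sp_par), 0)
      expect_identical(development_rate(sp_par$T_U + 5, sp_par), 0)
      # brute-force grid scan: strictly interior single maximum
      grid <- seq(sp_par$T_L, sp_par$T_U, by = 0.1)
      r <- development_rate(grid, sp_par)
      expect_true(all(r >= 0))
      imax <- which.max(r)
      expect_gt(imax, 1)
      expect_lt(imax, length(grid))
      # unimodal: increasing before the max, decreasing after
      expect_true(all(diff(r[1:imax]) > 0))
      expect_true(all(diff(r[imax:length(grid)]) < 0))
    }
  }
})

test_that("adult mortality: baseline at reference, heat-monotone, species-ordered", {
  p <- default_species_params()
  for (sp in c("albopictus", "pipiens")) {
    ap <- p[[sp]]$adult
    expect_identical(adult_mortality(20, ap), ap$mu0)
    grid <- seq(ap$T_H, 50, by = 0.25)
    r <- adult_mortality(grid, ap)
    expect_true(all(diff(r) >= 0))
    expect_true(all(adult_mortality(seq(-20, 50, by = 0.5), ap) >= ap$mu0))
  }
  # pipiens heat penalty engages at a lower temperature than albopictus
  expect_lt(p$pipiens$adult$T_H, p$albopictus$adult$T_H)
})

test_that("diapause induction is logistic while shortening, zero while lengthening", {
  dp <- default_species_params()$pipiens$diapause
  expect_equal(diapause_fraction(dp$D_crit, TRUE, dp), 0.5)
  expect_lt(diapause_fraction(dp$D_crit + 6, TRUE, dp), 0.01)
  expect_gt(diapause_fraction(dp$D_crit - 6, TRUE, dp), 0.99)
  for (dl in c(6, dp$D_crit, 18)) {
    expect_identical(diapause_fraction(dl, FALSE, dp), 0)
  }
})

test_that("competition mortality is gated at 15 deg C and linear in L", {
  expect_identical(competition_mortality(1e-3, 10, 5000), 0)
  expect_identical(competition_mortality(1e-3, 14.999, 5000), 0)
  expect_identical(competition_mortality(0, 30, 1e6), 0)
  expect_equal(competition_mortality(1e-4, 20, 1000), 0.1)
  expect_equal(competition_mortality(2e-4, 15, 500), 0.1) # gate is >=
})

test_that("daily step: absorbing zero, input validation, independence at c = 0", {
  d <- make_const_dataset(25)
  frc <- build_forcing(d)
  zero <- setNames(numeric(10), names(initial_state()))
  out <- step_daily(zero, frc$forcing[100, ], 1e-3, 1e-3, 1e-3)
  expect_identical(unname(out), numeric(10))

  bad <- initial_state(); bad[3] <- -1
  expect_error(step_daily(bad, frc$forcing[100, ], 0, 0, 0), "invalid state")
  bad2 <- initial_state(); bad2[1] <- NaN
  expect_error(step_daily(bad2, frc$forcing[100, ], 0, 0, 0), "invalid state")

  # with c = 0, the pipiens sub-state is identical whether or not
  # albopictus are present
  s_with <- initial_state(); s_with[c("alb_L", "pip_L")] <- c(5000, 300)
  s_without <- s_with; s_without["alb_L"] <- 0
  a <- step_daily(s_with, frc$forcing[150, ], 1e-3, 1e-3, 0)
  b <- step_daily(s_without, frc$forcing[150, ], 1e-3, 1e-3, 0)
  pip <- grep("^pip", names(a))
  expect_identical(a[pip], b[pip])
})

test_that("single larval cohort decays at the closed-form exponential rate", {
  # pipiens larvae only, rho = 0, constant 25 C, reproduction off:
  # L(t) = L0 exp(-(d_L + mu_L) t)
  d <- make_const_dataset(25)
  p <- default_species_params()
  p$pipiens$fecundity$f0 <- 0 # emerged adults must not refill the egg stage
  frc <- build_forcing(d, p)
  s <- setNames(numeric(10), names(initial_state()))
  s["pip_L"] <- 100
  dL <- development_rate(25, p$pipiens$larva)
  muL <- p$pipiens$larva$mu
  for (t in 1:10) {
    s <- step_daily(s, frc$forcing[t, ], 0, 0, 0)
    expect_equal(s[["pip_L"]], 100 * exp(-(dL + muL) * t), tolerance = 1e-12)
  }
})

test_that("zero initial abundances give an identically zero trajectory", {
  d <- make_const_dataset(22)
  zero <- setNames(numeric(10), names(initial_state()))
  tr <- simulate_season(d, parameter_vector(0.01, 0.01, 1e-3, 1e-3, 1e-3),
                        init = zero)
  expect_true(all(tr$states == 0))
})

test_that("compiled core and R reference stepper agree to machine precision", {
  sim <- quick_sim(seed = 5, c_true = 1.2e-3)
  set.seed(99)
  for (rep in 1:3) {
    th <- parameter_vector(runif(1, 0, 0.2), runif(1, 0, 0.2),
                           runif(1, 0, 1e-2), runif(1, 0, 1e-2),
                           runif(1, 0, 1e-2))
    tc <- simulate_season(sim$dataset, th, engine = "cpp")
    tr <- simulate_season(sim$dataset, th, engine = "r")
    expect_equal(tc$states, tr$states, tolerance = 1e-14)
  }
})

test_that("15 C gate: cool-year pipiens trajectories are bit-identical across c", {
  d <- make_const_dataset(10)
  base <- NULL
  for (cc in c(0, 1e-5, 1e-3)) {
    tr <- simulate_season(d, parameter_vector(0.01, 0.01, 1e-3, 1e-3, cc))
    pip <- tr$states[, grep("^pip", colnames(tr$states))]
    if (is.null(base)) base <- pip else expect_identical(pip, base)
  }
})

test_that("asymmetry: albopictus is bit-identical for any c and pipiens stock", {
  sim <- quick_sim(seed = 6)
  d <- sim$dataset
  ref <- simulate_season(d, parameter_vector(0.01, 0.01, 1e-3, 1e-3, 0))
  alb_cols <- grep("^alb", colnames(ref$states))
  for (cc in c(1e-5, 1e-3, 1e-2)) {
    tr <- simulate_season(d, parameter_vector(0.01, 0.01, 1e-3, 1e-3, cc))
    expect_identical(tr$states[, alb_cols], ref$states[, alb_cols])
  }
  # scaling the pipiens overwintering stock leaves albopictus untouched
  for (pipstock in c(0, 10, 1000)) {
    tr <- simulate_season(d, parameter_vector(0.01, 0.01, 1e-3, 1e-3, 1e-3),
                          init = initial_state(pip_adults = pipstock))
    expect_identical(tr$states[, alb_cols], ref$states[, alb_cols])
  }
})

test_that("pipiens seasonal adult total declines monotonically in c (warm year)", {
  sim <- quick_sim(seed = 7)
  totals <- vapply(c(0, 1e-6, 1e-5, 1e-4), function(cc) {
    tr <- simulate_season(sim$dataset,
                          parameter_vector(0.01, 0.01, 1e-3, 1e-3, cc))
    sum(adult_females(tr, "pipiens"))
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("with all loss channels off, stage totals are conserved", {
  d <- make_const_dataset(22)
  p <- conservative_params()
  frc <- build_forcing(d, p)
  init <- setNames(numeric(10), names(initial_state()))
  init[c("alb_E", "alb_L", "alb_P", "alb_A")] <- c(30, 20, 10, 5)
  init[c("pip_E", "pip_L", "pip_P", "pip_A")] <- c(40, 25, 15, 8)
  tr <- simulate_season(d, parameter_vector(0.01, 0.01, 0, 0, 0),
                        species_params = p, init = init, forcing = frc)
  tot <- rowSums(tr$states)
  expect_true(all(abs(tot - sum(init)) <= 1e-12 * sum(init)))
  # per species too
  alb <- rowSums(tr$states[, grep("^alb", colnames(tr$states))])
  expect_true(all(abs(alb - 65) <= 1e-12 * 65))
})

test_that("warm-year seasonality: pipiens adults peak before albopictus adults", {
  sim <- quick_sim(seed = 8, summer_mean = 25.5)
  tr <- sim$trajectory
  peak_pip <- tr$dates[which.max(adult_females(tr, "pipiens"))]
  peak_alb <- tr$dates[which.max(adult_females(tr, "albopictus"))]
  expect_lt(as.numeric(peak_pip), as.numeric(peak_alb))
})

test_that("simulation window must be covered by the temperature series", {
  sim <- quick_sim(seed = 9)
  d <- sim$dataset
  d$temperature <- d$temperature[d$temperature$date >= as.Date("2015-05-01"), ]
  expect_error(build_forcing(d), "does not cover")
})
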