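# SPD construction, gap detection, antiphase scoring, bookkeeping.

test_that("an SPD of one date equals that date's calibrated density", {
  cc <- identity_curve(0, 10000, sigma = 10)
  dates <- data.frame(c14_age_bp = 5000, c14_sd = 50)
  spd <- build_spd(dates, cc, step = 5)
  d <- calibrate_date(5000, 50, cc, step = 5)
  expect_equal(spd$grid, d$grid)
  expect_equal(spd$density, d$mass)
  expect_equal(spd$n_dates, 1)
})

test_that("SPDs are additive and conserve total mass", {
  cc <- identity_curve(0, 10000, sigma = 10)
  two <- data.frame(c14_age_bp = c(5000, 5000), c14_sd = c(50, 50))
  one <- data.frame(c14_age_bp = 5000, c14_sd = 50)
  expect_equal(build_spd(two, cc)$density, 2 * build_spd(one, cc)$density)

  withr::with_seed(3, {
    a <- data.frame(c14_age_bp = runif(12, 2000, 4000),
                    c14_sd = runif(12, 25, 60))
    b <- data.frame(c14_age_bp = runif(9, 5000, 8000),
                    c14_sd = runif(9, 25, 60))
  })
  sa <- build_spd(a, cc); sb <- build_spd(b, cc)
  su <- build_spd(rbind(a, b), cc)
  expect_equal(sum(sa$density), 12, tolerance = 1e-6)
  expect_equal(sum(su$density), 21, tolerance = 1e-6)
  # cell-wise additivity on the union grid
  at <- approx(sa$grid, sa$density, xout = su$grid, yleft = 0, yright = 0)$y
  bt <- approx(sb$grid, sb$density, xout = su$grid, yleft = 0, yright = 0)$y
  expect_equal(su$density, at + bt, tolerance = 1e-9)
  # normalized convention sums to 1
  expect_equal(sum(build_spd(a, cc, normalize = TRUE)$density), 1,
               tolerance = 1e-9)
  expect_error(build_spd(a[0, ], cc), "empty date list")
})

test_that("SPD mass concentrates where the dates were drawn", {
  curve <- sim_curve(c(0, 6000), wiggle_amp = 40, wiggle_period = 600,
                     seed = 21)
  sim <- sim_dates(data.frame(start = 3000, end = 1000, intensity = 1),
                   n_dates = 100, curve = curve, lab_sd = 30, seed = 22)
  spd <- build_spd(sim$dates, curve)
  inside <- spd$grid <= 3200 & spd$grid >= 800
  expect_gte(sum(spd$density[inside]) / sum(spd$density), 0.9)
})

test_that("gap detection ignores flat records and recovers a planted gap", {
  grid <- seq(0, 10000, by = 5)
  flat <- make_spd(grid, rep(1, length(grid)))
  expect_equal(nrow(detect_gaps(flat, 0.05, 200)), 0)

  dens <- rep(1, length(grid))
  dens[grid <= 6500 & grid >= 4500] <- 0
  gappy <- make_spd(grid, dens)
  g <- detect_gaps(gappy, 0.05, 200)
  expect_equal(nrow(g), 1)
  expect_lte(abs(g$start - 6500), 5)
  expect_lte(abs(g$end - 4500), 5)
  expect_equal(g$mean_density_inside, 0)

  # runs touching the window edge are record ends, not gaps
  edge <- rep(1, length(grid)); edge[grid >= 9000] <- 0
  expect_equal(nrow(detect_gaps(make_spd(grid, edge), 0.05, 200)), 0)

  expect_error(detect_gaps(flat, 0.05, min_duration = 5), "two grid steps")
  expect_error(detect_gaps(flat, 1.2, 200), "rel_threshold")
})

test_that("gaps are returned oldest-first", {
  grid <- seq(0, 12000, by = 5)
  dens <- rep(1, length(grid))
  dens[grid <= 3000 & grid >= 2500] <- 0
  dens[grid <= 9000 & grid >= 8000] <- 0
  g <- detect_gaps(make_spd(grid, dens), 0.05, 200)
  expect_equal(nrow(g), 2)
  expect_equal(g$start, c(9000, 3000))
})

test_that("antiphase scoring labels reversal and identity correctly", {
  grid <- seq(0, 5000, by = 5)
  dens <- 1 + sin(grid / 400)
  a <- make_spd(grid, dens, region = "A")
  b_same <- make_spd(grid, dens, region = "B")
  b_rev <- make_spd(grid, max(dens) - dens, region = "B")

  r1 <- antiphase_score(a, b_same, c(4000, 500))
  expect_equal(r1$score, 1)
  expect_equal(r1$label, "in-phase")

  r2 <- antiphase_score(a, b_rev, c(4000, 500))
  expect_equal(r2$score, -1)
  expect_equal(r2$label, "antiphased")

  expect_error(antiphase_score(a, b_same, c(1000, 500)), "1000 yr")
})

test_that("complementary synthetic occupations score as antiphased", {
  curve <- sim_curve(c(0, 11000), wiggle_amp = 40, wiggle_period = 600,
                     seed = 31)
  occ_a <- data.frame(start = c(9000, 4500), end = c(6500, 2000),
                      intensity = c(1, 1))
  # B is strongest exactly where A is absent, with weak background presence
  occ_b <- data.frame(start = c(9000, 6500, 4500), end = c(6500, 4500, 2000),
                      intensity = c(0.15, 1, 0.15))
  da <- sim_dates(occ_a, 150, curve, lab_sd = 30, seed = 32)$dates
  db <- sim_dates(occ_b, 150, curve, lab_sd = 30, seed = 33)$dates
  sa <- build_spd(da, curve, region = "A")
  sb <- build_spd(db, curve, region = "B")
  r <- antiphase_score(sa, sb, c(8500, 2500))
  expect_equal(r$label, "antiphased")
  expect_lt(r$score, -0.3)
})

test_that("percent change bookkeeping rounds to integer percent", {
  expect_equal(percent_change(488, 1042), 114L)
  expect_equal(percent_change(306, 816), 167L)
  expect_equal(percent_change(250, 250), 0L)
  expect_error(percent_change(0, 10), "old_count")
})
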