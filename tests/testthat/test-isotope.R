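# Proxy variability: adjacent-pair CVs, binning/flagging, growth rates,
# hiatus detection, proxy correlation.

test_that("adjacent CVs follow the two-point sd formula", {
  s <- isotope_series(c(100, 130), c(-5, -6))
  cv <- adjacent_cv(s)
  expect_equal(nrow(cv), 1)
  expect_equal(cv$cv, (1 / sqrt(2)) / 5.5, tolerance = 1e-9)
  expect_equal(cv$cv, 0.1286, tolerance = 5e-4)
  expect_equal(cv$mid_age, 115)
  expect_equal(cv$pair_span, 30)

  # identical pair -> zero
  expect_equal(adjacent_cv(isotope_series(c(1, 2), c(3, 3)))$cv, 0)

  # population convention is a uniform sqrt(2) rescale
  cvp <- adjacent_cv(s, "population")
  expect_equal(cvp$cv, cv$cv / sqrt(2))

  # mean-zero pair is undefined
  expect_error(adjacent_cv(isotope_series(c(1, 2), c(-1, 1))),
               "undefined CV")
})

test_that("CVs are invariant to scaling and sign of the proxy values", {
  withr::with_seed(14, {
    ages <- sort(runif(30, 0, 3000))
    vals <- rnorm(30, -4, 0.5)
  })
  base <- adjacent_cv(isotope_series(ages, vals))$cv
  for (c0 in c(-3, -1, 0.25, 7)) {
    expect_equal(adjacent_cv(isotope_series(ages, c0 * vals))$cv, base,
                 tolerance = 1e-12)
  }
})

test_that("n samples yield n-1 CVs and every CV lands in exactly one bin", {
  withr::with_seed(15, {
    ages <- sort(runif(120, 0, 6000))
    vals <- rnorm(120, -5, 0.3)
  })
  cvs <- adjacent_cv(isotope_series(ages, vals))
  expect_equal(nrow(cvs), 119)
  b <- bin_mean_cv(cvs, width = 250)
  expect_equal(sum(b$n_pairs), 119)
})

test_that("binned means, threshold and flags follow the stated conventions", {
  cvs <- make_cvs(c(100, 200, 300, 400), c(0.1, 0.3, 0.2, 0.4),
                  pair_span = rep(50, 4))
  b <- bin_mean_cv(cvs, width = 250, anchor = 0)
  expect_equal(b$mean_cv, c(0.2, 0.3))
  expect_equal(attr(b, "threshold"),
               attr(b, "mean") + attr(b, "sd"))

  # constant CVs: sd 0, strict inequality -> nothing flagged
  cc <- make_cvs(seq(50, 950, by = 100), rep(0.07, 10))
  bc <- bin_mean_cv(cc, width = 250)
  expect_equal(attr(bc, "sd"), 0)
  expect_false(any(bc$flagged))

  # threshold arithmetic is mean + one sd
  expect_equal(cv_threshold(0.019, 0.016), 0.035)

  # raw-statistics variant thresholds on the pairwise CVs themselves
  braw <- bin_mean_cv(cvs, width = 250, stats_on = "raw")
  expect_equal(attr(braw, "mean"), mean(cvs$cv))
  expect_equal(attr(braw, "sd"), sd(cvs$cv))

  expect_error(bin_mean_cv(cvs, width = 60), "twice the median pair span")
})

test_that("empty bins are absent rather than zero", {
  cvs <- make_cvs(c(100, 2100), c(0.1, 0.2), pair_span = c(20, 20))
  b <- bin_mean_cv(cvs, width = 250)
  expect_equal(nrow(b), 2)  # bins 0-250 and 2000-2250 only
  expect_equal(b$bin_start, c(0, 2000))
})

test_that("growth rates are depth increments over age increments", {
  s <- isotope_series(c(1000, 2000), c(0, 0) + 1, depth = c(0, 10))
  expect_equal(growth_rates(s)$rate, 0.01)

  # uniform deposition: constant rate
  ages <- seq(500, 5000, by = 300)
  su <- isotope_series(ages, rnorm(length(ages)), depth = 0.02 * (ages - 500))
  expect_equal(growth_rates(su)$rate, rep(0.02, length(ages) - 1))

  # 10x slowdown on the older half appears at the right pairs
  dep <- ifelse(ages <= 2600, 0.02 * (ages - 500),
                0.02 * 2100 + 0.002 * (ages - 2600))
  ss <- isotope_series(ages, rnorm(length(ages)), depth = dep)
  r <- growth_rates(ss)
  expect_equal(r$rate[r$age_older <= 2600], rep(0.02, 7))
  expect_equal(r$rate[r$age_younger >= 2600], rep(0.002, 8))

  expect_error(growth_rates(isotope_series(c(1, 2), c(1, 2))), "depth")
})

test_that("hiatus detection fires on long gaps and never on uniform spacing", {
  ages <- seq(1000, 3000, by = 20)
  s <- isotope_series(ages, rnorm(length(ages)))
  for (rf in c(1.5, 3, 10, 50)) {
    expect_equal(nrow(detect_hiatus(s, abs_min = 0.01, rel_factor = rf)), 0)
  }

  # one 2200-yr jump between 8100 and 5900
  ages2 <- c(seq(4000, 5900, by = 20), seq(8100, 10000, by = 20))
  h <- detect_hiatus(isotope_series(ages2, rnorm(length(ages2))))
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 8100)
  expect_equal(h$end, 5900)
  expect_equal(h$triggering_gap, 2200)
})

test_that("proxy correlation pairs by age and honours the window", {
  withr::with_seed(17, {
    ages <- sort(runif(60, 0, 9000))
    va <- rnorm(60)
  })
  a <- isotope_series(ages, va, proxy_name = "d18O")
  expect_equal(proxy_correlation(a, a)$statistic, 1)
  neg <- isotope_series(ages, -va, proxy_name = "d13C")
  expect_equal(proxy_correlation(a, neg)$statistic, -1)

  withr::with_seed(18, vb <- va + rnorm(60))
  b <- isotope_series(ages, vb, proxy_name = "d13C")
  win <- c(6000, 2000)
  r <- proxy_correlation(a, b, window = win)
  # oracle: mask then correlate on the full series
  keep <- ages <= 6000 & ages >= 2000
  expect_equal(r$statistic, spearman_rank(va[keep], vb[keep])$statistic)
  expect_equal(r$n_per_group, sum(keep))

  expect_error(proxy_correlation(a, b, window = c(100, 0)),
               "insufficient pairs")
})
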