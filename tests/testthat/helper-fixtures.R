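# Fixtures built in code: curves, densities and series used across tests.

identity_curve <- function(lo = 0, hi = 20000, sigma = 0) {
  cal_curve(c(lo, hi), c(lo, hi), c(sigma, sigma), name = "identity")
}

linear_curve <- function(slope, intercept = 0, lo = 0, hi = 20000,
                         sigma = 0) {
  theta <- c(lo, hi)
  cal_curve(theta, slope * theta + intercept, rep(sigma, 2),
            name = "linear")
}

# write a curve file in the IntCal .14c dialect (5 comma-separated columns,
# leading comment lines); returns the path
write_intcal_file <- function(cal_bp, c14_bp, sigma,
                              path = tempfile(fileext = ".14c")) {
  writeLines(c("# Synthetic curve in the .14c layout",
               "# CAL BP, 14C age, Error, Delta 14C, Sigma",
               sprintf("%g,%g,%g,0,0", cal_bp, c14_bp, sigma)), path)
  path
}

# hand-constructed SPD for gap/antiphase tests
make_spd <- function(grid, density, step = grid[2] - grid[1],
                     region = "manual", n_dates = 1) {
  structure(list(region = region, grid = grid, density = density,
                 n_dates = n_dates, step = step, normalized = FALSE),
            class = "spd_series")
}

# hand-constructed calibrated density
make_density <- function(grid, mass) {
  structure(list(grid = grid, mass = mass, step = grid[2] - grid[1],
                 c14_age = NA, c14_sd = NA), class = "cal_density")
}

# hand-constructed pairwise CV series
make_cvs <- function(mid_age, cv, pair_span = rep(20, length(cv))) {
  structure(data.frame(mid_age = mid_age, cv = cv, pair_span = pair_span),
            class = c("pairwise_cv", "data.frame"))
}

# two-sided exact Mann-Whitney p by brute-force enumeration of all
# C(n1+n2, n1) group labelings; deviation-from-center convention
brute_force_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  center <- n1 * (n - n1) / 2
  mean(abs(us - center) >= abs(u_obs - center) - 1e-12)
}
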