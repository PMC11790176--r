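# Radiocarbon calibration: curve handling, per-date calendar-age densities,
# and density summaries.
#
# Calendar convention throughout the package: cal BP = calendar years before
# AD 1950, positive and increasing into the past; "ka BP" = cal BP / 1000.

#' Construct a calibration curve object
#'
#' A calibration curve maps a calendar age theta (cal BP) to the expected
#' radiocarbon age mu(theta) (14C yr BP) with a curve error sigma(theta)
#' (14C yr). Knots are stored sorted by ascending calendar age and the curve
#' is evaluated by linear interpolation between them.
#'
#' @param cal_bp numeric vector of calendar ages (cal BP). Must be strictly
#'   increasing after sorting; duplicates are an error.
#' @param c14_bp numeric vector of curve radiocarbon ages (14C yr BP).
#' @param sigma numeric vector of curve errors (14C yr), all `>= 0`.
#' @param name text label for the curve.
#' @return An object of class `cal_curve`: a list with elements `name`,
#'   `cal_bp`, `c14_bp`, `sigma`.
#' @examples
#' cc <- cal_curve(c(0, 1000, 2000), c(0, 1000, 2000), c(10, 10, 10))
#' curve_at(cc, 500)
#' @export
cal_curve <- function(cal_bp, c14_bp, sigma, name = "custom") {
  if (length(cal_bp) < 2L) {
    stop("degenerate curve: need at least 2 knots, got ", length(cal_bp))
  }
  if (length(c14_bp) != length(cal_bp) || length(sigma) != length(cal_bp)) {
    stop("cal_bp, c14_bp and sigma must have equal length")
  }
  if (anyNA(cal_bp) || anyNA(c14_bp) || anyNA(sigma) ||
      any(!is.finite(c14_bp))) {
    stop("curve knots must be finite and non-missing")
  }
  if (anyDuplicated(cal_bp)) {
    stop("duplicate calendar ages in curve knots")
  }
  if (any(sigma < 0)) stop("curve error sigma must be >= 0")
  ord <- order(cal_bp)
  structure(
    list(name = name, cal_bp = as.numeric(cal_bp[ord]),
         c14_bp = as.numeric(c14_bp[ord]), sigma = as.numeric(sigma[ord])),
    class = "cal_curve"
  )
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("Calibration curve '%s': %d knots, %s-%s cal BP\n",
              x$name, length(x$cal_bp),
              format(min(x$cal_bp)), format(max(x$cal_bp))))
  invisible(x)
}

#' Load a calibration curve from a text file
#'
#' Two dialects are supported. `"intcal"` is the standard `.14c` layout:
#' comment lines starting with `#`, then comma-separated columns
#' `CAL BP, 14C age, Error, Delta14C, Sigma`, of which only the first three
#' are used. `"simple"` is a headerless CSV with columns
#' `cal_bp,c14_bp,sigma`.
#'
#' @param path path to the curve file.
#' @param dialect `"intcal"` or `"simple"`.
#' @param name curve label; defaults to the file name.
#' @return A [cal_curve] object.
#' @export
load_curve <- function(path, dialect = c("intcal", "simple"), name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("curve file not found: ", path)
  if (is.null(name)) name <- basename(path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (length(body) == 0L) {
    stop("degenerate curve: no data rows in ", path)
  }
  rows <- strsplit(body, ",")
  n_min <- if (dialect == "intcal") 3L else 3L
  parsed <- vapply(seq_along(rows), function(i) {
    r <- suppressWarnings(as.numeric(trimws(rows[[i]])))
    if (length(r) < n_min || anyNA(r[seq_len(n_min)])) {
      stop("malformed curve row at line ", which(keep)[i], " of ", path)
    }
    r[1:3]
  }, numeric(3))
  cal_curve(parsed[1, ], parsed[2, ], parsed[3, ], name = name)
}

#' Evaluate a calibration curve at a calendar age
#'
#' Linear interpolation between the bracketing knots; exact at knots.
#'
#' @param curve a [cal_curve].
#' @param theta calendar age(s), cal BP. Must lie within the knot range.
#' @return A list with numeric elements `mu` (curve 14C age) and `sigma`
#'   (curve error), each the same length as `theta`.
#' @export
curve_at <- function(curve, theta) {
  stopifnot(inherits(curve, "cal_curve"))
  rng <- range(curve$cal_bp)
  if (any(theta < rng[1] | theta > rng[2])) {
    stop(sprintf("calendar age outside curve support [%g, %g] cal BP",
                 rng[1], rng[2]))
  }
  mu <- stats::approx(curve$cal_bp, curve$c14_bp, xout = theta)$y
  sg <- stats::approx(curve$cal_bp, curve$sigma, xout = theta)$y
  list(mu = mu, sigma = sg)
}

#' Calibrate a single radiocarbon determination
#'
#' Standard probabilistic calibration: the unnormalized density at calendar
#' age theta is the Gaussian likelihood of the measured 14C age `c14_age`
#' with mean mu(theta) and standard deviation
#' `sqrt(c14_sd^2 + sigma_curve(theta)^2)`; the density is then normalized
#' to unit mass over the grid. Support is truncated where the standardized
#' residual exceeds 5 combined standard deviations.
#'
#' @param c14_age measured radiocarbon age, 14C yr BP.
#' @param c14_sd laboratory error, 14C yr, `> 0`.
#' @param curve a [cal_curve].
#' @param step grid step in calendar years (default 5).
#' @return An object of class `cal_density`: list with `grid` (ascending
#'   cal BP ages at constant step), `mass` (per-cell probability summing to
#'   1), `step`, `c14_age`, `c14_sd`.
#' @details If more than 1e-3 of the untruncated Gaussian mass would fall
#'   beyond the ends of the curve support, calibration aborts with a
#'   support-clipped error rather than silently renormalizing a clipped
#'   density.
#' @examples
#' cc <- cal_curve(c(0, 10000), c(0, 10000), c(0, 0))
#' d <- calibrate_date(5000, 50, cc, step = 1)
#' summarize_density(d)$median
#' @export
calibrate_date <- function(c14_age, c14_sd, curve, step = 5) {
  stopifnot(inherits(curve, "cal_curve"))
  if (!is.finite(c14_age)) stop("c14_age must be finite")
  if (!is.finite(c14_sd) || c14_sd <= 0) stop("c14_sd must be > 0")
  if (step <= 0) stop("grid step must be > 0")

  rng <- range(curve$cal_bp)
  # mass escaping beyond either end of the curve support, estimated from the
  # Gaussian likelihood at the endpoint curve values
  ends <- curve_at(curve, rng)
  sd_ends <- sqrt(c14_sd^2 + ends$sigma^2)
  mu_lo <- ends$mu[1]; mu_hi <- ends$mu[2]
  if (mu_lo > mu_hi) { tmp <- mu_lo; mu_lo <- mu_hi; mu_hi <- tmp
                       sd_ends <- rev(sd_ends) }
  out_mass <- stats::pnorm(mu_lo, mean = c14_age, sd = sd_ends[1]) +
    stats::pnorm(mu_hi, mean = c14_age, sd = sd_ends[2], lower.tail = FALSE)
  if (out_mass > 1e-3) {
    stop(sprintf(paste0("support clipped: %.4f of the probability mass of ",
                        "%g +/- %g falls outside curve '%s'"),
                 out_mass, c14_age, c14_sd, curve$name))
  }

  # grid aligned to multiples of step so that densities from a common curve
  # can be summed cell-by-cell
  grid <- seq(ceiling(rng[1] / step) * step, floor(rng[2] / step) * step,
              by = step)
  cv <- curve_at(curve, grid)
  comb_sd <- sqrt(c14_sd^2 + cv$sigma^2)
  z <- (c14_age - cv$mu) / comb_sd
  keep <- abs(z) <= 5
  if (!any(keep)) {
    stop("no grid cell within 5 combined sigmas; check date against curve")
  }
  idx <- range(which(keep))
  grid <- grid[idx[1]:idx[2]]
  dens <- stats::dnorm(c14_age, mean = cv$mu[idx[1]:idx[2]],
                       sd = comb_sd[idx[1]:idx[2]])
  mass <- dens / sum(dens)
  structure(list(grid = grid, mass = mass, step = step,
                 c14_age = c14_age, c14_sd = c14_sd),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  s <- summarize_density(x)
  cat(sprintf(
    "Calibrated density for %g +/- %g 14C BP: median %g cal BP, 95%% [%g, %g]\n",
    x$c14_age, x$c14_sd, s$median, s$interval_95[1], s$interval_95[2]))
  invisible(x)
}

#' Summarize a calibrated density
#'
#' @param d a `cal_density` from [calibrate_date()].
#' @return List with `median` (smallest grid age whose cumulative mass
#'   strictly exceeds 0.5; a cell bringing the total to exactly one half
#'   leaves the median at the next cell) and `interval_95` (outer envelope
#'   `c(lo, hi)` in cal BP of the highest-density set of grid cells
#'   covering at least 0.95 mass).
#' @export
summarize_density <- function(d) {
  stopifnot(inherits(d, "cal_density"))
  cum <- cumsum(d$mass)
  med <- d$grid[which(cum - 0.5 > 1e-9)[1]]
  ord <- order(d$mass, decreasing = TRUE)
  take <- ord[seq_len(which(cumsum(d$mass[ord]) >= 0.95)[1])]
  list(median = med, interval_95 = range(d$grid[take]))
}

#' Weighted mean age of a calibrated density
#'
#' @param d a `cal_density`.
#' @return Mean calendar age (cal BP), `sum(grid * mass)`.
#' @export
density_mean <- function(d) {
  stopifnot(inherits(d, "cal_density"))
  sum(d$grid * d$mass)
}

#' Standard deviation of a calibrated density
#'
#' @param d a `cal_density`.
#' @return Standard deviation in calendar years.
#' @export
density_sd <- function(d) {
  stopifnot(inherits(d, "cal_density"))
  m <- sum(d$grid * d$mass)
  sqrt(sum((d$grid - m)^2 * d$mass))
}
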