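# Synthetic-data generators. Every pipeline input can be simulated with the
# statistical structure the analysis assumes: date sets drawn from
# piecewise-constant occupation intensities mapped through a wiggly but
# monotone calibration curve with lab error; isotope series with AR(1)
# noise and epoch-wise variance inflation; depth-age series with
# depositional hiatuses. Generators are deterministic under a fixed seed
# and return "truth" sidecars so downstream detectors can be scored.

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Simulate a wiggly but monotone calibration curve
#'
#' `mu(theta) = theta + w(theta)` where `w` is a smooth seeded perturbation
#' built from three sinusoids of periods `wiggle_period`, `wiggle_period/2`
#' and `wiggle_period/3` with random phases, scaled so
#' `max |w| <= wiggle_amp`. If the draw breaks strict monotonicity the
#' amplitude is damped (factor 0.7) and the curve regenerated, with a
#' warning. Curve error is constant.
#'
#' @param span `c(older, younger)` or `c(younger, older)` cal BP; must span
#'   at least 1000 yr.
#' @param wiggle_amp maximum perturbation, 14C yr.
#' @param wiggle_period dominant wiggle period, yr.
#' @param sigma constant curve error, 14C yr.
#' @param seed integer seed (NULL to use the current RNG state).
#' @param knot_step knot spacing, yr (default 5).
#' @return A [cal_curve].
#' @export
sim_curve <- function(span, wiggle_amp = 50, wiggle_period = 500,
                      sigma = 10, seed = NULL, knot_step = 5) {
  lo <- min(span); hi <- max(span)
  if (hi - lo < 1000) stop("curve span must be at least 1000 yr")
  theta <- seq(lo, hi, by = knot_step)
  if (wiggle_amp == 0) {
    return(cal_curve(theta, theta, rep(sigma, length(theta)),
                     name = "synthetic-identity"))
  }
  with_optional_seed(seed, {
    amp <- wiggle_amp
    repeat {
      phases <- stats::runif(3, 0, 2 * pi)
      w <- 0.6 * sin(2 * pi * theta / wiggle_period + phases[1]) +
        0.3 * sin(4 * pi * theta / wiggle_period + phases[2]) +
        0.1 * sin(6 * pi * theta / wiggle_period + phases[3])
      w <- amp * w / max(abs(w))
      mu <- theta + w
      if (all(diff(mu) > 0)) break
      amp <- amp * 0.7
    }
    if (amp < wiggle_amp) {
      warning("wiggle amplitude ", wiggle_amp,
              " breaks monotonicity; damped to ", amp)
    }
    cal_curve(theta, mu, rep(sigma, length(theta)), name = "synthetic-wiggly")
  })
}

#' Simulate radiocarbon determinations from an occupation model
#'
#' True calendar ages are drawn proportionally to a piecewise-constant
#' occupation intensity (uniform within each phase, phases weighted by
#' `intensity * duration`), mapped through the curve mean `mu(theta)`, and
#' perturbed by Gaussian lab error. The true calendar ages are returned in
#' a `truth` sidecar for oracle testing.
#'
#' @param phases `data.frame` with columns `start` (older bound), `end`
#'   (younger bound), `intensity` (relative deposition rate `>= 0`); phases
#'   must not overlap and at least one must have positive intensity.
#' @param n_dates number of determinations to draw (`> 0`).
#' @param curve a [cal_curve] whose support contains every phase.
#' @param lab_sd lab error in 14C yr: a scalar, or `c(lo, hi)` for per-date
#'   uniform draws.
#' @param seed integer seed.
#' @param region region label written on the dates.
#' @return List with `dates` (`data.frame` in the [read_dates()] layout)
#'   and `truth` (`data.frame` with `cal_bp`, the true calendar ages, and
#'   `phase`, the generating phase index).
#' @export
sim_dates <- function(phases, n_dates, curve, lab_sd = 40, seed = NULL,
                      region = "synthetic") {
  stopifnot(inherits(curve, "cal_curve"))
  if (n_dates <= 0) stop("empty input: n_dates must be > 0")
  if (!all(c("start", "end", "intensity") %in% names(phases))) {
    stop("phases needs columns start, end, intensity")
  }
  if (any(phases$intensity < 0) || all(phases$intensity == 0)) {
    stop("at least one phase must have positive intensity, none negative")
  }
  if (any(phases$start <= phases$end)) {
    stop("each phase needs start (older) > end (younger)")
  }
  ord <- order(phases$start)
  p <- phases[ord, , drop = FALSE]
  if (nrow(p) > 1L && any(p$start[-nrow(p)] > p$end[-1])) {
    stop("phases must not overlap")
  }
  rng <- range(curve$cal_bp)
  if (min(p$end) < rng[1] || max(p$start) > rng[2]) {
    stop("phases must lie within the curve support")
  }
  with_optional_seed(seed, {
    wt <- p$intensity * (p$start - p$end)
    ph <- sample.int(nrow(p), n_dates, replace = TRUE, prob = wt)
    theta <- stats::runif(n_dates, min = p$end[ph], max = p$start[ph])
    mu <- curve_at(curve, theta)$mu
    sd_i <- if (length(lab_sd) == 2L) {
      stats::runif(n_dates, lab_sd[1], lab_sd[2])
    } else rep(lab_sd, n_dates)
    y <- stats::rnorm(n_dates, mean = mu, sd = sd_i)
    list(
      dates = data.frame(
        lab_id = sprintf("SIM-%04d", seq_len(n_dates)),
        c14_age_bp = y, c14_sd = sd_i,
        site = sprintf("site%02d", ph), region = region,
        stringsAsFactors = FALSE),
      truth = data.frame(cal_bp = theta, phase = ord[ph]))
  })
}

#' Simulate an isotope proxy series with variance-regime epochs
#'
#' AR(1) residuals with marginal standard deviation `base_sd` times the
#' active epoch multiplier are added to `mean_level`. Sample ages are
#' irregular: successive spacings are `spacing_mean` perturbed by a uniform
#' jitter. The sidecar records the epoch membership of every sample.
#'
#' @param span `c(older, younger)` cal BP (any order).
#' @param base_sd baseline residual standard deviation, per mil.
#' @param epochs optional `data.frame` with `start` (older), `end`
#'   (younger), `sd_multiplier` (`> 0`); epochs must lie within the span.
#' @param ar_coefficient lag-1 autocorrelation `rho` in `[0, 1)`.
#' @param mean_level series mean, per mil.
#' @param spacing_mean mean sample spacing, yr.
#' @param spacing_jitter half-width of the uniform spacing jitter, yr.
#' @param proxy_name proxy label.
#' @param seed integer seed.
#' @return An [isotope_series] with an extra attribute `truth`: a
#'   `data.frame` with `age` and `epoch` (0 for background, otherwise the
#'   epoch row index).
#' @export
sim_isotope <- function(span, base_sd = 0.15, epochs = NULL,
                        ar_coefficient = 0.5, mean_level = -5,
                        spacing_mean = 20, spacing_jitter = 10,
                        proxy_name = "d18O", seed = NULL) {
  lo <- min(span); hi <- max(span)
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    stop("ar_coefficient must be in [0, 1)")
  }
  if (!is.null(epochs)) {
    if (any(epochs$sd_multiplier <= 0)) stop("sd multipliers must be > 0")
    if (any(epochs$start > hi) || any(epochs$end < lo)) {
      stop("epochs must lie within the span")
    }
  }
  with_optional_seed(seed, {
    n_guess <- ceiling((hi - lo) / max(spacing_mean - spacing_jitter, 1)) + 2L
    sp <- pmax(spacing_mean +
                 stats::runif(n_guess, -spacing_jitter, spacing_jitter), 1)
    ages <- lo + cumsum(sp)
    ages <- c(lo, ages[ages <= hi])
    n <- length(ages)
    epoch_of <- integer(n)
    mult <- rep(1, n)
    if (!is.null(epochs)) {
      for (k in seq_len(nrow(epochs))) {
        inside <- ages <= epochs$start[k] & ages >= epochs$end[k]
        epoch_of[inside] <- k
        mult[inside] <- epochs$sd_multiplier[k]
      }
    }
    rho <- ar_coefficient
    # iterate oldest -> youngest so the AR memory runs forward in time
    e <- numeric(n)
    sd_marg <- base_sd * mult
    e[n] <- stats::rnorm(1, 0, sd_marg[n])
    if (n > 1) {
      innov <- stats::rnorm(n - 1)
      for (i in (n - 1):1) {
        e[i] <- rho * e[i + 1] + innov[n - i] * sd_marg[i] * sqrt(1 - rho^2)
      }
    }
    s <- isotope_series(ages, mean_level + e, proxy_name = proxy_name)
    attr(s, "truth") <- data.frame(age = ages, epoch = epoch_of)
    s
  })
}

#' Simulate a depth-age series with growth regimes and hiatuses
#'
#' Deposition proceeds at a constant rate within each regime and stops
#' inside hiatus intervals; no samples fall inside a hiatus. Depth is
#' measured from the top (youngest covered age) and integrates the rate
#' over depositional time.
#'
#' @param n number of samples.
#' @param rate_regimes `data.frame` with `start` (older), `end` (younger),
#'   `rate` (mm/yr, `>= 0`).
#' @param hiatuses optional `data.frame` with `start`, `end` (cal BP);
#'   must not overlap any regime.
#' @param jitter_frac jitter of sample ages within a regime, as a fraction
#'   of the mean spacing (default 0.3).
#' @param seed integer seed.
#' @return An [isotope_series] with `depth` (mm) and a dummy proxy value;
#'   attribute `truth` lists the planted hiatuses and regimes.
#' @export
sim_depth_age <- function(n, rate_regimes, hiatuses = NULL,
                          jitter_frac = 0.3, seed = NULL) {
  if (!all(c("start", "end", "rate") %in% names(rate_regimes))) {
    stop("rate_regimes needs columns start, end, rate")
  }
  if (any(rate_regimes$rate < 0)) stop("rates must be >= 0")
  reg <- rate_regimes[order(-rate_regimes$start), , drop = FALSE]
  if (!is.null(hiatuses) && nrow(hiatuses) > 0L) {
    for (k in seq_len(nrow(hiatuses))) {
      ov <- pmin(reg$start, hiatuses$start[k]) - pmax(reg$end, hiatuses$end[k])
      if (any(ov > 0)) stop("config error: hiatus overlaps a growth regime")
    }
  }
  with_optional_seed(seed, {
    dur <- reg$start - reg$end
    n_per <- pmax(1L, round(n * dur / sum(dur)))
    ages <- unlist(lapply(seq_len(nrow(reg)), function(k) {
      m <- n_per[k]
      base <- seq(reg$end[k], reg$start[k], length.out = m + 2L)[2:(m + 1L)]
      jit <- (dur[k] / (m + 1)) * jitter_frac
      sort(base + stats::runif(m, -jit, jit))
    }))
    ages <- sort(unique(ages))
    # depth from top: integral of rate from the youngest covered age
    young <- min(reg$end)
    depth_at <- function(a) {
      sum(pmax(0, pmin(a, reg$start) - pmax(young, reg$end)) * reg$rate)
    }
    depth <- vapply(ages, depth_at, 0)
    s <- isotope_series(ages, stats::rnorm(length(ages)), depth = depth,
                        proxy_name = "synthetic")
    attr(s, "truth") <- list(hiatuses = hiatuses, regimes = reg)
    s
  })
}
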