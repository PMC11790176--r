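# Summed probability distributions, occupation-gap detection, and
# antiphase scoring between regional SPDs.

#' Build a summed probability distribution (SPD)
#'
#' Calibrates every determination in `dates` and sums the per-date calendar
#' densities cell by cell. The unnormalized SPD carries total mass equal to
#' the number of dates; with `normalize = TRUE` it is divided by that count
#' so the total mass is 1.
#'
#' @param dates `data.frame` with columns `c14_age_bp` and `c14_sd` (as
#'   returned by [read_dates()]).
#' @param curve a [cal_curve].
#' @param step grid step, calendar years.
#' @param normalize divide by the number of dates (default FALSE).
#' @param region label stored on the result.
#' @return Object of class `spd_series`: list with `region`, `grid`
#'   (ascending cal BP, constant step), `density`, `n_dates`, `step`,
#'   `normalized`.
#' @export
build_spd <- function(dates, curve, step = 5, normalize = FALSE,
                      region = "all") {
  if (is.null(dates) || nrow(dates) == 0L) {
    stop("empty date list: at least one determination is required")
  }
  stopifnot(inherits(curve, "cal_curve"))
  dens <- lapply(seq_len(nrow(dates)), function(i) {
    calibrate_date(dates$c14_age_bp[i], dates$c14_sd[i], curve, step = step)
  })
  lo <- min(vapply(dens, function(d) d$grid[1], 0))
  hi <- max(vapply(dens, function(d) d$grid[length(d$grid)], 0))
  grid <- seq(lo, hi, by = step)
  total <- numeric(length(grid))
  for (d in dens) {
    i0 <- round((d$grid[1] - lo) / step) + 1L
    idx <- i0:(i0 + length(d$grid) - 1L)
    total[idx] <- total[idx] + d$mass
  }
  n <- nrow(dates)
  structure(list(region = region, grid = grid,
                 density = if (normalize) total / n else total,
                 n_dates = n, step = step, normalized = normalize),
            class = "spd_series")
}

#' @export
print.spd_series <- function(x, ...) {
  cat(sprintf("SPD '%s': %d dates, %s-%s cal BP at %g yr step%s\n",
              x$region, x$n_dates, format(min(x$grid)), format(max(x$grid)),
              x$step, if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Detect occupation gaps in an SPD
#'
#' A gap is a maximal run of grid cells whose density falls below
#' `rel_threshold` times the mean cell density over the analysis window,
#' lasting at least `min_duration` years. This operationalizes statements
#' of the form "total absence of ages between X and Y ka BP". A gap must be
#' bracketed by occupation on both sides: runs that touch either edge of
#' the analysis window (after clipping to the SPD grid) are censored record
#' ends, not gaps, and are not reported.
#'
#' @param spd an `spd_series`.
#' @param rel_threshold fraction of the window mean density, in `[0, 1)`.
#' @param min_duration minimum gap duration in years (must be at least two
#'   grid steps).
#' @param window analysis window `c(older, younger)` cal BP; default
#'   `c(15000, 0)`. Clipped to the SPD grid.
#' @return `data.frame` with one row per gap, oldest first: `start` (older
#'   bound), `end` (younger bound), `duration`, `mean_density_inside`,
#'   `threshold_used`.
#' @export
detect_gaps <- function(spd, rel_threshold = 0.05, min_duration = 200,
                        window = c(15000, 0)) {
  stopifnot(inherits(spd, "spd_series"))
  if (rel_threshold < 0 || rel_threshold >= 1) {
    stop("rel_threshold must be in [0, 1)")
  }
  if (min_duration < 2 * spd$step) {
    stop("min_duration must be at least two grid steps (",
         2 * spd$step, " yr)")
  }
  w_old <- max(window); w_yng <- min(window)
  sel <- spd$grid <= w_old & spd$grid >= w_yng
  if (!any(sel)) stop("analysis window does not intersect the SPD grid")
  g <- spd$grid[sel]
  d <- spd$density[sel]
  thr <- rel_threshold * mean(d)
  below <- d < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i <- starts[k]; j <- ends[k]
    if (i == 1L || j == length(g)) next  # record end, not a bracketed gap
    dur <- g[j] - g[i]
    if (dur < min_duration) next
    out[[length(out) + 1L]] <- data.frame(
      start = g[j], end = g[i], duration = dur,
      mean_density_inside = mean(d[i:j]), threshold_used = thr)
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0),
                      mean_density_inside = numeric(0),
                      threshold_used = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(-res$start), , drop = FALSE]
}

#' Antiphase score between two regional SPDs
#'
#' Resamples both SPDs onto a common grid over the window and computes the
#' Spearman rank correlation of the two density vectors. Scores at or below
#' -0.3 are labelled `"antiphased"`, at or above 0.3 `"in-phase"`, otherwise
#' `"indeterminate"`. The labels are descriptive conventions, not
#' significance claims.
#'
#' @param a,b `spd_series` objects.
#' @param window `c(older, younger)` cal BP; must span at least 1000 yr and
#'   lie within both grids.
#' @return List with `region_a`, `region_b`, `window`, `score`, `label`,
#'   and the underlying `test` ([spearman_rank()] result).
#' @export
antiphase_score <- function(a, b, window) {
  stopifnot(inherits(a, "spd_series"), inherits(b, "spd_series"))
  w_old <- max(window); w_yng <- min(window)
  if (w_old - w_yng < 1000) stop("antiphase window must span at least 1000 yr")
  for (s in list(a, b)) {
    if (w_yng < min(s$grid) || w_old > max(s$grid)) {
      stop("window not contained in SPD grid for region '", s$region, "'")
    }
  }
  step <- min(a$step, b$step)
  g <- seq(w_yng, w_old, by = step)
  da <- stats::approx(a$grid, a$density, xout = g)$y
  db <- stats::approx(b$grid, b$density, xout = g)$y
  test <- spearman_rank(da, db)
  score <- test$statistic
  label <- if (score <= -0.3) "antiphased" else
    if (score >= 0.3) "in-phase" else "indeterminate"
  list(region_a = a$region, region_b = b$region,
       window = c(w_old, w_yng), score = score, label = label, test = test)
}

#' Percentage change between two counts
#'
#' Database growth bookkeeping: `100 * (new - old) / old`, rounded to the
#' nearest integer percent.
#'
#' @param old_count,new_count non-negative counts; `old_count > 0`.
#' @return Integer percent.
#' @examples
#' percent_change(488, 1042)  # 114
#' @export
percent_change <- function(old_count, new_count) {
  if (old_count <= 0) stop("old_count must be > 0")
  as.integer(round(100 * (new_count - old_count) / old_count))
}
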