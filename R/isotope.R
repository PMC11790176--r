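# Rapid-variability detection on proxy series: adjacent-pair coefficients
# of variation, binned mean CVs with extreme-epoch flagging, speleothem
# growth rates and depositional hiatus detection.

#' Adjacent-pair coefficients of variation
#'
#' For every pair of adjacent samples `(x1, x2)` of an age-ordered proxy
#' series, computes `cv = sd / |mean|` where `mean = (x1 + x2) / 2` and, by
#' default, `sd = |x1 - x2| / sqrt(2)` (the two-point sample standard
#' deviation, n-1 denominator). With `sd_convention = "population"` the
#' divisor is 2 instead, a uniform `sqrt(2)` rescaling that leaves the
#' extreme-epoch flagging of [bin_mean_cv()] unchanged.
#'
#' Using `|mean|` makes negative delta-18O series yield positive CVs; a pair
#' whose mean is zero (values straddling or touching zero symmetrically)
#' has no defined CV and raises an error naming the pair.
#'
#' @param s an [isotope_series].
#' @param sd_convention `"sample"` (default, n-1) or `"population"` (n).
#' @return `data.frame` of class `pairwise_cv` with one row per adjacent
#'   pair (`n - 1` rows): `mid_age` (mean of the two ages), `cv`,
#'   `pair_span` (years between the two samples).
#' @export
adjacent_cv <- function(s, sd_convention = c("sample", "population")) {
  stopifnot(inherits(s, "isotope_series"))
  sd_convention <- match.arg(sd_convention)
  x1 <- s$value[-nrow(s)]
  x2 <- s$value[-1]
  m <- (x1 + x2) / 2
  if (any(m == 0)) {
    i <- which(m == 0)[1]
    stop(sprintf("undefined CV: pair %d (values %g, %g) has mean 0",
                 i, x1[i], x2[i]))
  }
  divisor <- if (sd_convention == "sample") sqrt(2) else 2
  cv <- (abs(x2 - x1) / divisor) / abs(m)
  out <- data.frame(mid_age = (s$age[-nrow(s)] + s$age[-1]) / 2,
                    cv = cv,
                    pair_span = diff(s$age))
  attr(out, "proxy_name") <- attr(s, "proxy_name")
  attr(out, "sd_convention") <- sd_convention
  class(out) <- c("pairwise_cv", "data.frame")
  out
}

#' Extreme-variability threshold
#'
#' The flagging threshold is the mean plus one standard deviation of the
#' CV series under consideration.
#'
#' @param mean_cv mean of the CVs.
#' @param sd_cv standard deviation of the CVs.
#' @return `mean_cv + sd_cv`.
#' @examples
#' cv_threshold(0.019, 0.016)  # 0.035
#' @export
cv_threshold <- function(mean_cv, sd_cv) mean_cv + sd_cv

#' Bin adjacent-pair CVs into fixed time slots and flag extreme epochs
#'
#' Assigns each pairwise CV to a bin `[anchor + k w, anchor + (k+1) w)` by
#' its midpoint age and averages within bins. Bins containing no pairs are
#' reported as missing, not zero. The flagging threshold is
#' `mean + 1 sd`, computed either over the nonempty bin means
#' (`stats_on = "binned"`, the default) or over the raw pairwise CVs
#' (`stats_on = "raw"`); a bin is flagged when its mean CV strictly exceeds
#' the threshold.
#'
#' @param cvs a `pairwise_cv` from [adjacent_cv()].
#' @param width bin width in years (commonly 250 or 120).
#' @param anchor bin origin, cal BP (default 0).
#' @param stats_on `"binned"` or `"raw"`: which series the mean and sd of
#'   the threshold are computed on.
#' @return `data.frame` of class `binned_cv` with one row per nonempty bin:
#'   `bin_start` (younger edge), `bin_end` (older edge), `mid_age`,
#'   `mean_cv`, `n_pairs`, `flagged`. Attributes `mean`, `sd`, `threshold`,
#'   `width`, `anchor`, `stats_on`.
#' @export
bin_mean_cv <- function(cvs, width = 250, anchor = 0,
                        stats_on = c("binned", "raw")) {
  stopifnot(inherits(cvs, "pairwise_cv"))
  stats_on <- match.arg(stats_on)
  if (width < 2 * stats::median(cvs$pair_span)) {
    stop("bin width must be at least twice the median pair span")
  }
  if (nrow(cvs) == 0L) stop("empty input: no pairwise CVs to bin")
  k <- floor((cvs$mid_age - anchor) / width)
  means <- tapply(cvs$cv, k, mean)
  counts <- tapply(cvs$cv, k, length)
  kk <- as.numeric(names(means))
  m <- if (stats_on == "binned") mean(means) else mean(cvs$cv)
  s <- if (stats_on == "binned") stats::sd(means) else stats::sd(cvs$cv)
  if (is.na(s)) s <- 0  # single bin / single pair
  tau <- cv_threshold(m, s)
  out <- data.frame(bin_start = anchor + kk * width,
                    bin_end = anchor + (kk + 1) * width,
                    mid_age = anchor + (kk + 0.5) * width,
                    mean_cv = as.numeric(means),
                    n_pairs = as.integer(counts),
                    flagged = as.numeric(means) > tau)
  out <- out[order(out$mid_age), , drop = FALSE]
  attr(out, "mean") <- m
  attr(out, "sd") <- s
  attr(out, "threshold") <- tau
  attr(out, "width") <- width
  attr(out, "anchor") <- anchor
  attr(out, "stats_on") <- stats_on
  class(out) <- c("binned_cv", "data.frame")
  out
}

#' Speleothem growth rates
#'
#' Rate per adjacent sample pair: `|depth increment| / age increment`
#' (mm per year). Requires a depth column.
#'
#' @param s an [isotope_series] with a `depth` column (mm from top).
#' @return `data.frame` with one row per adjacent pair: `age_older`,
#'   `age_younger`, `mid_age`, `rate` (mm/yr).
#' @export
growth_rates <- function(s) {
  stopifnot(inherits(s, "isotope_series"))
  if (is.null(s$depth)) stop("depth column required for growth rates")
  d_age <- diff(s$age)
  if (any(d_age == 0)) stop("duplicate ages: growth rate undefined")
  data.frame(age_older = s$age[-1],
             age_younger = s$age[-nrow(s)],
             mid_age = (s$age[-1] + s$age[-nrow(s)]) / 2,
             rate = abs(diff(s$depth)) / d_age)
}

#' Detect depositional hiatuses from sample-age spacing
#'
#' An adjacent age gap is flagged as a hiatus when it exceeds
#' `max(abs_min, rel_factor * median spacing)`. The interval spans the two
#' bracketing sample ages. A uniformly spaced series never triggers for any
#' `rel_factor > 1`.
#'
#' @param s an [isotope_series] (>= 3 samples).
#' @param abs_min absolute minimum gap in years (default 500).
#' @param rel_factor multiple of the median spacing (default 10).
#' @return `data.frame` with one row per hiatus, oldest first: `start`
#'   (older bound), `end` (younger bound), `triggering_gap` (years).
#' @export
detect_hiatus <- function(s, abs_min = 500, rel_factor = 10) {
  stopifnot(inherits(s, "isotope_series"))
  if (nrow(s) < 3L) stop("need at least 3 samples")
  gaps <- diff(s$age)
  thr <- max(abs_min, rel_factor * stats::median(gaps))
  hit <- which(gaps > thr)
  out <- data.frame(start = s$age[hit + 1L], end = s$age[hit],
                    triggering_gap = gaps[hit])
  out[order(-out$start), , drop = FALSE]
}

#' Correlation between two proxies measured on the same samples
#'
#' Pairs the two series on shared sample identity (when both carry
#' `sample_id`) or on exact age equality, optionally restricts to a time
#' window, and delegates to [spearman_rank()].
#'
#' @param a,b [isotope_series] objects measured on the same points.
#' @param window optional `c(older, younger)` cal BP restriction.
#' @return A `rank_test` (`r_s`).
#' @export
proxy_correlation <- function(a, b, window = NULL) {
  stopifnot(inherits(a, "isotope_series"), inherits(b, "isotope_series"))
  if (!is.null(a$sample_id) && !is.null(b$sample_id)) {
    i <- match(a$sample_id, b$sample_id)
    keep <- !is.na(i)
    age <- a$age[keep]; va <- a$value[keep]; vb <- b$value[i[keep]]
  } else {
    i <- match(a$age, b$age)
    keep <- !is.na(i)
    age <- a$age[keep]; va <- a$value[keep]; vb <- b$value[i[keep]]
  }
  if (!is.null(window)) {
    sel <- age <= max(window) & age >= min(window)
    va <- va[sel]; vb <- vb[sel]
  }
  if (length(va) < 3L) {
    stop("insufficient pairs: fewer than 3 shared samples in window")
  }
  spearman_rank(va, vb)
}
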