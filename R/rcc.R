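# Rapid climate change (RCC) event catalogue and interval matching of
# demographic gaps / variability epochs against it.

#' Load an RCC event catalogue
#'
#' Without a path, loads the bundled catalogue of 28 published Holocene /
#' Late Glacial rapid climate change events (labelled calendar intervals in
#' ka BP, oldest the 14.9-13.9 ka Meltwater pulse 1A, youngest the Little
#' Ice Age). Point events ("ca. X ka") are stored with `start_ka == end_ka`.
#'
#' @param path optional CSV with columns `label,start_ka,end_ka,reference`.
#' @return `data.frame` of class `rcc_catalog` with columns `label`,
#'   `start_ka` (older bound), `end_ka` (younger bound), `reference`.
#' @export
load_rcc_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rcc_events.csv", package = "holodem",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    need <- c("label", "start_ka", "end_ka")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("catalogue missing column(s): ", paste(miss, collapse = ", "))
    }
    if (any(!is.finite(df$start_ka)) || any(!is.finite(df$end_ka))) {
      stop("malformed catalogue row: non-numeric age bound")
    }
    if (any(df$start_ka < df$end_ka) || any(df$end_ka < 0)) {
      stop("malformed catalogue row: require start_ka >= end_ka >= 0")
    }
  }
  if (is.null(df$reference)) df$reference <- NA_character_
  class(df) <- c("rcc_catalog", "data.frame")
  df
}

#' Match demographic intervals against an RCC catalogue
#'
#' An event matches an interval when the event's age range, widened by
#' `tolerance` on both sides, intersects it. Point events (`start == end`)
#' thereby become `[start + tolerance, start - tolerance]`. All matching
#' events are reported, sorted by decreasing overlap length; the verdict is
#' `"yes"` when at least one event matches, `"no"` otherwise ("unclear"
#' verdicts are a user annotation, not emitted by the matcher).
#'
#' @param intervals `data.frame` with columns `start` (older bound) and
#'   `end` (younger bound) in cal BP, for example from [detect_gaps()] or
#'   the flagged bins of [bin_mean_cv()] (use `bin_end`/`bin_start`).
#' @param catalog an `rcc_catalog` (ka BP; converted internally).
#' @param tolerance widening in ka (default 0.1); must be `>= 0`.
#' @param region label attached to each report.
#' @param evidence evidence string attached to each report (e.g.
#'   `"Age SPD depletion"` for gaps, `"Strong oscillation"` for flagged CV
#'   epochs).
#' @return List of match reports, one per interval, each a list with
#'   `region`, `interval` (`c(start, end)` cal BP), `evidence`, `matches`
#'   (`data.frame` of events with `overlap_yr`), `verdict`.
#' @export
match_intervals <- function(intervals, catalog, tolerance = 0.1,
                            region = "region", evidence = "Age SPD depletion") {
  stopifnot(inherits(catalog, "rcc_catalog"))
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (is.null(intervals) || nrow(intervals) == 0L) return(list())
  ev_start <- (catalog$start_ka + tolerance) * 1000
  ev_end <- (catalog$end_ka - tolerance) * 1000
  lapply(seq_len(nrow(intervals)), function(i) {
    g_start <- intervals$start[i]
    g_end <- intervals$end[i]
    # closed-interval intersection length (>= 0 means they touch/overlap)
    ov <- pmin(g_start, ev_start) - pmax(g_end, ev_end)
    hit <- which(ov >= 0)
    m <- catalog[hit, , drop = FALSE]
    m$overlap_yr <- pmax(ov[hit], 0)
    m <- m[order(-m$overlap_yr), , drop = FALSE]
    class(m) <- "data.frame"
    list(region = region,
         interval = c(start = g_start, end = g_end),
         evidence = evidence,
         matches = m,
         verdict = if (nrow(m) > 0) "yes" else "no")
  })
}

#' Tabulate match reports in the regional-summary layout
#'
#' One row per interval with columns `area_region`, `instability_age_ka`
#' ("older to younger"), `evidence` and `rcc_relation` ("Yes - <event
#' labels>" or "No").
#'
#' @param reports list of reports from [match_intervals()].
#' @return `data.frame`.
#' @export
build_region_table <- function(reports) {
  if (length(reports) == 0L) {
    return(data.frame(area_region = character(0),
                      instability_age_ka = character(0),
                      evidence = character(0),
                      rcc_relation = character(0)))
  }
  rows <- lapply(reports, function(r) {
    age <- if (r$interval["start"] == r$interval["end"]) {
      sprintf("ca. %.1f", r$interval["start"] / 1000)
    } else {
      sprintf("%.1f to %.1f", r$interval["start"] / 1000,
              r$interval["end"] / 1000)
    }
    rel <- if (r$verdict == "yes") {
      paste0("Yes - ", paste(r$matches$label, collapse = " + "))
    } else "No"
    data.frame(area_region = r$region, instability_age_ka = age,
               evidence = r$evidence, rcc_relation = rel)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
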