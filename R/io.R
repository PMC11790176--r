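# CSV input/output in the dialects the pipeline consumes.

#' Read a radiocarbon date database
#'
#' Expects a CSV with header
#' `lab_id,c14_age_bp,c14_sd,site,region,material,lat,lon`; the trailing
#' fields (`material`, `lat`, `lon`) are optional.
#'
#' @param path CSV file path.
#' @param region optional region label; if given, only matching rows are
#'   returned.
#' @return `data.frame` with at least `lab_id`, `c14_age_bp`, `c14_sd`,
#'   `site`, `region`.
#' @export
read_dates <- function(path, region = NULL) {
  if (!file.exists(path)) stop("dates file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lab_id", "c14_age_bp", "c14_sd")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("dates file missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(df$site)) df$site <- NA_character_
  if (is.null(df$region)) df$region <- NA_character_
  if (any(!is.finite(df$c14_age_bp))) stop("non-finite c14_age_bp in ", path)
  if (any(!is.finite(df$c14_sd) | df$c14_sd <= 0)) {
    stop("c14_sd must be finite and > 0 in ", path)
  }
  if (!is.null(region)) df <- df[df$region %in% region, , drop = FALSE]
  df
}

#' Construct an isotope proxy series
#'
#' An age-ordered series of proxy measurements (for example speleothem
#' delta-18O or delta-13C, in per mil), optionally with a depth column
#' (distance from the speleothem top, mm).
#'
#' @param age sample ages, cal BP years. Sorted ascending internally;
#'   duplicated ages are allowed only when `allow_ties = TRUE` (growth-rate
#'   computation requires distinct ages).
#' @param value proxy measurements, finite.
#' @param depth optional depths from top (mm), same length as `age`.
#' @param proxy_name text label, e.g. `"d18O"`.
#' @param sample_id optional sample identifiers (used to pair proxies
#'   measured on the same points).
#' @param allow_ties allow duplicated ages (default FALSE).
#' @return `data.frame` of class `isotope_series` with columns `age`,
#'   `value`, and optionally `depth`, `sample_id`; attribute `proxy_name`.
#' @export
isotope_series <- function(age, value, depth = NULL, proxy_name = "proxy",
                           sample_id = NULL, allow_ties = FALSE) {
  if (length(age) < 2L) stop("isotope series needs at least 2 samples")
  if (length(value) != length(age)) stop("age and value lengths differ")
  if (anyNA(age) || anyNA(value) || any(!is.finite(value))) {
    stop("ages and values must be finite and non-missing")
  }
  ord <- order(age)
  df <- data.frame(age = as.numeric(age[ord]), value = as.numeric(value[ord]))
  if (!allow_ties && anyDuplicated(df$age)) {
    stop("duplicated sample ages; pass allow_ties = TRUE to keep them")
  }
  if (!is.null(depth)) {
    if (length(depth) != length(age)) stop("depth length differs from age")
    df$depth <- as.numeric(depth[ord])
  }
  if (!is.null(sample_id)) df$sample_id <- sample_id[ord]
  attr(df, "proxy_name") <- proxy_name
  class(df) <- c("isotope_series", "data.frame")
  df
}

#' Read an isotope proxy series from CSV
#'
#' Expects columns `sample_id,age_cal_bp,d18O_permil,d13C_permil,depth_mm`;
#' either proxy column may be absent.
#'
#' @param path CSV file path.
#' @param proxy which proxy column to read: `"d18O"` or `"d13C"`.
#' @param age_units `"bp"` (cal BP years, default) or `"ka"` (thousands,
#'   converted to years).
#' @return An [isotope_series].
#' @export
read_isotope_series <- function(path, proxy = c("d18O", "d13C"),
                                age_units = c("bp", "ka")) {
  proxy <- match.arg(proxy)
  age_units <- match.arg(age_units)
  if (!file.exists(path)) stop("isotope file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  col <- paste0(proxy, "_permil")
  if (is.null(df[[col]])) stop("column ", col, " not present in ", path)
  if (is.null(df$age_cal_bp)) stop("column age_cal_bp not present in ", path)
  age <- df$age_cal_bp
  if (age_units == "ka") age <- age * 1000
  keep <- is.finite(df[[col]])
  isotope_series(age[keep], df[[col]][keep],
                 depth = if (!is.null(df$depth_mm)) df$depth_mm[keep],
                 sample_id = if (!is.null(df$sample_id)) df$sample_id[keep],
                 proxy_name = proxy)
}

# short non-cryptographic content hash used to stamp pipeline outputs
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
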