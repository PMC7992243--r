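#' @importFrom stats rbinom runif
#' @importFrom utils read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse timestamps from character EHR fields
#'
#' Accepts ISO-8601 date-times (`T` or space separator, optional seconds)
#' and bare dates; everything is interpreted as UTC.  Naive timestamps are
#' assumed UTC, which keeps window arithmetic free of DST artefacts.
#' Unparseable entries become `NA` so callers can reject those rows.
#'
#' @param x character vector.
#' @return POSIXct vector (UTC) with `NA` where parsing failed.
#' @keywords internal
parse_ts <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  for (f in fmts) {
    idx <- which(is.na(out) & !is.na(x))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], f, tz = "UTC"))
  }
  out
}

format_ts <- function(x) {
  ifelse(is.na(x), "", format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
}

parse_bool <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Age in completed years at a reference time
#' @keywords internal
age_at <- function(birth, at) {
  b <- as.POSIXlt(birth, tz = "UTC")
  a <- as.POSIXlt(at, tz = "UTC")
  age <- a$year - b$year
  not_reached <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  age - as.integer(not_reached)
}

#' Round half away from zero
#'
#' `round()` in R is banker's rounding (96.875 -> 96.8 at one decimal);
#' published diagnostic tables use conventional half-up rounding
#' (96.875 -> 96.9), so metric display goes through this helper.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

hours_diff <- function(a, b) as.numeric(difftime(a, b, units = "hours"))
mins_diff <- function(a, b) as.numeric(difftime(a, b, units = "mins"))
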