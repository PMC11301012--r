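#' @importFrom stats setNames
NULL

#' Round half away from zero
#'
#' Decimal rounding in which ties (.5) round up in absolute value, the
#' convention used in clinical report tables. Base \code{round()} rounds
#' half to even, which disagrees with printed survey percentages at ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to \code{digits} places.
#' @export
#' @examples
#' round_half_up(2.5, 0)   # 3, where round(2.5) is 2
#' round_half_up(41.666, 1)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Parse "YYYY-MM-DDTHH:MM[:SS]" (T or space separator) into calendar date and
# minutes since midnight (fractional if seconds present). Invalid entries
# become NA in both components.
parse_timestamp <- function(ts) {
  ts <- gsub(" ", "T", as.character(ts), fixed = TRUE)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}(:\\d{2})?$", ts)
  date <- as.Date(rep(NA_integer_, length(ts)), origin = "1970-01-01")
  minute <- rep(NA_real_, length(ts))
  if (any(ok)) {
    date[ok] <- as.Date(substr(ts[ok], 1, 10))
    hh <- as.numeric(substr(ts[ok], 12, 13))
    mm <- as.numeric(substr(ts[ok], 15, 16))
    ss <- ifelse(nchar(ts[ok]) >= 19, as.numeric(substr(ts[ok], 18, 19)), 0)
    bad <- hh > 23 | mm > 59 | ss > 59
    minute[ok] <- ifelse(bad, NA_real_, hh * 60 + mm + ss / 60)
    date[ok][bad] <- NA
  }
  list(date = date, minute = minute)
}

format_timestamp <- function(date, minute) {
  sprintf("%sT%02d:%02d", format(date, "%Y-%m-%d"),
          floor(minute / 60), floor(minute %% 60))
}

# Polynomial rolling hash of a string, reported as 8 hex digits; used for
# config fingerprints in run manifests (no cryptographic intent).
config_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
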