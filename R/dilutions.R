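#' Parse serum dilutions written as fractions
#'
#' Titers in serology are conventionally written as reciprocal fractions
#' ("1/8" means a dilution fraction of 0.125). `parse_dilution()` accepts
#' either that notation or plain decimals and returns the dilution fraction;
#' `dilution_label()` is its inverse, rendering a fraction as "1/k" whenever
#' the reciprocal is (numerically) a whole number.
#'
#' @param x Character or numeric vector. Strings may be "1/8"-style
#'   fractions or decimal numbers; `NA` and `"none"` map to `NA` (controls
#'   carry no dilution).
#' @return `parse_dilution()`: numeric vector of dilution fractions in
#'   (0, 1]. `dilution_label()`: character vector.
#' @examples
#' parse_dilution(c("1/4", "0.125", "none"))
#' dilution_label(c(0.25, 1/128, NA))
#' @export
parse_dilution <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  missing <- is.na(x) | x == "" | tolower(x) == "none"
  frac <- !missing & grepl("/", x, fixed = TRUE)
  if (any(frac)) {
    parts <- strsplit(x[frac], "/", fixed = TRUE)
    out[frac] <- vapply(parts, function(p) {
      as.numeric(p[[1]]) / as.numeric(p[[2]])
    }, numeric(1))
  }
  plain <- !missing & !frac
  out[plain] <- suppressWarnings(as.numeric(x[plain]))
  if (anyNA(out[plain])) {
    abort(paste0("Unparseable dilution value(s): ",
                 paste(unique(x[plain][is.na(out[plain])]), collapse = ", ")))
  }
  out
}

#' @rdname parse_dilution
#' @export
dilution_label <- function(x) {
  vapply(as.numeric(x), function(d) {
    if (is.na(d)) return("none")
    recip <- 1 / d
    if (abs(recip - round(recip)) < 1e-8) {
      paste0("1/", format(round(recip), scientific = FALSE))
    } else {
      format(d, digits = 6)
    }
  }, character(1))
}

#' Two-fold serial dilution series
#'
#' @param strongest Strongest (least dilute) serum dilution fraction,
#'   default 1/4.
#' @param n Number of two-fold steps, default 6 (1/4 down to 1/128).
#' @return Numeric vector of dilution fractions, strictly decreasing.
#' @examples
#' dilution_series()
#' @export
dilution_series <- function(strongest = 1 / 4, n = 6) {
  stopifnot(strongest > 0, strongest < 1, n >= 1)
  strongest / 2^(seq_len(n) - 1)
}
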