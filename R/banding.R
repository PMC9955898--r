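#' Numeric-to-linguistic banding tables
#'
#' A banding table translates a raw numeric evaluation into a linguistic
#' term: each row is an interval and the term it maps to. Intervals are
#' half-open `[lower, upper)` except the last, which is closed
#' `[lower, upper]`, so a value sitting exactly on an interior boundary goes
#' to the upper band. Intervals must be ordered and non-overlapping; gaps are
#' allowed but values falling in a gap (or outside the table altogether)
#' raise an error rather than being clamped — out-of-calibration inputs
#' should fail loudly.
#'
#' @param lower,upper Numeric vectors of interval bounds (equal length,
#'   increasing, `lower < upper`, `lower[i+1] >= upper[i]`).
#' @param term Character vector of linguistic terms, one per interval.
#' @return A tibble with columns `lower`, `upper`, `term`.
#' @examples
#' percentage_bands()
#' band_value(c(94.1, 86, 99.9, 95), percentage_bands())
#' @export
bands <- function(lower, upper, term) {
  lower <- as.numeric(lower); upper <- as.numeric(upper); term <- as.character(term)
  if (length(lower) < 1L || length(lower) != length(upper) || length(lower) != length(term)) {
    abort_input("lower, upper and term must be non-empty vectors of equal length.")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    abort_input("Each band needs finite lower < upper.")
  }
  if (length(lower) > 1L && any(lower[-1L] < upper[-length(upper)])) {
    abort_input("Bands must be ordered and non-overlapping (lower[i+1] >= upper[i]).")
  }
  tibble(lower = lower, upper = upper, term = term)
}

#' Default percentage bands
#'
#' The bundled banding for percentage-type performance criteria:
#' `[70, 80) -> L`, `[80, 90) -> M`, `[90, 95) -> H`, `[95, 100] -> VH`.
#'
#' @return A [bands()] tibble.
#' @export
percentage_bands <- function() {
  bands(c(70, 80, 90, 95), c(80, 90, 95, 100), c("L", "M", "H", "VH"))
}

#' Default processing-time bands
#'
#' Two-band split for a cost (min-aim) criterion measured in seconds:
#' `[0, 350) -> L`, `[350, 450] -> M`. This is the unique two-band split
#' consistent with all nine printed time labels of the bundled brain-tumor
#' fixture; fully user-overridable.
#'
#' @return A [bands()] tibble.
#' @export
time_bands <- function() {
  bands(c(0, 350), c(350, 450), c("L", "M"))
}

#' Map numeric values to linguistic terms through a banding table
#'
#' @param x Numeric vector of raw evaluations.
#' @param banding A [bands()] tibble.
#' @return Character vector of terms, one per value.
#' @export
band_value <- function(x, banding) {
  if (!is.data.frame(banding) || !all(c("lower", "upper", "term") %in% names(banding)) ||
      nrow(banding) < 1L) {
    abort_input("`banding` must be a non-empty bands() table.")
  }
  x <- as.numeric(x)
  nb <- nrow(banding)
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nb)) {
    hit <- if (i < nb) {
      x >= banding$lower[i] & x < banding$upper[i]
    } else {
      x >= banding$lower[i] & x <= banding$upper[i]
    }
    out[hit & is.na(out)] <- banding$term[i]
  }
  if (anyNA(out)) {
    bad <- x[is.na(out)]
    abort_input(paste0(
      "Value(s) outside all bands: ", paste(bad, collapse = ", "),
      ". Bands cover [", banding$lower[1L], ", ", banding$upper[nb], "]",
      if (nb > 1L) paste0(" with boundaries at ",
                          paste(banding$lower[-1L], collapse = ", ")) else "",
      "."))
  }
  out
}
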