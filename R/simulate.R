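#' Simulate a decision matrix with controlled structure
#'
#' Generates a seeded, reproducible decision matrix shaped like the bundled
#' brain-tumor classifier study: `n` alternatives scored on `k` criteria,
#' most max-aim "score" criteria on a percentage scale plus at least one
#' min-aim "cost" criterion, with linguistic terms derived from banding so
#' generated matrices are always label-consistent. Optional structure can
#' be planted for property testing: a weakly dominant alternative (at least
#' as good everywhere, strictly better somewhere — any monotone outranking
#' scheme must put it first) and/or a duplicated evaluation profile (which
#' must tie exactly downstream).
#'
#' @param n_alternatives Number of alternatives (>= 2; default 9).
#' @param n_criteria Number of criteria (>= 1; default 6).
#' @param seed Integer seed; identical seed and configuration give a
#'   byte-identical matrix.
#' @param prop_min Fraction of min-aim cost criteria (default 1/6, i.e. one
#'   cost criterion in the default configuration).
#' @param value_model `"percentage"` (default): scores drawn uniformly on
#'   \[70, 100\] (2 decimals) and costs on \[300, 450\] (integers, seconds),
#'   with terms derived through [percentage_bands()] / [time_bands()];
#'   `"linguistic"`: terms drawn from the scale, no raw values.
#' @param weight_model `"linguistic"` (terms drawn from the scale; default)
#'   or `"crisp"` (uniform on \[0.1, 1\], 2 decimals).
#' @param plant_dominant Plant a weakly dominant alternative named
#'   `"dominant"` (first row)?
#' @param plant_duplicate Make the last two alternatives (`"twin1"`,
#'   `"twin2"`) cell-identical?
#' @param scale A [linguistic_scale()].
#' @return A [decision_matrix()] with the seed stored in `attr(, "seed")`.
#' @examples
#' dm <- simulate_decision_matrix(seed = 42, plant_dominant = TRUE)
#' tidy(promethee_flows(dm))
#' @export
simulate_decision_matrix <- function(n_alternatives = 9, n_criteria = 6,
                                     seed = 1L, prop_min = 1 / 6,
                                     value_model = c("percentage", "linguistic"),
                                     weight_model = c("linguistic", "crisp"),
                                     plant_dominant = FALSE,
                                     plant_duplicate = FALSE,
                                     scale = default_scale()) {
  value_model <- match.arg(value_model)
  weight_model <- match.arg(weight_model)
  n <- as.integer(n_alternatives); k <- as.integer(n_criteria)
  if (is.na(n) || n < 2L) abort_input("`n_alternatives` must be >= 2.")
  if (is.na(k) || k < 1L) abort_input("`n_criteria` must be >= 1.")
  if (plant_dominant && plant_duplicate && n < 3L) {
    abort_input("Planting both a dominant alternative and a duplicate pair needs >= 3 alternatives.")
  }
  if (!is.numeric(prop_min) || prop_min < 0 || prop_min >= 1) {
    abort_input("`prop_min` must be in [0, 1).")
  }
  n_min <- min(k - 1L, max(if (prop_min > 0) 1L else 0L, round(prop_min * k)))
  if (k == 1L) n_min <- 0L
  n_max <- k - n_min
  crit_names <- c(if (n_max) paste0("score", seq_len(n_max)),
                  if (n_min) paste0("cost", seq_len(n_min)))
  aims <- c(rep("max", n_max), rep("min", n_min))
  alt_names <- sprintf("alt%02d", seq_len(n))
  if (plant_dominant) alt_names[1L] <- "dominant"
  if (plant_duplicate) alt_names[c(n - 1L, n)] <- c("twin1", "twin2")

  top_term <- scale$term[1L]
  positive_terms <- scale$term[(scale$l + scale$m + scale$u) / 3 > 0]
  if (!length(positive_terms)) abort_input("Scale has no term with a positive Yager index to use as a weight.")

  withr::with_seed(as.integer(seed), {
    if (value_model == "percentage") {
      raw <- matrix(NA_real_, n, k)
      for (j in seq_len(k)) {
        raw[, j] <- if (aims[j] == "max") round(runif(n, 70, 100), 2)
                    else round(runif(n, 300, 450))
      }
      if (plant_dominant) raw <- plant_dominant_raw(raw, aims)
      if (plant_duplicate) raw[n, ] <- raw[n - 1L, ]
      banding <- stats::setNames(
        map(aims, function(a) if (a == "max") percentage_bands() else time_bands()),
        crit_names)
      terms <- matrix(NA_character_, n, k)
      for (j in seq_len(k)) terms[, j] <- band_value(raw[, j], banding[[j]])
      cells <- matrix(paste0(fmt_num(raw), "|", terms), n, k)
    } else {
      terms <- matrix(sample(scale$term, n * k, replace = TRUE), n, k)
      if (plant_dominant) {
        terms[1L, ] <- top_term
        # no other alternative may match the dominant profile everywhere
        for (i in 2L:n) if (all(terms[i, ] == top_term)) {
          terms[i, 1L] <- scale$term[min(2L, nrow(scale))]
        }
      }
      if (plant_duplicate) terms[n, ] <- terms[n - 1L, ]
      banding <- NULL
      cells <- terms
    }
    weights <- if (weight_model == "linguistic") {
      sample(positive_terms, k, replace = TRUE)
    } else {
      round(runif(k, 0.1, 1), 2)
    }
    df <- as.data.frame(cells, stringsAsFactors = FALSE)
    names(df) <- crit_names
    df <- cbind(data.frame(alternative = alt_names, stringsAsFactors = FALSE), df)
    dm <- decision_matrix(df, aim = aims, weight = weights,
                          scale = scale, banding = banding)
    attr(dm, "seed") <- as.integer(seed)
    dm
  })
}

# make row 1 the column-wise best of rows 2..n, then strictly better on one
# criterion, staying inside the banding calibration ranges
plant_dominant_raw <- function(raw, aims) {
  n <- nrow(raw)
  others <- raw[-1L, , drop = FALSE]
  for (j in seq_len(ncol(raw))) {
    raw[1L, j] <- if (aims[j] == "max") max(others[, j]) else min(others[, j])
  }
  for (j in seq_len(ncol(raw))) {
    if (aims[j] == "max") {
      bumped <- round(raw[1L, j] + 0.5 * (100 - raw[1L, j]), 2)
      if (bumped > raw[1L, j]) { raw[1L, j] <- bumped; return(raw) }
    } else {
      bumped <- max(300, round(raw[1L, j] - 0.5 * (raw[1L, j] - 300)))
      if (bumped < raw[1L, j]) { raw[1L, j] <- bumped; return(raw) }
    }
  }
  abort_input("Cannot plant a strictly dominant alternative: every criterion is already saturated.")
}
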