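#' Linguistic scales of triangular fuzzy numbers
#'
#' A linguistic scale maps an ordered set of qualitative terms (highest to
#' lowest, e.g. `VH > H > M > L > VL`) to triangular fuzzy numbers. A
#' triangular fuzzy number (TFN) is the triple `(l, m, u)` with `l <= m <= u`:
#' membership peaks at the modal value `m` and vanishes outside the support
#' `[l, u]`. The scale is the bridge between expert judgements expressed in
#' words and the crisp arithmetic of the outranking engine.
#'
#' The scale is data, not code: any ordered list of terms works, as long as
#' the Yager centroid indices of the terms strictly decrease in scale order
#' (so that "higher" terms really defuzzify higher).
#'
#' @param data A data frame with columns `term` (character), `l`, `m`, `u`
#'   (numeric), ordered from the highest term to the lowest.
#' @return A `linguistic_scale` tibble with columns `term`, `l`, `m`, `u`.
#' @examples
#' sc <- default_scale()
#' term_to_tfn("VH", sc)
#' defuzzify_term(c("VH", "M"), sc)
#' @seealso [default_scale()], [term_to_tfn()], [defuzzify_yager()]
#' @export
linguistic_scale <- function(data) {
  req <- c("term", "l", "m", "u")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort_input("`data` must be a data frame with columns term, l, m, u.")
  }
  out <- as_tibble(data)[req]
  out$term <- as.character(out$term)
  for (col in c("l", "m", "u")) out[[col]] <- as.numeric(out[[col]])
  if (nrow(out) < 1L) abort_input("A linguistic scale needs at least one term.")
  if (anyDuplicated(out$term)) {
    abort_input(paste0("Duplicated scale terms: ",
                       paste(unique(out$term[duplicated(out$term)]), collapse = ", ")))
  }
  bad <- which(!(out$l <= out$m & out$m <= out$u) | !is.finite(out$l + out$m + out$u))
  if (length(bad)) {
    abort_input(paste0("Invalid triangular fuzzy number for term(s): ",
                       paste(out$term[bad], collapse = ", "),
                       " (need finite l <= m <= u)."))
  }
  y <- (out$l + out$m + out$u) / 3
  if (nrow(out) > 1L && any(diff(y) >= 0)) {
    abort_input("Yager indices must be strictly decreasing in scale order (highest term first).")
  }
  class(out) <- c("linguistic_scale", class(out))
  out
}

#' Default five-term linguistic scale
#'
#' The bundled VH/H/M/L/VL scale: `VH = (0.75, 1, 1)`, `H = (0.5, 0.75, 1)`,
#' `M = (0.25, 0.5, 0.75)`, `L = (0, 0.25, 0.5)`, `VL = (0, 0, 0.25)`.
#' Loaded from the JSON scale file shipped with the package.
#'
#' @return A [linguistic_scale()] tibble.
#' @export
default_scale <- function() {
  read_scale(system.file("extdata", "default_scale.json", package = "fpromethee",
                         mustWork = TRUE))
}

#' Read or write a linguistic-scale JSON file
#'
#' Scale files are JSON objects of the form
#' `{"terms": [{"label": "VH", "tfn": [0.75, 1, 1]}, ...]}`, ordered from the
#' highest term to the lowest.
#'
#' @param path Path to a scale JSON file.
#' @return `read_scale()` returns a [linguistic_scale()]; `write_scale()`
#'   returns `path` invisibly.
#' @export
read_scale <- function(path) {
  if (!file.exists(path)) abort_input(paste0("Scale file not found: ", path))
  parsed <- tryCatch(read_json(path), error = function(e) {
    abort_input(paste0("Could not parse scale JSON '", path, "': ", conditionMessage(e)))
  })
  terms <- parsed[["terms"]]
  if (is.null(terms) || !length(terms)) {
    abort_input(paste0("Scale file '", path, "' has no \"terms\" array."))
  }
  linguistic_scale(tibble(
    term = map_chr(terms, function(t) as.character(t[["label"]])),
    l = map_dbl(terms, function(t) as.numeric(t[["tfn"]][[1]])),
    m = map_dbl(terms, function(t) as.numeric(t[["tfn"]][[2]])),
    u = map_dbl(terms, function(t) as.numeric(t[["tfn"]][[3]]))
  ))
}

#' @param scale A [linguistic_scale()].
#' @rdname read_scale
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "linguistic_scale"))
  obj <- list(terms = pmap(scale, function(term, l, m, u) {
    list(label = term, tfn = c(l, m, u))
  }))
  write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Look up the triangular fuzzy number of a linguistic term
#'
#' @param term Character vector of terms; each must belong to the scale.
#' @param scale A [linguistic_scale()]; defaults to [default_scale()].
#' @return A tibble with one row per input term and columns
#'   `term`, `l`, `m`, `u`.
#' @examples
#' term_to_tfn(c("H", "VL"))
#' @export
term_to_tfn <- function(term, scale = default_scale()) {
  stopifnot(inherits(scale, "linguistic_scale"))
  term <- as.character(term)
  idx <- match(term, scale$term)
  if (anyNA(idx)) {
    bad <- unique(term[is.na(idx)])
    abort_input(paste0("Unknown linguistic term(s): ", paste(bad, collapse = ", "),
                       ". Valid terms: ", paste(scale$term, collapse = ", "), "."))
  }
  out <- as_tibble(scale)[idx, c("term", "l", "m", "u")]
  out
}

#' Yager centroid defuzzification
#'
#' Collapses a triangular fuzzy number to its crisp centroid
#' `(l + m + u) / 3`. The centroid always lies in the support `[l, u]`, is
#' monotone in each of `l`, `m`, `u`, and equals `m` for a symmetric triangle.
#'
#' @param l Numeric vector of lower bounds, or a data frame with columns
#'   `l`, `m`, `u` (as returned by [term_to_tfn()]).
#' @param m,u Numeric vectors (ignored when `l` is a data frame).
#' @return Numeric vector of crisp values.
#' @examples
#' defuzzify_yager(0.75, 1, 1)      # 0.9167
#' defuzzify_yager(term_to_tfn("M")) # 0.5
#' @export
defuzzify_yager <- function(l, m = NULL, u = NULL) {
  if (is.data.frame(l)) {
    df <- l
    if (!all(c("l", "m", "u") %in% names(df))) {
      abort_input("Data-frame input to defuzzify_yager() needs columns l, m, u.")
    }
    l <- as.numeric(df$l); m <- as.numeric(df$m); u <- as.numeric(df$u)
  }
  l <- as.numeric(l); m <- as.numeric(m); u <- as.numeric(u)
  if (length(l) != length(m) || length(m) != length(u)) {
    abort_input("l, m, u must have equal lengths.")
  }
  bad <- which(!(l <= m & m <= u) | !is.finite(l + m + u))
  if (length(bad)) {
    abort_input(paste0("Invalid triangular fuzzy number at position(s) ",
                       paste(bad, collapse = ", "), ": need finite l <= m <= u."))
  }
  (l + m + u) / 3
}

#' Defuzzify linguistic terms directly
#'
#' Convenience wrapper: `defuzzify_yager(term_to_tfn(term, scale))`.
#'
#' @inheritParams term_to_tfn
#' @return Numeric vector of crisp values, one per term.
#' @export
defuzzify_term <- function(term, scale = default_scale()) {
  defuzzify_yager(term_to_tfn(term, scale))
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat("Linguistic scale (", nrow(x), " terms, highest first)\n", sep = "")
  df <- as.data.frame(x)
  df$yager <- round((df$l + df$m + df$u) / 3, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
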