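#' Build a decision matrix
#'
#' The decision matrix is the central input of the pipeline: `n >= 2`
#' alternatives evaluated on `k >= 1` criteria. Each cell can carry a raw
#' numeric value, a linguistic term from the scale, or both. Each criterion
#' has an optimisation aim (`"max"` or `"min"`), an importance weight given
#' either as a linguistic term (defuzzified with the Yager centroid) or as a
#' positive crisp number, and a preference-function specification used by
#' [promethee_flows()].
#'
#' @param data A data frame whose first column holds unique alternative
#'   names; every other column is a criterion. Numeric columns are taken as
#'   raw values; character columns may hold a bare number (`"94.1"`), a bare
#'   term (`"H"`), or both as `"94.1|H"`.
#' @param aim Character vector of length `k`, each `"max"` or `"min"`.
#' @param weight Vector of length `k`: linguistic terms (character) or
#'   positive crisp numbers. Character entries that are not scale terms but
#'   parse as numbers are treated as crisp.
#' @param pf Preference-function kind per criterion, one of `"usual"`,
#'   `"u_shape"`, `"v_shape"`, `"level"`, `"linear"`, `"gaussian"`
#'   (recycled; default `"gaussian"`).
#' @param q,p,s Optional per-criterion thresholds (recycled): indifference
#'   `q`, strict preference `p`, Gaussian inflection `s`. `NA` means "not
#'   set"; an unset Gaussian `s` is resolved at flow time to the population
#'   standard deviation of the crisp column.
#' @param scale A [linguistic_scale()].
#' @param banding Optional numeric-to-term banding: a single [bands()] table
#'   (applied to every criterion) or a named list of tables keyed by
#'   criterion name. Banding is only used when explicitly requested
#'   ([apply_banding()], [validate_labels()]) or when linguistic-mode
#'   evaluation meets a cell that has a raw value but no term.
#' @return A `decision_matrix` object.
#' @examples
#' dm <- decision_matrix(
#'   data.frame(alternative = c("a", "b"), acc = c("H", "VH"), cost = c("M", "L")),
#'   aim = c("max", "min"), weight = c("VH", "H")
#' )
#' dm
#' @export
decision_matrix <- function(data, aim, weight, pf = "gaussian",
                            q = NA_real_, p = NA_real_, s = NA_real_,
                            scale = default_scale(), banding = NULL) {
  if (!is.data.frame(data) || ncol(data) < 2L) {
    abort_input("`data` must be a data frame with an alternative column plus >= 1 criterion column.")
  }
  alternatives <- as.character(data[[1L]])
  n <- length(alternatives)
  if (n < 2L) abort_input("A decision matrix needs at least 2 alternatives (outranking flows are undefined otherwise).")
  if (anyDuplicated(alternatives)) {
    abort_input(paste0("Duplicated alternative names: ",
                       paste(unique(alternatives[duplicated(alternatives)]), collapse = ", ")))
  }
  crit_names <- names(data)[-1L]
  k <- length(crit_names)
  if (anyDuplicated(crit_names)) abort_input("Criterion names must be unique.")

  aim <- as.character(aim)
  if (length(aim) != k || !all(aim %in% c("max", "min"))) {
    abort_input(paste0("`aim` must give 'max' or 'min' for each of the ", k, " criteria."))
  }

  # weights: scale terms or positive crisp numbers
  if (length(weight) == 1L && k > 1L) weight <- rep(weight, k)
  if (length(weight) != k) abort_input(paste0("`weight` must have length ", k, "."))
  weight_term <- rep(NA_character_, k)
  weight_crisp <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    wj <- weight[[j]]
    if (is.character(wj) && wj %in% scale$term) {
      weight_term[j] <- wj
      weight_crisp[j] <- defuzzify_term(wj, scale)
    } else {
      num <- suppressWarnings(as.numeric(wj))
      if (is.na(num)) {
        abort_input(paste0("Weight '", wj, "' for criterion '", crit_names[j],
                           "' is neither a scale term (",
                           paste(scale$term, collapse = ", "), ") nor a number."))
      }
      weight_crisp[j] <- num
    }
  }
  if (any(!is.finite(weight_crisp)) || any(weight_crisp <= 0)) {
    abort_input("All crisp criterion weights must be positive and finite.")
  }

  pf <- rep_len(as.character(pf), k)
  kinds <- c("usual", "u_shape", "v_shape", "level", "linear", "gaussian")
  if (!all(pf %in% kinds)) {
    abort_input(paste0("Unknown preference-function kind(s): ",
                       paste(setdiff(pf, kinds), collapse = ", "),
                       ". Valid kinds: ", paste(kinds, collapse = ", "), "."))
  }
  q <- rep_len(as.numeric(q), k)
  p <- rep_len(as.numeric(p), k)
  s <- rep_len(as.numeric(s), k)
  for (j in seq_len(k)) {
    validate_pf_spec(pf[j], q[j], p[j], s[j],
                     where = paste0("criterion '", crit_names[j], "'"),
                     require_s = FALSE)
  }

  raw <- matrix(NA_real_, n, k, dimnames = list(alternatives, crit_names))
  terms <- matrix(NA_character_, n, k, dimnames = list(alternatives, crit_names))
  for (j in seq_len(k)) {
    col <- data[[j + 1L]]
    if (is.numeric(col)) {
      raw[, j] <- as.numeric(col)
    } else {
      parsed <- parse_cells(as.character(col), scale, crit_names[j])
      raw[, j] <- parsed$raw
      terms[, j] <- parsed$term
    }
  }
  empty <- is.na(raw) & is.na(terms)
  if (any(empty)) {
    idx <- which(empty, arr.ind = TRUE)[1L, ]
    abort_input(paste0("Empty cell: alternative '", alternatives[idx[1L]],
                       "', criterion '", crit_names[idx[2L]],
                       "' has neither a raw value nor a term."))
  }

  banding <- normalise_banding(banding, crit_names)

  structure(
    list(
      alternatives = alternatives,
      criteria = tibble(name = crit_names, aim = aim,
                        weight_term = weight_term, weight_crisp = weight_crisp,
                        pf = pf, q = q, p = p, s = s),
      raw = raw,
      terms = terms,
      scale = scale,
      banding = banding
    ),
    class = "decision_matrix"
  )
}

# "94.1|H" / "H" / "94.1" -> list(raw=, term=); empty strings stay NA/NA
parse_cells <- function(x, scale, crit_name) {
  x <- str_trim(x)
  rawv <- rep(NA_real_, length(x))
  termv <- rep(NA_character_, length(x))
  for (i in seq_along(x)) {
    cell <- x[i]
    if (is.na(cell) || cell == "") next
    parts <- str_trim(strsplit(cell, "|", fixed = TRUE)[[1L]])
    for (part in parts[parts != ""]) {
      num <- suppressWarnings(as.numeric(part))
      if (!is.na(num)) {
        rawv[i] <- num
      } else if (part %in% scale$term) {
        termv[i] <- part
      } else {
        abort_input(paste0("Cell '", cell, "' (criterion '", crit_name,
                           "', row ", i, "): '", part,
                           "' is neither a number nor a scale term (",
                           paste(scale$term, collapse = ", "), ")."))
      }
    }
  }
  list(raw = rawv, term = termv)
}

normalise_banding <- function(banding, crit_names) {
  if (is.null(banding)) return(list())
  if (is.data.frame(banding)) {
    banding <- stats::setNames(rep(list(banding), length(crit_names)), crit_names)
  }
  if (!is.list(banding) || is.null(names(banding)) ||
      !all(names(banding) %in% crit_names)) {
    abort_input("`banding` must be a bands() table or a named list keyed by criterion name.")
  }
  banding
}

#' @export
print.decision_matrix <- function(x, ...) {
  k <- n_criteria(x); n <- n_alternatives(x)
  cat("Decision matrix: ", n, " alternatives x ", k, " criteria\n", sep = "")
  hdr <- paste0(x$criteria$name, " [", x$criteria$aim, "/",
                ifelse(is.na(x$criteria$weight_term),
                       format(round(x$criteria$weight_crisp, 2)),
                       x$criteria$weight_term), "]")
  cells <- matrix("", n, k, dimnames = list(x$alternatives, hdr))
  for (j in seq_len(k)) {
    cells[, j] <- format_cell(x$raw[, j], x$terms[, j])
  }
  print(as.data.frame(cells), ...)
  invisible(x)
}

format_cell <- function(raw, term) {
  out <- character(length(raw))
  both <- !is.na(raw) & !is.na(term)
  out[both] <- paste0(fmt_num(raw[both]), "|", term[both])
  out[!both & !is.na(raw)] <- fmt_num(raw[!both & !is.na(raw)])
  out[!both & !is.na(term)] <- term[!both & !is.na(term)]
  out
}

# shortest decimal string that round-trips to the same double
fmt_num <- function(x) {
  map_chr(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  })
}

#' Decision-matrix accessors
#'
#' @param x A [decision_matrix()].
#' @return `n_alternatives()`/`n_criteria()` return integers;
#'   `criteria()` returns the criteria tibble (name, aim, weight_term,
#'   weight_crisp, pf, q, p, s); `alternatives()` the alternative names.
#' @export
n_alternatives <- function(x) length(x$alternatives)

#' @rdname n_alternatives
#' @export
n_criteria <- function(x) nrow(x$criteria)

#' @rdname n_alternatives
#' @export
criteria <- function(x) x$criteria

#' @rdname n_alternatives
#' @export
alternatives <- function(x) x$alternatives

#' @method as_tibble decision_matrix
#' @export
as_tibble.decision_matrix <- function(x, ...) {
  expand.grid(alternative = x$alternatives, criterion = x$criteria$name,
              stringsAsFactors = FALSE) |>
    as_tibble() |>
    mutate(value = as.vector(x$raw), term = as.vector(x$terms)) |>
    arrange(match(.data$alternative, x$alternatives),
            match(.data$criterion, x$criteria$name))
}

#' Crisp per-cell evaluations
#'
#' Converts every cell of the matrix to a crisp scalar. In `"linguistic"`
#' mode a cell's term is defuzzified with the Yager centroid; a cell with a
#' raw value but no term is first banded through the criterion's banding
#' table (an error if none is attached). In `"raw"` mode the numeric value
#' is returned unchanged.
#'
#' @param dm A [decision_matrix()].
#' @param mode `"linguistic"` or `"raw"`.
#' @return A tibble: `alternative` plus one numeric column per criterion.
#' @export
crisp_values <- function(dm, mode = c("linguistic", "raw")) {
  E <- crisp_matrix(dm, match.arg(mode))
  bind_cols(tibble(alternative = dm$alternatives), as_tibble(as.data.frame(E)))
}

crisp_matrix <- function(dm, mode) {
  stopifnot(inherits(dm, "decision_matrix"))
  n <- n_alternatives(dm); k <- n_criteria(dm)
  E <- matrix(NA_real_, n, k, dimnames = dimnames(dm$raw))
  if (mode == "raw") {
    miss <- which(is.na(dm$raw), arr.ind = TRUE)
    if (nrow(miss)) {
      abort_input(paste0("Missing raw value for alternative '",
                         dm$alternatives[miss[1L, 1L]], "', criterion '",
                         dm$criteria$name[miss[1L, 2L]], "' (mode 'raw')."))
    }
    return(dm$raw)
  }
  for (j in seq_len(k)) {
    tj <- dm$terms[, j]
    fill <- is.na(tj)
    if (any(fill)) {
      bnd <- dm$banding[[dm$criteria$name[j]]]
      if (is.null(bnd) || any(is.na(dm$raw[fill, j]))) {
        i <- which(fill)[1L]
        abort_input(paste0("Missing term for alternative '", dm$alternatives[i],
                           "', criterion '", dm$criteria$name[j],
                           "' (mode 'linguistic')",
                           if (is.null(bnd)) " and no banding attached to derive one."
                           else " and no raw value to band.", ""))
      }
      tj[fill] <- band_value(dm$raw[fill, j], bnd)
    }
    E[, j] <- defuzzify_term(tj, dm$scale)
  }
  E
}

#' Fill linguistic terms from raw values through banding
#'
#' @param dm A [decision_matrix()] with banding attached (or `banding`
#'   supplied here).
#' @param banding Optional banding override, as in [decision_matrix()].
#' @param overwrite Replace existing terms (`TRUE`) or only fill missing
#'   ones (`FALSE`, default)?
#' @return The modified decision matrix.
#' @export
apply_banding <- function(dm, banding = NULL, overwrite = FALSE) {
  stopifnot(inherits(dm, "decision_matrix"))
  if (!is.null(banding)) dm$banding <- normalise_banding(banding, dm$criteria$name)
  if (!length(dm$banding)) abort_input("No banding attached to the matrix.")
  for (nm in names(dm$banding)) {
    j <- match(nm, dm$criteria$name)
    target <- if (overwrite) !is.na(dm$raw[, j]) else is.na(dm$terms[, j]) & !is.na(dm$raw[, j])
    if (any(target)) {
      dm$terms[target, j] <- band_value(dm$raw[target, j], dm$banding[[nm]])
    }
  }
  dm
}

#' Audit printed terms against their banding rule
#'
#' For every cell that carries both a raw value and a term, and whose
#' criterion has a banding table, compares the stored (printed) term with
#' the term the banding rule produces. Cells lacking either field, or on
#' criteria without banding, are skipped and counted separately.
#'
#' @param dm A [decision_matrix()].
#' @param banding Optional banding override, as in [decision_matrix()].
#' @return A tibble of mismatches (`alternative`, `criterion`, `value`,
#'   `printed`, `banded`) with attributes `n_checked` and `n_skipped`. Zero
#'   rows means every auditable cell is consistent.
#' @export
validate_labels <- function(dm, banding = NULL) {
  stopifnot(inherits(dm, "decision_matrix"))
  if (!is.null(banding)) dm$banding <- normalise_banding(banding, dm$criteria$name)
  out <- list()
  n_checked <- 0L; n_skipped <- 0L
  for (j in seq_len(n_criteria(dm))) {
    nm <- dm$criteria$name[j]
    bnd <- dm$banding[[nm]]
    auditable <- !is.na(dm$raw[, j]) & !is.na(dm$terms[, j]) & !is.null(bnd)
    n_skipped <- n_skipped + sum(!auditable)
    if (is.null(bnd) || !any(auditable)) next
    banded <- band_value(dm$raw[auditable, j], bnd)
    printed <- dm$terms[auditable, j]
    n_checked <- n_checked + sum(auditable)
    bad <- banded != printed
    if (any(bad)) {
      out[[nm]] <- tibble(
        alternative = dm$alternatives[auditable][bad],
        criterion = nm,
        value = dm$raw[auditable, j][bad],
        printed = printed[bad],
        banded = banded[bad]
      )
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(alternative = character(), criterion = character(),
           value = numeric(), printed = character(), banded = character())
  attr(res, "n_checked") <- n_checked
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Replace one criterion's weight
#'
#' @param dm A [decision_matrix()].
#' @param criterion Criterion name.
#' @param new_weight A scale term or a positive crisp number.
#' @return The modified decision matrix.
#' @export
set_weight <- function(dm, criterion, new_weight) {
  stopifnot(inherits(dm, "decision_matrix"))
  j <- match(criterion, dm$criteria$name)
  if (is.na(j)) {
    abort_input(paste0("Unknown criterion '", criterion, "'. Criteria: ",
                       paste(dm$criteria$name, collapse = ", "), "."))
  }
  if (is.character(new_weight) && new_weight %in% dm$scale$term) {
    dm$criteria$weight_term[j] <- new_weight
    dm$criteria$weight_crisp[j] <- defuzzify_term(new_weight, dm$scale)
  } else {
    num <- suppressWarnings(as.numeric(new_weight))
    if (is.na(num) || num <= 0) {
      abort_input(paste0("New weight must be a scale term or a positive number, got '",
                         new_weight, "'."))
    }
    dm$criteria$weight_term[j] <- NA_character_
    dm$criteria$weight_crisp[j] <- num
  }
  dm
}
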