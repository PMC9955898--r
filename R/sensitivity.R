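#' One-at-a-time criterion-weight perturbation
#'
#' Recomputes the PROMETHEE II flows with a single criterion's weight
#' changed (all other weights, the evaluations, and the preference
#' functions untouched) and reports how the ranking responded. The ranking
#' is considered preserved when the ordered tie-group sequences of
#' alternative names are identical — net-flow values are allowed to move.
#'
#' @param dm A [decision_matrix()].
#' @param criterion Criterion name to perturb.
#' @param new_weight New weight: a scale term or a positive crisp number.
#' @inheritParams promethee_flows
#' @return A `sensitivity_report` object; [tidy()] gives per-alternative
#'   baseline/perturbed flows, deltas and ranks, [glance()] a one-row
#'   summary including `ranking_preserved`.
#' @examples
#' dm <- load_fixture("brain_tumor_linguistic")
#' rep <- perturb_weight(dm, "specificity", "M")
#' glance(rep)
#' @export
perturb_weight <- function(dm, criterion, new_weight,
                           mode = c("linguistic", "raw"), s = NULL,
                           tie_tol = 1e-9) {
  mode <- match.arg(mode)
  j <- match(criterion, dm$criteria$name)
  if (is.na(j)) {
    abort_input(paste0("Unknown criterion '", criterion, "'. Criteria: ",
                       paste(dm$criteria$name, collapse = ", "), "."))
  }
  baseline <- promethee_flows(dm, mode = mode, s = s, tie_tol = tie_tol)
  dm2 <- set_weight(dm, criterion, new_weight)
  perturbed <- promethee_flows(dm2, mode = mode, s = s, tie_tol = tie_tol)
  deltas <- tidy(baseline) |>
    rename(net_baseline = "net_flow", rank_baseline = "rank") |>
    select("alternative", "net_baseline", "rank_baseline") |>
    left_join(tidy(perturbed) |>
                rename(net_perturbed = "net_flow", rank_perturbed = "rank") |>
                select("alternative", "net_perturbed", "rank_perturbed"),
              by = "alternative") |>
    mutate(delta = .data$net_perturbed - .data$net_baseline)
  structure(
    list(criterion = criterion,
         old_term = dm$criteria$weight_term[j],
         old_crisp = dm$criteria$weight_crisp[j],
         new_term = dm2$criteria$weight_term[j],
         new_crisp = dm2$criteria$weight_crisp[j],
         baseline = baseline,
         perturbed = perturbed,
         deltas = deltas,
         ranking_preserved = identical(ranking_signature(baseline),
                                       ranking_signature(perturbed)),
         mode = mode),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, digits = 4, ...) {
  fmt_w <- function(term, crisp) {
    if (!is.na(term)) paste0(term, " (", round(crisp, 2), ")") else format(round(crisp, 2))
  }
  cat("Weight sensitivity on '", x$criterion, "': ",
      fmt_w(x$old_term, x$old_crisp), " -> ", fmt_w(x$new_term, x$new_crisp),
      "\n", sep = "")
  df <- as.data.frame(tidy(x))
  for (col in c("net_baseline", "net_perturbed", "delta")) df[[col]] <- round(df[[col]], digits)
  print(df[order(df$rank_baseline), ], row.names = FALSE)
  cat("ranking preserved:", if (x$ranking_preserved) "yes" else "no", "\n")
  invisible(x)
}

#' @method tidy sensitivity_report
#' @export
tidy.sensitivity_report <- function(x, ...) x$deltas

#' @method glance sensitivity_report
#' @export
glance.sensitivity_report <- function(x, ...) {
  tibble(
    criterion = x$criterion,
    old_term = x$old_term, old_weight = x$old_crisp,
    new_term = x$new_term, new_weight = x$new_crisp,
    mode = x$mode,
    ranking_preserved = x$ranking_preserved,
    max_abs_delta = max(abs(x$deltas$delta))
  )
}

#' @method autoplot sensitivity_report
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  df <- tidy(object) |>
    mutate(alternative = stats::reorder(.data$alternative, .data$net_baseline))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$alternative)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$net_baseline,
                                       xend = .data$net_perturbed,
                                       yend = .data$alternative),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$net_baseline, colour = "baseline")) +
    ggplot2::geom_point(ggplot2::aes(x = .data$net_perturbed, colour = "perturbed")) +
    ggplot2::labs(x = "Net outranking flow φ", y = NULL, colour = NULL,
                  title = paste0("Weight perturbation on '", object$criterion, "'")) +
    ggplot2::theme_minimal()
}

#' Rank-stability interval of one criterion weight
#'
#' Scans a grid of crisp weights for the chosen criterion (all other
#' weights fixed) and returns the maximal contiguous interval around the
#' baseline weight within which the complete tie-group ranking is
#' unchanged. Endpoints are reported at grid precision; the interval always
#' contains the baseline weight.
#'
#' @inheritParams perturb_weight
#' @param resolution Grid step (default 0.01).
#' @param w_max Upper end of the scanned range `(0, w_max]` (default 1).
#' @return A one-row tibble: `criterion`, `baseline_weight`, `lower`,
#'   `upper`, `resolution`, `w_max`, `full_range` (does the interval span
#'   the whole scanned range?).
#' @export
stability_interval <- function(dm, criterion, resolution = 0.01, w_max = 1,
                               mode = c("linguistic", "raw"), s = NULL,
                               tie_tol = 1e-9) {
  mode <- match.arg(mode)
  if (!is.numeric(resolution) || resolution <= 0) {
    abort_input("`resolution` must be > 0.")
  }
  j <- match(criterion, dm$criteria$name)
  if (is.na(j)) {
    abort_input(paste0("Unknown criterion '", criterion, "'. Criteria: ",
                       paste(dm$criteria$name, collapse = ", "), "."))
  }
  baseline <- promethee_flows(dm, mode = mode, s = s, tie_tol = tie_tol)
  if (length(baseline$tie_groups) == 1L) {
    warn("All alternatives are tied at the baseline; the stability interval is degenerate.")
  }
  sig0 <- ranking_signature(baseline)
  w0 <- dm$criteria$weight_crisp[j]
  grid <- sort(unique(c(seq(resolution, w_max, by = resolution), w0)))
  same <- map_lgl(grid, function(w) {
    fl <- promethee_flows(set_weight(dm, criterion, w),
                          mode = mode, s = s, tie_tol = tie_tol)
    identical(ranking_signature(fl), sig0)
  })
  i0 <- match(w0, grid)
  if (!same[i0]) abort_internal("Baseline weight does not reproduce the baseline ranking.")
  lo <- i0; while (lo > 1L && same[lo - 1L]) lo <- lo - 1L
  hi <- i0; while (hi < length(grid) && same[hi + 1L]) hi <- hi + 1L
  tibble(
    criterion = criterion,
    baseline_weight = w0,
    lower = grid[lo],
    upper = grid[hi],
    resolution = resolution,
    w_max = w_max,
    full_range = lo == 1L && hi == length(grid)
  )
}
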