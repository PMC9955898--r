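#' PROMETHEE II outranking flows
#'
#' Runs the complete-ranking PROMETHEE II procedure on a decision matrix.
#' For every ordered pair of alternatives `(a, b)` and every criterion `j`,
#' the signed deviation `d_j(a, b)` (crisp value of `a` minus `b`, sign
#' flipped on min-aim criteria so that positive always means "a preferred")
#' is passed through the criterion's preference function; the aggregated
#' preference index is the weight-normalised sum
#' `pi(a, b) = sum_j w_j P_j(a, b) / sum_j w_j`. Flows are
#' `phi+(a) = mean of pi(a, .)`, `phi-(a) = mean of pi(., a)` over the
#' `n - 1` others, `phi = phi+ - phi-`; alternatives are ranked by net flow
#' with competition-style tied ranks.
#'
#' Unset Gaussian thresholds are resolved per criterion to the population
#' standard deviation of its `n` crisp evaluations (a criterion with zero
#' spread contributes zero preference). Weights enter normalised by their
#' sum, so only weight ratios matter.
#'
#' @param dm A [decision_matrix()].
#' @param mode `"linguistic"` (defuzzified terms; default) or `"raw"`
#'   (numeric values).
#' @param s Optional Gaussian-threshold override: a single number for all
#'   criteria or a named vector keyed by criterion name.
#' @param tie_tol Net flows closer than this are grouped as ties
#'   (default `1e-9`).
#' @return A `promethee_flows` object; [tidy()] gives the per-alternative
#'   table (`alternative`, `phi_plus`, `phi_minus`, `net_flow`, `rank`),
#'   [glance()] a one-row summary, [autoplot()] a net-flow bar chart.
#' @examples
#' dm <- load_fixture("brain_tumor_linguistic")
#' fl <- promethee_flows(dm)
#' tidy(fl)
#' @export
promethee_flows <- function(dm, mode = c("linguistic", "raw"), s = NULL,
                            tie_tol = 1e-9) {
  stopifnot(inherits(dm, "decision_matrix"))
  mode <- match.arg(mode)
  if (!is.numeric(tie_tol) || length(tie_tol) != 1L || tie_tol < 0) {
    abort_input("`tie_tol` must be a single nonnegative number.")
  }
  n <- n_alternatives(dm)
  if (n < 2L) abort_input("Flows need at least 2 alternatives.")
  E <- crisp_matrix(dm, mode)
  s_used <- resolve_s(dm, E, s)
  PI <- preference_index_matrix(dm, E, s_used)
  phi_plus <- rowSums(PI) / (n - 1)
  phi_minus <- colSums(PI) / (n - 1)
  net <- phi_plus - phi_minus
  if (abs(sum(net)) > 1e-9 * max(1, n)) {
    abort_internal("Net-flow conservation violated (sum of net flows not ~0).")
  }
  rk <- rank_groups(net, tie_tol)
  flows <- tibble(
    alternative = dm$alternatives,
    phi_plus = unname(phi_plus),
    phi_minus = unname(phi_minus),
    net_flow = unname(net),
    rank = rk$rank
  )
  structure(
    list(flows = flows,
         tie_groups = map(rk$groups, function(i) dm$alternatives[i]),
         mode = mode,
         s = s_used,
         weights = stats::setNames(dm$criteria$weight_crisp, dm$criteria$name),
         tie_tol = tie_tol,
         n = n, k = n_criteria(dm)),
    class = "promethee_flows"
  )
}

# weighted-average preference index matrix pi(a, b); diagonal zero
preference_index_matrix <- function(dm, E, s_used) {
  n <- nrow(E); k <- ncol(E)
  w <- dm$criteria$weight_crisp
  tw <- sum(w)
  if (!is.finite(tw) || tw <= 0) abort_input("Total criterion weight must be positive.")
  wn <- w / tw
  PI <- matrix(0, n, n, dimnames = list(rownames(E), rownames(E)))
  for (j in seq_len(k)) {
    D <- outer(E[, j], E[, j], "-")
    if (dm$criteria$aim[j] == "min") D <- -D
    P <- matrix(
      preference_degree(as.vector(D), kind = dm$criteria$pf[j],
                        q = dm$criteria$q[j], p = dm$criteria$p[j],
                        s = s_used[j]),
      n, n)
    PI <- PI + wn[j] * P
  }
  diag(PI) <- 0
  PI
}

# per-criterion gaussian threshold: override > stored spec > population sd
resolve_s <- function(dm, E, s_arg) {
  k <- n_criteria(dm)
  nm <- dm$criteria$name
  s_used <- dm$criteria$s
  if (!is.null(s_arg)) {
    s_arg <- stats::setNames(as.numeric(s_arg), names(s_arg))
    if (length(s_arg) == 1L && is.null(names(s_arg))) {
      s_used <- rep(s_arg, k)
    } else {
      if (is.null(names(s_arg)) || !all(names(s_arg) %in% nm)) {
        abort_input(paste0("`s` overrides must be a single number or named by criterion (",
                           paste(nm, collapse = ", "), ")."))
      }
      s_used[match(names(s_arg), nm)] <- s_arg
    }
    if (any(!is.na(s_used) & s_used < 0)) abort_input("Gaussian s overrides must be >= 0.")
  }
  auto <- is.na(s_used) & dm$criteria$pf == "gaussian"
  if (any(auto)) {
    s_used[auto] <- apply(E[, auto, drop = FALSE], 2L,
                          function(x) sqrt(mean((x - mean(x))^2)))
  }
  stats::setNames(s_used, nm)
}

#' Competition-style ranks from net flows
#'
#' Tied net flows (within `tie_tol` of the tie-group head) share a rank;
#' the next group's rank skips by the group size (1, 2, 2, 4, ...). Within
#' a tie group, alternatives keep input order.
#'
#' @param net_flow Numeric vector of net flows.
#' @param tie_tol Tie tolerance.
#' @return Integer vector of ranks aligned with the input.
#' @examples
#' rank_complete(c(0.3, 0.1, 0.1, -0.5)) # 1 2 2 4
#' @export
rank_complete <- function(net_flow, tie_tol = 1e-9) {
  rank_groups(as.numeric(net_flow), tie_tol)$rank
}

rank_groups <- function(net, tie_tol) {
  n <- length(net)
  ord <- order(-net) # stable: ties keep input order
  rank <- integer(n)
  groups <- list()
  head_val <- NA_real_; head_pos <- 0L
  for (pos in seq_len(n)) {
    i <- ord[pos]
    if (pos == 1L || head_val - net[i] > tie_tol) {
      head_val <- net[i]; head_pos <- pos
      groups[[length(groups) + 1L]] <- integer()
    }
    rank[i] <- head_pos
    groups[[length(groups)]] <- c(groups[[length(groups)]], i)
  }
  list(rank = rank, groups = groups)
}

# ordered tie-group signature used for ranking comparisons
ranking_signature <- function(x) {
  stopifnot(inherits(x, "promethee_flows"))
  map_chr(x$tie_groups, function(g) paste(g, collapse = "+"))
}

#' Signed pairwise deviations per criterion
#'
#' Long table of `d_j(a, b)`: crisp evaluation of `a` minus `b`, sign
#' flipped on min-aim criteria, so positive always means "a preferred over
#' b on this criterion".
#'
#' @inheritParams promethee_flows
#' @return A tibble with columns `a`, `b`, `criterion`, `deviation`.
#' @export
deviations <- function(dm, mode = c("linguistic", "raw")) {
  mode <- match.arg(mode)
  E <- crisp_matrix(dm, mode)
  out <- list()
  for (j in seq_len(n_criteria(dm))) {
    D <- outer(E[, j], E[, j], "-")
    if (dm$criteria$aim[j] == "min") D <- -D
    out[[j]] <- tibble(
      a = rep(dm$alternatives, times = length(dm$alternatives)),
      b = rep(dm$alternatives, each = length(dm$alternatives)),
      criterion = dm$criteria$name[j],
      deviation = as.vector(D)
    ) |> filter(.data$a != .data$b)
  }
  bind_rows(out)
}

#' Aggregated preference index for one ordered pair
#'
#' `pi(a, b) = sum_j w_j P_j(a, b) / sum_j w_j`, in `[0, 1]`.
#'
#' @inheritParams promethee_flows
#' @param a,b Alternative names.
#' @return A single number.
#' @export
aggregated_preference <- function(dm, a, b, mode = c("linguistic", "raw"), s = NULL) {
  mode <- match.arg(mode)
  ia <- match(a, dm$alternatives); ib <- match(b, dm$alternatives)
  if (is.na(ia) || is.na(ib)) {
    abort_input(paste0("Unknown alternative(s): ",
                       paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "), "."))
  }
  E <- crisp_matrix(dm, mode)
  PI <- preference_index_matrix(dm, E, resolve_s(dm, E, s))
  unname(PI[ia, ib])
}

#' @export
print.promethee_flows <- function(x, digits = 4, ...) {
  cat("PROMETHEE II flows (", x$n, " alternatives, ", x$k, " criteria, mode '",
      x$mode, "')\n", sep = "")
  df <- tidy(x) |> arrange(.data$rank, match(.data$alternative, x$flows$alternative))
  df <- df[, c("rank", "alternative", "net_flow", "phi_plus", "phi_minus")]
  df$net_flow <- round(df$net_flow, digits)
  df$phi_plus <- round(df$phi_plus, digits)
  df$phi_minus <- round(df$phi_minus, digits)
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

#' @method tidy promethee_flows
#' @export
tidy.promethee_flows <- function(x, ...) x$flows

#' @method glance promethee_flows
#' @export
glance.promethee_flows <- function(x, ...) {
  tibble(
    n_alternatives = x$n,
    n_criteria = x$k,
    mode = x$mode,
    n_tie_groups = length(x$tie_groups),
    sum_net_flow = sum(x$flows$net_flow),
    tie_tol = x$tie_tol
  )
}

#' @method autoplot promethee_flows
#' @export
autoplot.promethee_flows <- function(object, ...) {
  df <- tidy(object) |>
    mutate(alternative = stats::reorder(.data$alternative, .data$net_flow))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alternative, y = .data$net_flow,
                                   fill = .data$net_flow >= 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Net outranking flow φ",
                  title = "PROMETHEE II complete ranking") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.promethee_flows
#' @param object A `promethee_flows` object.
#' @param ... Passed on.
#' @export
plot_flows <- function(object, ...) autoplot(object, ...)
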