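# Independent brute-force PROMETHEE II: scalar triple loops, no shared code
# with the package engine. Gaussian and usual preference functions only.
oracle_flows <- function(E, aims, w, svec = NULL, kinds = NULL) {
  n <- nrow(E)
  k <- ncol(E)
  if (is.null(kinds)) kinds <- rep("gaussian", k)
  if (is.null(svec)) {
    svec <- numeric(k)
    for (j in seq_len(k)) {
      mu <- sum(E[, j]) / n
      svec[j] <- sqrt(sum((E[, j] - mu)^2) / n)
    }
  }
  wsum <- sum(w)
  phi_plus <- numeric(n)
  phi_minus <- numeric(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      acc <- 0
      for (j in seq_len(k)) {
        d <- E[a, j] - E[b, j]
        if (aims[j] == "min") d <- -d
        P <- 0
        if (d > 0) {
          if (kinds[j] == "usual") {
            P <- 1
          } else if (svec[j] > 0) {
            P <- 1 - exp(-d * d / (2 * svec[j]^2))
          }
        }
        acc <- acc + w[j] * P / wsum
      }
      phi_plus[a] <- phi_plus[a] + acc / (n - 1)
      phi_minus[b] <- phi_minus[b] + acc / (n - 1)
    }
  }
  list(phi_plus = phi_plus, phi_minus = phi_minus, net = phi_plus - phi_minus)
}

# decision matrix from a plain numeric matrix (raw-mode analysis)
raw_dm <- function(E, aims, weights, ...) {
  df <- cbind(
    data.frame(alternative = sprintf("a%02d", seq_len(nrow(E)))),
    as.data.frame(E)
  )
  names(df)[-1] <- sprintf("c%02d", seq_len(ncol(E)))
  decision_matrix(df, aim = aims, weight = weights, ...)
}

# decision matrix from a character matrix of linguistic terms
term_dm <- function(terms, aims, weights, ...) {
  df <- cbind(
    data.frame(alternative = sprintf("a%02d", seq_len(nrow(terms)))),
    as.data.frame(terms, stringsAsFactors = FALSE)
  )
  names(df)[-1] <- sprintf("c%02d", seq_len(ncol(terms)))
  decision_matrix(df, aim = aims, weight = weights, ...)
}

fixture_banding <- function(dm) {
  stats::setNames(
    lapply(criteria(dm)$aim,
           function(a) if (a == "max") percentage_bands() else time_bands()),
    criteria(dm)$name
  )
}
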