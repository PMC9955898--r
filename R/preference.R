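#' Preference functions of the PROMETHEE catalogue
#'
#' Maps a signed pairwise deviation `d` on one criterion to a preference
#' degree `P` in `[0, 1]`. Non-positive deviations never generate
#' preference, for every kind. For `d > 0`:
#'
#' * `usual`:   `P = 1`
#' * `u_shape`: `P = 1` if `d > q`, else 0
#' * `v_shape`: `P = min(d / p, 1)`
#' * `level`:   `P = 0` for `d <= q`, `1/2` for `q < d <= p`, `1` for `d > p`
#' * `linear`:  `P = clamp((d - q) / (p - q), 0, 1)`
#' * `gaussian`: `P = 1 - exp(-d^2 / (2 s^2))`
#'
#' A Gaussian criterion with `s = 0` (a constant crisp column, where the
#' automatic threshold degenerates) contributes zero preference.
#'
#' @param d Numeric vector of signed deviations.
#' @param kind One of `"usual"`, `"u_shape"`, `"v_shape"`, `"level"`,
#'   `"linear"`, `"gaussian"`.
#' @param q Indifference threshold (default 0).
#' @param p Strict-preference threshold.
#' @param s Gaussian inflection threshold.
#' @return Numeric vector of preference degrees in `[0, 1]`.
#' @examples
#' preference_degree(c(-0.3, 0, 0.2), "usual")
#' preference_degree(0.1, "gaussian", s = 0.1) # 1 - exp(-1/2)
#' @export
preference_degree <- function(d, kind = "gaussian", q = 0, p = NA_real_, s = NA_real_) {
  kind <- match.arg(kind, c("usual", "u_shape", "v_shape", "level", "linear", "gaussian"))
  if (is.na(q)) q <- 0
  validate_pf_spec(kind, q, p, s, where = "preference_degree()", require_s = TRUE)
  d <- as.numeric(d)
  P <- switch(kind,
    usual   = as.numeric(d > 0),
    u_shape = as.numeric(d > q),
    v_shape = pmin(pmax(d, 0) / p, 1),
    level   = ifelse(d > p, 1, ifelse(d > q, 0.5, 0)),
    linear  = pmin(pmax((d - q) / (p - q), 0), 1),
    gaussian = if (s == 0) rep(0, length(d)) else 1 - exp(-d^2 / (2 * s^2))
  )
  P[d <= 0] <- 0
  P
}

# threshold validation shared by the constructor (where s may still be
# unresolved) and preference_degree() (where gaussian needs a concrete s)
validate_pf_spec <- function(kind, q, p, s, where, require_s) {
  chk <- function(ok, msg) if (!ok) {
    abort_input(paste0("Invalid preference-function spec at ", where, ": ", msg))
  }
  if (!is.na(q)) chk(q >= 0, "q must be nonnegative.")
  if (!is.na(p)) chk(p >= 0, "p must be nonnegative.")
  if (!is.na(q) && !is.na(p)) chk(q <= p, "need q <= p.")
  switch(kind,
    u_shape = chk(!is.na(q), "u_shape needs threshold q."),
    v_shape = chk(!is.na(p) && p > 0, "v_shape needs threshold p > 0."),
    level   = chk(!is.na(q) && !is.na(p), "level needs thresholds q and p."),
    linear  = chk(!is.na(q) && !is.na(p) && p > q,
                  "linear needs thresholds q < p."),
    gaussian = if (require_s) {
      chk(!is.na(s) && s >= 0, "gaussian needs threshold s >= 0.")
    } else if (!is.na(s)) {
      chk(s > 0, "an explicit gaussian s must be > 0.")
    },
    NULL
  )
  invisible(TRUE)
}
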