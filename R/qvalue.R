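#' Storey q-values
#'
#' Estimates the null proportion pi0 by a cubic smoothing spline over the
#' tail-proportion estimates at `lambda = 0.05, 0.10, ..., 0.90`, evaluated at
#' the largest lambda, then converts p-values to q-values (monotone step-up).
#' When the smoother yields a pi0 outside (0, 1] the method falls back to
#' `pi0 = 1`, which reduces to Benjamini-Hochberg.
#'
#' @param p numeric p-values in \[0, 1\]; `NA`s are carried through.
#' @param lambda grid of tuning values for the pi0 estimate.
#' @param pi0 optional fixed pi0 overriding the smoother (e.g. `1` for BH).
#' @return numeric vector of q-values, same length and order as `p`, with the
#'   estimated pi0 attached as attribute `"pi0"`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.90, by = 0.05), pi0 = NULL) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    pi0 <- tryCatch({
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      predict(fit, x = max(lambda))$y
    }, error = function(e) NA_real_)
    if (is.na(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
  }
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  qv <- pmin(1, cummin(pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]))[ro]
  q[ok] <- qv
  attr(q, "pi0") <- pi0
  q
}
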