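# Thomas algorithm for tridiagonal systems, with multi right-hand sides.
# All implicit steps in the package funnel through this routine; the
# multi-RHS form is what makes the per-station transverse tissue solves cheap
# (one factorization sweep, vectorized over axial stations).

#' Solve a tridiagonal linear system
#'
#' @param lower subdiagonal, length `n - 1`.
#' @param diagonal main diagonal, length `n`.
#' @param upper superdiagonal, length `n - 1`.
#' @param b right-hand side: vector of length `n` or an `n x m` matrix
#'   (each column an independent RHS).
#' @return solution with the same shape as `b`.
#' @keywords internal
tridiag_solve <- function(lower, diagonal, upper, b) {
  n <- length(diagonal)
  vec_in <- is.null(dim(b))
  b <- as.matrix(b)
  if (nrow(b) != n) stop("RHS dimension mismatch in tridiagonal solve")
  if (any(!is.finite(diagonal)) || any(!is.finite(b))) {
    stop("non-finite inputs to tridiagonal solve")
  }
  cp <- numeric(n)
  dp <- matrix(0, n, ncol(b))
  piv <- diagonal[1]
  if (abs(piv) < 1e-300) stop("singular linear system (zero pivot)")
  if (n > 1) cp[1] <- upper[1] / piv
  dp[1, ] <- b[1, ] / piv
  if (n > 1) {
    for (i in 2:n) {
      piv <- diagonal[i] - lower[i - 1] * cp[i - 1]
      if (abs(piv) < 1e-300) stop("singular linear system (zero pivot)")
      if (i < n) cp[i] <- upper[i] / piv
      dp[i, ] <- (b[i, ] - lower[i - 1] * dp[i - 1, ]) / piv
    }
    for (i in (n - 1):1) {
      dp[i, ] <- dp[i, ] - cp[i] * dp[i + 1, ]
    }
  }
  if (vec_in) drop(dp) else dp
}
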