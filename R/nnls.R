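# Lawson-Hanson active-set non-negative least squares.
# Solves min_x ||A x - b||_2 subject to x >= 0.

#' Non-negative least squares
#'
#' Lawson-Hanson active-set algorithm. At convergence the
#' Karush-Kuhn-Tucker conditions hold: the gradient of the residual sum
#' of squares is zero on the passive (positive) set and non-negative on
#' the active (zero) set.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param tol tolerance on the dual feasibility check.
#' @param max_iter iteration cap (defaults to 10 * n).
#' @return list with `x` (non-negative coefficients), `residual`
#'   (Euclidean norm of `A x - b`), and `deviance` (residual sum of
#'   squares).
#' @export
nnls_fit <- function(A, b, tol = 1e-10, max_iter = 10L * ncol(A)) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  scale <- max(abs(crossprod(A, b)), 1)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))          # gradient of -0.5 RSS at x = 0
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol * scale) {
    iter <- iter + 1L
    if (iter > max_iter) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      fit <- tryCatch(
        qr.coef(qr(A[, P, drop = FALSE]), b),
        error = function(e) rep(NA_real_, length(P)))
      fit[is.na(fit)] <- 0
      z[P] <- fit
      if (all(z[P] > 0)) { x <- z; break }
      # step from x toward z until the first passive coefficient
      # reaches zero, then retire the vanished coefficients
      neg <- P[z[P] <= 0]
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio[!is.finite(ratio)] <- 0
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      x[neg][x[neg] <= tol] <- 0
      passive <- passive & x > 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x[x < 0] <- 0
  r <- drop(b - A %*% x)
  list(x = x, residual = sqrt(sum(r^2)), deviance = sum(r^2))
}
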