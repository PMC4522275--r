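#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `argmin_{x >= 0} ||A x - b||_2` with the classical Lawson-Hanson
#' active-set algorithm. Deterministic: when several candidate variables tie
#' for entry into the passive set, the lowest column index wins. This is the
#' per-pixel solver behind spectral unmixing, where `A` holds one endmember
#' spectrum per column and `b` is the observed pixel spectrum.
#'
#' @param A Numeric matrix, `B x K`, `B >= K`.
#' @param b Numeric vector of length `B`.
#' @param tol Tolerance on the dual (gradient) for optimality; default scales
#'   with the problem.
#' @return List with `coef` (length-K non-negative solution) and `resid`
#'   (Euclidean norm of `A coef - b`).
#' @export
#' @examples
#' A <- cbind(c(1, 1), c(1, 0))
#' nnls_solve(A, c(0, 0.5))$coef # c(0.25, 0)
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (!all(is.finite(A)) || !all(is.finite(b))) {
    stop("non-finite values in NNLS inputs")
  }
  K <- ncol(A)
  stopifnot(nrow(A) == length(b), nrow(A) >= K)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * K * max(1, max(abs(b)))

  x <- numeric(K)
  passive <- rep(FALSE, K)
  w <- drop(crossprod(A, b))          # gradient at x = 0
  it <- 0L
  max_it <- 30L * K

  while (any(!passive) && any(w[!passive] > tol) && it < max_it) {
    it <- it + 1L
    # entering variable: largest dual among active; which.max takes the
    # first (lowest-index) maximum, giving the deterministic tie-break
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE

    repeat {
      P <- which(passive)
      z <- numeric(K)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) break
      # step toward z until the first passive variable hits zero
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { z <- numeric(K); break }
    }
    x <- z
    w <- drop(crossprod(A, b - A %*% x))
  }
  x[x < 0] <- 0
  list(coef = x, resid = sqrt(sum((A %*% x - b)^2)))
}
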