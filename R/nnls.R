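# Lawson-Hanson active-set non-negative least squares:
# minimize ||A x - b||_2 subject to x >= 0.
# Classic algorithm; returns the solution, the passive (unconstrained) set
# and the residual norm. Deterministic.
nnls_fit <- function(A, b, tol = NULL, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * norm(A, "F") * max(m, n)
  if (is.null(max_iter)) max_iter <- 3L * n
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      zp <- tryCatch(
        qr.coef(qr(A[, P, drop = FALSE]), b),
        error = function(e) rep(NA_real_, length(P)))
      zp[is.na(zp)] <- 0
      if (all(zp > tol)) {
        x[] <- 0; x[P] <- zp
        break
      }
      # backtrack toward the feasible region
      neg <- which(zp <= tol)
      alpha <- min(x[P][neg] / (x[P][neg] - zp[neg]))
      x[P] <- x[P] + alpha * (zp - x[P])
      passive[P[x[P] <= tol]] <- FALSE
      x[x <= tol & !passive] <- 0
      if (!any(passive)) { x[] <- 0; break }
    }
    w <- crossprod(A, b - A %*% x)
  }
  list(x = x, passive = which(passive),
       rnorm = sqrt(sum((b - A %*% x)^2)))
}
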