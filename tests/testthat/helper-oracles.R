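# Independent brute-force implementations used as oracles. These are written
# directly from the defining formulas (normal equations, determinants,
# eigenvalues) and share no code with the package internals.

oracle_mglm <- function(Y, X) {
  Y <- cbind(Y)
  XtX <- t(X) %*% X
  B <- solve(XtX) %*% t(X) %*% Y
  E <- Y - X %*% B
  list(B = B, E = E, XtX_inv = solve(XtX),
       Sigma = t(E) %*% E / (nrow(X) - ncol(X)))
}

# Wilks lambda two ways: from determinants and from the eigenvalues of
# solve(E_sscp) %*% H, plus the exact c = 1 F transform.
oracle_wilks <- function(Y, X, C, L) {
  fit <- oracle_mglm(Y, X)
  CBL <- C %*% fit$B %*% L
  H <- t(CBL) %*% solve(C %*% fit$XtX_inv %*% t(C)) %*% CBL
  Esscp <- t(L) %*% t(fit$E) %*% fit$E %*% L
  lambda_det <- det(Esscp) / det(Esscp + H)
  ev <- eigen(solve(Esscp) %*% H, only.values = TRUE)$values
  lambda_eig <- prod(1 / (1 + Re(ev)))
  n <- nrow(X); k <- ncol(X); l <- ncol(L); cc <- nrow(C)
  out <- list(lambda_det = lambda_det, lambda_eig = lambda_eig)
  if (cc == 1) {
    out$df1 <- l
    out$df2 <- n - k - l + 1
    out$F <- ((1 - lambda_det) / lambda_det) * (out$df2 / out$df1)
  }
  out
}

# partial correlation of x and y given Z from the inverse correlation matrix
oracle_partial_cor <- function(x, y, Z) {
  Om <- solve(stats::cor(cbind(x, y, Z)))
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

# direct (shift-and-add) separable Gaussian smoothing of a 3D array
oracle_smooth3d <- function(arr, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  d <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, d)
    for (t in seq_along(k)) {
      off <- t - r - 1L
      for (i in seq_len(d[axis])) {
        j <- i + off
        if (j < 1 || j > d[axis]) next
        idx_to <- list(quote(expr =), quote(expr =), quote(expr =))
        idx_from <- idx_to
        idx_to[[axis]] <- i; idx_from[[axis]] <- j
        slab <- do.call(`[`, c(list(arr), idx_from, list(drop = FALSE)))
        cur <- do.call(`[`, c(list(out), idx_to, list(drop = FALSE)))
        out <- do.call(`[<-`, c(list(out), idx_to, list(cur + k[t] * slab)))
      }
    }
    arr <- out
  }
  arr
}
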