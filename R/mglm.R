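#' Fit a multivariate general linear model at one voxel
#'
#' Ordinary least squares fit of `Y = X B + E` for an n x p response matrix
#' (one column per modality) and an n x k design matrix, via the QR
#' decomposition of X. The residual covariance is estimated per voxel as
#' `Sigma_hat = E_hat' E_hat / (n - k)` under the assumption that the
#' covariance structure is common across subjects.
#'
#' @param Y n x p numeric matrix (a single voxel's multimodal observations),
#'   or an n-vector (treated as p = 1).
#' @param X n x k design matrix (see [build_design()]).
#' @return object of class `mglm` with elements `coefficients` (k x p),
#'   `residuals` (n x p), `fitted.values`, `sigma` (p x p), `df.residual`,
#'   `n`, `k`, `p`, `xtx_inv`, and the modality/column names.
#' @seealso [wilks_test()], [canonical_vectors()], [mglm_map()]
#' @export
mglm <- function(Y, X) {
  Y <- cbind(Y)
  X <- unclass(X)
  n <- nrow(X); k <- ncol(X); p <- ncol(Y)
  if (nrow(Y) != n) stop_cfg("Y and X must have the same number of rows")
  if (n <= k + p - 1)
    stop_cfg("n must exceed k + p - 1 for positive error df (n = ", n,
             ", k = ", k, ", p = ", p, ": deficit ", k + p - n, ")")
  qx <- qr(X)
  if (qx$rank < k) stop_cfg("design matrix is rank deficient")
  B <- qr.coef(qx, Y)
  fitted <- X %*% B
  E <- Y - fitted
  sigma <- crossprod(E) / (n - k)
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  rownames(B) <- colnames(X)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(p))
  colnames(B) <- colnames(Y)
  dimnames(sigma) <- list(colnames(Y), colnames(Y))
  structure(list(coefficients = B, residuals = E, fitted.values = fitted,
                 sigma = sigma, df.residual = n - k,
                 n = n, k = k, p = p, xtx_inv = xtx_inv,
                 modalities = colnames(Y), regressors = colnames(X)),
            class = "mglm")
}

#' @export
coef.mglm <- function(object, ...) object$coefficients

#' @export
residuals.mglm <- function(object, ...) object$residuals

#' @export
fitted.mglm <- function(object, ...) object$fitted.values

#' @export
print.mglm <- function(x, ...) {
  cat("Multivariate GLM fit: n =", x$n, ", k =", x$k, "regressors, p =",
      x$p, "responses\n\nCoefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.mglm <- function(object, contrast = NULL, ...) {
  res <- list(fit = object, wilks = NULL)
  if (is.null(contrast) && object$k >= 2)
    contrast <- age_contrast(object$k, object$p)
  if (!is.null(contrast)) res$wilks <- wilks_test(object, contrast)
  class(res) <- "summary.mglm"
  res
}

#' @export
print.summary.mglm <- function(x, ...) {
  print(x$fit)
  cat("\nResidual covariance (Sigma_hat):\n")
  print(x$fit$sigma)
  if (!is.null(x$wilks)) {
    cat("\n")
    print(x$wilks)
  }
  invisible(x)
}

# F statistic and df from Wilks' lambda. c = 1 (or l = 1) admits an exact F;
# otherwise Rao's approximation with t set to 1 when its radicand's
# denominator vanishes.
wilks_to_F <- function(lambda, n, k, l, cc) {
  if (cc == 1) {
    df1 <- l
    df2 <- n - k - l + 1
    Fst <- ((1 - lambda) / lambda) * (df2 / df1)
    return(list(F = Fst, df1 = df1, df2 = df2, exact = TRUE))
  }
  s <- l * cc
  denom <- l^2 + cc^2 - 5
  tt <- if (denom > 0) sqrt((l^2 * cc^2 - 4) / denom) else 1
  m <- n - k - (l - cc + 1) / 2
  df1 <- s
  df2 <- m * tt - s / 2 + 1
  lam_t <- lambda^(1 / tt)
  Fst <- ((1 - lam_t) / lam_t) * (df2 / df1)
  list(F = Fst, df1 = df1, df2 = df2, exact = (cc == 1 || l <= 2))
}

#' Test the hypothesis C B L = 0 through Wilks' lambda
#'
#' Forms the hypothesis SSCP `H = (C B L)' [C (X'X)^-1 C']^-1 (C B L)` and
#' the error SSCP `E = L' E_hat' E_hat L`, and computes
#' `lambda = det(E) / det(E + H)`. For a single-row contrast the statistic
#' has an exact F distribution with `(l, n - k - l + 1)` degrees of freedom;
#' otherwise Rao's F approximation is used (exact whenever `c = 1` or
#' `l <= 2`).
#'
#' @param fit an [mglm()] fit.
#' @param contrast an [mglm_contrast()] (or [age_contrast()]).
#' @return object of class `wilks_test`: `lambda`, `F`, `df1`, `df2`,
#'   `p.value`, `exact`, plus the `H` and `E_sscp` matrices.
#' @export
wilks_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "mglm"), inherits(contrast, "mglm_contrast"))
  C <- contrast$C; L <- contrast$L
  if (ncol(C) != fit$k) stop_cfg("C has ", ncol(C), " columns; design has k = ", fit$k)
  if (nrow(L) != fit$p) stop_cfg("L has ", nrow(L), " rows; fit has p = ", fit$p)
  CBL <- C %*% fit$coefficients %*% L
  W <- C %*% fit$xtx_inv %*% t(C)
  H <- t(CBL) %*% solve(W, CBL)
  Esscp <- t(L) %*% crossprod(fit$residuals) %*% L
  detE <- det(Esscp)
  if (!is.finite(detE) || detE <= 0)
    stop_cfg("singular error SSCP matrix (a tested variate is constant); ",
             "check mask hygiene / valid-mask construction")
  lambda <- detE / det(Esscp + H)
  fr <- wilks_to_F(lambda, fit$n, fit$k, contrast$l, contrast$c)
  structure(list(lambda = lambda, F = fr$F, df1 = fr$df1, df2 = fr$df2,
                 p.value = stats::pf(fr$F, fr$df1, fr$df2, lower.tail = FALSE),
                 exact = fr$exact, H = H, E_sscp = Esscp,
                 n = fit$n, k = fit$k, l = contrast$l, c = contrast$c),
            class = "wilks_test")
}

#' @export
print.wilks_test <- function(x, ...) {
  cat(sprintf("Wilks' lambda = %.5f, %s F(%g, %g) = %.4f, p = %.4g\n",
              x$lambda, if (x$exact) "exact" else "approximate",
              x$df1, x$df2, x$F, x$p.value))
  invisible(x)
}

#' Canonical vectors of a multivariate contrast
#'
#' Solves the generalized eigenproblem `H v = eigenvalue * E v` (H and E the
#' hypothesis and error SSCP matrices of the contrast) and returns the
#' eigenvectors sorted by descending eigenvalue. Wilks' lambda factorizes as
#' the product of `1 / (1 + eigenvalue_i)`. Each weight vector is scaled to
#' unit Euclidean norm by default (landing absolute weights in [0, 1]);
#' `normalize = "error"` rescales so that `v' (E/(n-k)) v = 1` instead. The
#' number of possible canonical variates is the smaller of the number of
#' tested dependent variables and the number of non-intercept regressors;
#' only `rank(H) = c` eigenvalues are nonzero for a rank-c hypothesis.
#' Because the vectors derive from an F-type test, only the magnitudes of the
#' weights are interpretable.
#'
#' @param fit an [mglm()] fit.
#' @param contrast an [mglm_contrast()].
#' @param normalize `"unit"` (default) or `"error"`.
#' @return object of class `canonical_result`: `weights` (l x l, columns =
#'   variates), `eigenvalues` (descending), `n_variates` (possible variates),
#'   `modalities`.
#' @export
canonical_vectors <- function(fit, contrast, normalize = c("unit", "error")) {
  normalize <- match.arg(normalize)
  wt <- wilks_test(fit, contrast)
  H <- wt$H; E <- wt$E_sscp
  l <- contrast$l
  U <- chol(E)
  Ui <- backsolve(U, diag(l))
  M <- t(Ui) %*% H %*% Ui
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- Ui %*% eig$vectors
  scl <- switch(normalize,
                unit = sqrt(colSums(vecs^2)),
                error = sqrt(colSums(vecs * ((E / (fit$n - fit$k)) %*% vecs))))
  vecs <- sweep(vecs, 2, scl, `/`)
  mods <- if (l == fit$p) fit$modalities else paste0("variate", seq_len(l))
  rownames(vecs) <- mods
  colnames(vecs) <- paste0("can", seq_len(l))
  structure(list(weights = vecs, eigenvalues = vals,
                 n_variates = min(l, fit$k - 1L),
                 rank_h = contrast$c, modalities = mods),
            class = "canonical_result")
}

#' @export
print.canonical_result <- function(x, ...) {
  cat("Canonical decomposition:", x$n_variates, "possible variate(s),",
      "hypothesis rank", x$rank_h, "\nEigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\nAbsolute weights (columns = variates):\n")
  print(abs(x$weights))
  invisible(x)
}
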