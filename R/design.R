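#' Build the shared n x k design matrix
#'
#' The first column is the intercept (all ones); the remaining columns are
#' mean-centred regressors in the order age, TIV, gender, scanner. The two
#' categorical covariates must have exactly two levels and are coded 0/1
#' before centring (F-tests on any single column are invariant to affine
#' recoding, so this choice is inconsequential for inference).
#'
#' @param cov covariate table with columns `age`, `tiv`, `gender`, `scanner`.
#' @return a numeric matrix of class `mglm_design` with column names
#'   `intercept`, `age`, `tiv`, `gender`, `scanner`.
#' @export
build_design <- function(cov) {
  req <- c("age", "tiv", "gender", "scanner")
  if (!all(req %in% names(cov)))
    stop_cfg("covariates must contain: ", paste(req, collapse = ", "))
  if (anyNA(cov[req])) stop_cfg("covariates contain missing values")
  n <- nrow(cov)
  code2 <- function(x, what) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) > 2)
      stop_cfg(what, " has ", length(lev), " levels; the default single-column",
               " coding supports exactly 2 - extend the coding rule")
    as.numeric(as.character(x) == lev[length(lev)])
  }
  X <- cbind(intercept = rep(1, n),
             age = cov$age - mean(cov$age),
             tiv = cov$tiv - mean(cov$tiv),
             gender = code2(cov$gender, "gender"),
             scanner = code2(cov$scanner, "scanner"))
  X[, -1] <- sweep(X[, -1, drop = FALSE], 2, colMeans(X[, -1, drop = FALSE]))
  k <- ncol(X)
  if (qr(X)$rank < k)
    stop_cfg("design matrix is rank deficient (a regressor is constant or ",
             "collinear)")
  structure(X, class = c("mglm_design", class(X)))
}

#' @export
print.mglm_design <- function(x, ...) {
  cat("Design matrix:", nrow(x), "subjects x", ncol(x), "columns (",
      paste(colnames(x), collapse = ", "), ")\n")
  invisible(x)
}

#' Write / read a design matrix as TSV for audit
#'
#' @param X design matrix.
#' @param path TSV path.
#' @export
write_design <- function(X, path) {
  utils::write.table(as.data.frame(unclass(X)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  structure(m, class = c("mglm_design", class(m)))
}

#' Construct a hypothesis contrast for the multivariate GLM
#'
#' The null hypothesis is `C B L = 0`: `C` (c x k) selects combinations of
#' regressors (rows of B), `L` (p x l) selects combinations of modalities
#' (columns of B).
#'
#' @param C c x k row-contrast matrix with linearly independent rows.
#' @param L p x l column-contrast matrix with linearly independent columns.
#' @return object of class `mglm_contrast`.
#' @export
mglm_contrast <- function(C, L) {
  C <- rbind(C); L <- cbind(L)
  if (qr(C)$rank < nrow(C)) stop_cfg("rows of C must be linearly independent")
  if (qr(L)$rank < ncol(L)) stop_cfg("columns of L must be linearly independent")
  structure(list(C = C, L = L, c = nrow(C), l = ncol(L)),
            class = "mglm_contrast")
}

#' The single-row age contrast with identity modality contrast
#'
#' `C` has a single 1 in the age position (column 2 of the default design)
#' and `L` is the p x p identity: a MANOVA-style test of the joint age
#' effect across all modalities.
#'
#' @param k number of design columns (>= 2).
#' @param p number of modalities.
#' @param age_col column index of the age regressor (default 2).
#' @return an `mglm_contrast`.
#' @export
age_contrast <- function(k, p, age_col = 2L) {
  if (k < 2) stop_cfg("k must be >= 2")
  C <- matrix(0, 1, k)
  C[1, age_col] <- 1
  mglm_contrast(C, diag(p))
}

#' @export
print.mglm_contrast <- function(x, ...) {
  cat("Hypothesis contrast C B L = 0: c =", x$c, "row(s), l =", x$l,
      "tested variate(s)\n")
  invisible(x)
}
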