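#' Fit voxelwise univariate GLMs for one modality
#'
#' Least-squares fit of every voxel's across-subject values on a shared
#' design matrix, vectorized over voxels.
#'
#' @param Y n x V matrix (columns = voxels) or an n-vector.
#' @param X n x k design matrix of full column rank.
#' @return object of class `uglm_fit`: `beta` (k x V), `rss` (V),
#'   `df.residual` (= n - k), `xtx_inv`, and the design.
#' @export
fit_uglm <- function(Y, X) {
  Y <- cbind(Y)
  X <- unclass(X)
  n <- nrow(X); k <- ncol(X)
  if (nrow(Y) != n) stop_cfg("Y and X must have the same number of rows")
  qx <- qr(X)
  if (qx$rank < k) stop_cfg("design matrix is rank deficient")
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  structure(list(beta = beta, rss = colSums(res^2), df.residual = n - k,
                 xtx_inv = chol2inv(qr.R(qx)), X = X, n = n, k = k),
            class = "uglm_fit")
}

#' F-test of a single-row contrast on a voxelwise univariate fit
#'
#' Per voxel, `F = (c beta)^2 / (c (X'X)^-1 c' * rss / (n - k))` with
#' `(1, n - k)` degrees of freedom. Voxels with zero residual variance
#' (possible only on noiseless synthetic input) get `p = 0` with a warning
#' and are flagged in `degenerate`.
#'
#' @param fit a [fit_uglm()] result.
#' @param contrast_row length-k numeric contrast vector.
#' @return list with per-voxel `F` and `p` vectors, `df1`, `df2`, and a
#'   logical `degenerate` vector.
#' @export
f_test <- function(fit, contrast_row) {
  stopifnot(inherits(fit, "uglm_fit"))
  uglm_f_values(fit, contrast_row)
}

# F statistic of a single-row contrast on a uglm_fit; returns vectors.
# rss = 0 voxels (noiseless input) get p = 0 and are flagged.
uglm_f_values <- function(fit, contrast_row) {
  crow <- rbind(c(contrast_row))
  if (ncol(crow) != fit$k) stop_cfg("contrast row must have k = ", fit$k,
                                    " entries")
  s <- drop(crow %*% fit$xtx_inv %*% t(crow))
  cb <- drop(crow %*% fit$beta)
  mse <- fit$rss / fit$df.residual
  degenerate <- mse <= 0
  Fst <- (cb^2) / (s * pmax(mse, .Machine$double.xmin))
  pval <- stats::pf(Fst, 1, fit$df.residual, lower.tail = FALSE)
  if (any(degenerate)) {
    warning("zero residual variance at ", sum(degenerate),
            " voxel(s); p set to 0 there (noiseless input)")
    Fst[degenerate] <- Inf
    pval[degenerate] <- 0
  }
  list(F = Fst, p = pval, df1 = 1, df2 = fit$df.residual,
       degenerate = degenerate)
}

#' Voxelwise univariate F-map for a single-row contrast
#'
#' Fits the univariate GLM at every in-mask voxel of one modality and
#' computes the F statistic of the contrast with (1, n - k) degrees of
#' freedom.
#'
#' @param ds standardized `multimodal_dataset` (see [standardize_dataset()]).
#' @param modality modality name.
#' @param design n x k design matrix.
#' @param mask binary 3D array (default: the dataset's analysis mask).
#' @param contrast_row length-k contrast vector (default: the age column).
#' @return object of class `stat_map` with `stat_kind = "F_uni"`.
#' @export
uglm_map <- function(ds, modality, design, mask = NULL, contrast_row = NULL) {
  stopifnot(inherits(ds, "multimodal_dataset"))
  if (!isTRUE(ds$standardized))
    stop_cfg("dataset must be standardized first (standardize_dataset)")
  if (!modality %in% ds$modalities) stop_cfg("unknown modality: ", modality)
  mask <- (mask %||% ds$analysis_mask)
  if (is.null(mask)) stop_cfg("no mask supplied and dataset has no analysis_mask")
  if (sum(mask != 0) == 0) stop_cfg("empty mask")
  X <- unclass(design)
  k <- ncol(X)
  if (is.null(contrast_row)) {
    contrast_row <- rep(0, k)
    contrast_row[2] <- 1
  }
  Y <- flatten_stack(ds$stacks[[modality]], mask)
  fit <- fit_uglm(Y, X)
  fv <- uglm_f_values(fit, contrast_row)
  stat_map(stat = unflatten(fv$F, mask),
           p_uncorrected = unflatten(fv$p, mask),
           mask = (mask != 0) * 1L,
           df = c(fv$df1, fv$df2),
           stat_kind = "F_uni",
           n = fit$n, k = k,
           modality = modality)
}

#' Construct a per-voxel statistic map
#'
#' @param stat 3D array of statistic values (NA outside the mask).
#' @param p_uncorrected 3D array of uncorrected p-values.
#' @param mask binary 3D array.
#' @param df degrees of freedom (numerator, denominator).
#' @param stat_kind `"F_uni"` or `"wilks_F"`.
#' @param ... further fields stored on the object (e.g. `lambda`,
#'   `canonical`, `n`, `k`, `l`, `c`, `modality`).
#' @return object of class `stat_map`.
#' @export
stat_map <- function(stat, p_uncorrected, mask, df, stat_kind, ...) {
  structure(c(list(stat = stat, p_uncorrected = p_uncorrected, mask = mask,
                   df = df, stat_kind = stat_kind), list(...)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$stat[x$mask != 0]
  cat(sprintf("Statistic map [%s], df = (%g, %g), %d in-mask voxels\n",
              x$stat_kind, x$df[1], x$df[2], sum(x$mask != 0)))
  cat(sprintf("  stat range: %.3f .. %.3f; min uncorrected p: %.3g\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              min(x$p_uncorrected[x$mask != 0], na.rm = TRUE)))
  invisible(x)
}

#' Plot a statistic map slice
#'
#' @param x a `stat_map`.
#' @param z slice index (default: middle slice).
#' @param ... passed to [graphics::image()].
#' @export
plot.stat_map <- function(x, z = NULL, ...) {
  d <- dim(x$stat)
  z <- z %||% ceiling(d[3] / 2)
  sl <- x$stat[, , z]
  sl[x$mask[, , z] == 0] <- NA
  graphics::image(seq_len(d[1]), seq_len(d[2]), sl,
                  xlab = "x", ylab = "y",
                  main = sprintf("%s map, slice z = %d", x$stat_kind, z), ...)
  invisible(x)
}

#' Write a statistic map as NIfTI with a JSON sidecar
#'
#' @param map a `stat_map`.
#' @param prefix path prefix; writes `<prefix>_stat.nii.gz`,
#'   `<prefix>_p.nii.gz` and `<prefix>.json` (plus lambda / canonical-weight
#'   volumes when present).
#' @return invisibly, the written file paths.
#' @export
write_stat_map <- function(map, prefix) {
  files <- c(paste0(prefix, "_stat.nii.gz"), paste0(prefix, "_p.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(ifelse(is.na(map$stat), 0, map$stat)),
                     files[1])
  RNifti::writeNifti(RNifti::asNifti(ifelse(is.na(map$p_uncorrected), 1,
                                            map$p_uncorrected)), files[2])
  if (!is.null(map$lambda)) {
    f <- paste0(prefix, "_lambda.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(ifelse(is.na(map$lambda), 1, map$lambda)), f)
    files <- c(files, f)
  }
  if (!is.null(map$canonical)) {
    for (j in seq_len(dim(map$canonical)[4])) {
      f <- sprintf("%s_canweight_%s.nii.gz", prefix,
                   map$modalities[j] %||% paste0("m", j))
      w <- map$canonical[, , , j]
      RNifti::writeNifti(RNifti::asNifti(ifelse(is.na(w), 0, abs(w))), f)
      files <- c(files, f)
    }
  }
  side <- list(stat_kind = map$stat_kind, df = map$df, n = map$n, k = map$k,
               l = map$l, c = map$c, modality = map$modality,
               modalities = map$modalities)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(side[!vapply(side, is.null, TRUE)], js,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, js))
}
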