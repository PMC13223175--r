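#' Fisher z transform of a correlation and its standard error
#'
#' `fisher_z(r) = atanh(r)`. The default standard error is the classic
#' `1 / sqrt(n - 3)`; `adjusted = TRUE` subtracts the number of partialled
#' nuisance covariates as well (`1 / sqrt(n - g - 3)`).
#'
#' @param r correlation in (-1, 1).
#' @export
fisher_z <- function(r) atanh(r)

#' @rdname fisher_z
#' @param n number of subjects.
#' @param n_nuisance number of partialled nuisance covariates g.
#' @param adjusted use the covariate-adjusted denominator.
#' @export
fisher_z_se <- function(n, n_nuisance = 0, adjusted = FALSE) {
  d <- if (adjusted) n - n_nuisance - 3 else n - 3
  if (d <= 0) stop_cfg("too few subjects for a Fisher z standard error")
  1 / sqrt(d)
}

#' Extract per-subject ROI medians for every modality
#'
#' The median over the ROI's in-mask voxels of the (standardized) maps, per
#' subject and modality.
#'
#' @param ds standardized `multimodal_dataset`.
#' @param roi_mask binary 3D array.
#' @param mask analysis mask intersected with the ROI (default: the
#'   dataset's analysis mask).
#' @param roi_name used in error messages.
#' @return n x p matrix of medians (columns = modalities).
#' @export
extract_roi_medians <- function(ds, roi_mask, mask = NULL, roi_name = "ROI") {
  stopifnot(inherits(ds, "multimodal_dataset"))
  mask <- mask %||% ds$analysis_mask %||% array(1L, ds$grid_shape)
  m <- (roi_mask != 0) & (mask != 0)
  if (!any(m)) stop_cfg("ROI '", roi_name, "' does not intersect the analysis mask")
  out <- vapply(ds$modalities, function(mod) {
    Y <- flatten_stack(ds$stacks[[mod]], m)      # n x V
    apply(Y, 1, stats::median)
  }, numeric(ds$n))
  out <- matrix(out, nrow = ds$n,
                dimnames = list(ds$covariates$participant_id, ds$modalities))
  out
}

# residualize a vector (or matrix columns) on an intercept plus nuisance
residualize <- function(y, nuisance = NULL) {
  n <- NROW(y)
  Z <- cbind(rep(1, n), nuisance)
  qz <- qr(Z)
  y - qr.fitted(qz, cbind(y))[, 1]
}

#' Partial correlation of ROI medians with age
#'
#' Both the medians and age are residualized on an intercept plus the
#' nuisance covariates (Frisch-Waugh partialling); the partial correlation
#' is the Pearson correlation of the two residual vectors. The p-value uses
#' the t transform with `df = n - 2 - g` (g = number of nuisance columns);
#' the Fisher z effect size and its standard error accompany it. A linear
#' trend of the adjusted medians on adjusted age is fitted for plotting.
#'
#' @param medians per-subject values (e.g. one column of
#'   [extract_roi_medians()]).
#' @param age per-subject ages.
#' @param nuisance data.frame or matrix of nuisance covariates (gender, TIV,
#'   scanner), or `NULL` for a plain Pearson correlation.
#' @param adjusted_se use the covariate-adjusted Fisher z standard error.
#' @return object of class `roi_result`: `r_partial`, `p_value`,
#'   `fisher_z`, `se_z`, `n`, `df`, `slope`, `intercept`.
#' @export
partial_correlation <- function(medians, age, nuisance = NULL,
                                adjusted_se = FALSE) {
  n <- length(age)
  if (length(medians) != n) stop_cfg("medians and age lengths differ")
  N <- if (is.null(nuisance)) NULL else {
    nm <- as.data.frame(nuisance)
    mm <- do.call(cbind, lapply(nm, function(col) {
      if (is.numeric(col)) col else as.numeric(factor(col))
    }))
    mm
  }
  g <- if (is.null(N)) 0L else ncol(N)
  if (n < 5 + g) stop_cfg("need at least ", 5 + g, " subjects")
  yr <- residualize(medians, N)
  ar <- residualize(age, N)
  tol_y <- 1e-10 * max(1, max(abs(medians)))
  tol_a <- 1e-10 * max(1, max(abs(age)))
  if (stats::sd(yr) <= tol_y || stats::sd(ar) <= tol_a)
    stop_cfg("zero-variance residuals; partial correlation undefined")
  r <- stats::cor(yr, ar)
  df <- n - 2L - g
  tt <- r * sqrt(df / (1 - r^2))
  pval <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  trend <- linear_age_trend(yr, ar)
  structure(list(r_partial = r, p_value = pval,
                 fisher_z = fisher_z(r),
                 se_z = fisher_z_se(n, g, adjusted = adjusted_se),
                 n = n, df = df, n_nuisance = g,
                 slope = trend$slope, intercept = trend$intercept),
            class = "roi_result")
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("partial r = %.3f (p = %.3g, df = %d), Fisher z = %.3f (SE %.3f)\n",
              x$r_partial, x$p_value, x$df, x$fisher_z, x$se_z))
  invisible(x)
}

#' Ordinary least-squares age trend of ROI medians
#'
#' @param medians per-subject values.
#' @param age per-subject ages (possibly residualized).
#' @return list with `slope`, `intercept`, `fitted`.
#' @export
linear_age_trend <- function(medians, age) {
  if (length(age) < 3) stop_cfg("need at least 3 subjects")
  if (stats::sd(age) == 0) stop_cfg("age is constant; trend undefined")
  fit <- stats::lm.fit(cbind(1, age), cbind(medians))
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       fitted = drop(cbind(1, age) %*% fit$coefficients))
}

#' Absolute canonical weights at an ROI's peak voxel
#'
#' The peak is the in-ROI voxel with the largest multivariate F; the first
#' canonical weight vector there (unit Euclidean norm, absolute values)
#' gives each modality's contribution to the multivariate age effect at
#' that location - a peak-voxel property, not an ROI-wide contribution.
#'
#' @param map a `stat_map` from [mglm_map()] with a canonical store.
#' @param roi_mask binary 3D array.
#' @return list with `weights` (named, absolute, unit norm), `peak`
#'   (voxel coordinate) and `peak_stat`.
#' @export
peak_canonical_vector <- function(map, roi_mask) {
  m <- (roi_mask != 0) & (map$mask != 0)
  if (!any(m)) stop_cfg("ROI does not intersect the map's mask")
  vox <- which(m)
  pk <- vox[which.max(map$stat[vox])]
  ijk <- arrayInd(pk, dim(map$mask))[1, ]
  list(weights = canonical_at(map, ijk, absolute = TRUE),
       peak = ijk, peak_stat = map$stat[pk])
}

#' ROI partial-correlation table across regions and modalities
#'
#' For every ROI label and modality: extract per-subject medians, partial
#' out gender, TIV and scanner, and correlate with age; mirrors a
#' region-by-modality report of Pearson partial r, p, Fisher z and its SE.
#'
#' @param ds standardized `multimodal_dataset`.
#' @param roi_labels integer 3D array of ROI codes (0 = background); default
#'   the dataset's region labels.
#' @param roi_names optional named integer vector mapping names to codes.
#' @param adjusted_se see [partial_correlation()].
#' @return `data.frame` with columns `roi`, `modality`, `r`, `p`,
#'   `fisher_z`, `se_z`, `n`.
#' @export
roi_table <- function(ds, roi_labels = NULL, roi_names = NULL,
                      adjusted_se = FALSE) {
  stopifnot(inherits(ds, "multimodal_dataset"))
  roi_labels <- roi_labels %||% ds$region_labels
  codes <- sort(setdiff(unique(as.vector(roi_labels)), 0))
  if (is.null(roi_names)) {
    roi_names <- stats::setNames(codes, paste0("region", codes))
  }
  nuis <- ds$covariates[, c("gender", "tiv", "scanner")]
  rows <- list()
  for (nm in names(roi_names)) {
    mask <- (roi_labels %in% roi_names[[nm]]) * 1L
    dim(mask) <- dim(roi_labels)
    med <- tryCatch(extract_roi_medians(ds, mask, roi_name = nm),
                    error = function(e) NULL)
    if (is.null(med)) {
      warning("skipping ROI '", nm, "': no voxels in the analysis mask")
      next
    }
    for (mod in ds$modalities) {
      pc <- partial_correlation(med[, mod], ds$covariates$age, nuis,
                                adjusted_se = adjusted_se)
      rows[[length(rows) + 1L]] <-
        data.frame(roi = nm, modality = mod, r = pc$r_partial,
                   p = pc$p_value, fisher_z = pc$fisher_z, se_z = pc$se_z,
                   n = pc$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
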