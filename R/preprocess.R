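#' Z-score a modality stack per voxel across subjects
#'
#' Each in-mask voxel is centred by its across-subject mean and scaled by its
#' across-subject standard deviation (n-1 denominator), making modalities
#' with different native units comparable. Voxels whose standard deviation
#' falls below `sd_floor` are removed from the valid mask rather than set to
#' zero, since a constant column would distort downstream cluster statistics.
#'
#' @param stack 4D (x, y, z, subject) array with at least 3 subjects.
#' @param mask binary 3D array of voxels to standardize (default: all).
#' @param sd_floor minimum admissible across-subject standard deviation.
#' @param modality optional modality name carried through.
#' @return object of class `standardized_stack`: list with `values` (4D, NA
#'   outside the valid mask), `valid_mask`, and `modality`.
#' @export
zscore_across_subjects <- function(stack, mask = NULL, sd_floor = 1e-8,
                                   modality = NULL) {
  d <- dim(stack)
  stopifnot(length(d) == 4L)
  n <- d[4]
  if (n < 3) stop_cfg("z-scoring requires at least 3 subjects (got ", n, ")")
  if (is.null(mask)) mask <- array(1L, d[1:3])
  if (!all(dim(mask) == d[1:3])) stop_cfg("mask grid mismatch")
  Y <- flatten_stack(stack, mask)              # n x V
  mu <- colMeans(Y)
  sdv <- sqrt(colSums(sweep(Y, 2, mu)^2) / (n - 1))
  ok <- sdv >= sd_floor
  Z <- sweep(sweep(Y, 2, mu), 2, pmax(sdv, sd_floor), `/`)
  Z[, !ok] <- NA_real_
  vox <- which(mask != 0)
  values <- array(NA_real_, d)
  flat <- matrix(values, nrow = prod(d[1:3]), ncol = n)
  flat[vox, ] <- t(Z)
  valid <- array(0L, d[1:3])
  valid[vox[ok]] <- 1L
  structure(list(values = array(flat, d), valid_mask = valid,
                 modality = modality),
            class = "standardized_stack")
}

#' @export
print.standardized_stack <- function(x, ...) {
  cat("Standardized stack", if (!is.null(x$modality)) paste0("(", x$modality, ")"),
      ":", sum(x$valid_mask), "valid voxels,", dim(x$values)[4], "subjects\n")
  invisible(x)
}

#' Make two tissue masks mutually exclusive
#'
#' Voxels claimed by both masks are removed from both, yielding explicit
#' non-overlapping GM and WM analysis masks.
#'
#' @param gm,wm binary 3D arrays on the same grid.
#' @return list with disjoint `gm` and `wm` binary arrays.
#' @export
build_exclusive_masks <- function(gm, wm) {
  if (!all(dim(gm) == dim(wm))) stop_cfg("mask shapes differ")
  overlap <- (gm != 0) & (wm != 0)
  list(gm = ((gm != 0) & !overlap) * 1L,
       wm = ((wm != 0) & !overlap) * 1L)
}

#' Standardize every modality of a dataset within an analysis mask
#'
#' Applies [zscore_across_subjects()] per modality within `mask` and stores
#' the resulting analysis mask: the intersection of `mask` with all
#' modalities' valid masks, so the multivariate data matrix is complete at
#' every analyzed voxel.
#'
#' @param ds a `multimodal_dataset`.
#' @param mask binary 3D array (default: union of the exclusive GM/WM masks).
#' @param sd_floor see [zscore_across_subjects()].
#' @return a `multimodal_dataset` with z-scored stacks, `standardized = TRUE`
#'   and an `analysis_mask` element.
#' @export
standardize_dataset <- function(ds, mask = NULL, sd_floor = 1e-8) {
  stopifnot(inherits(ds, "multimodal_dataset"))
  excl <- build_exclusive_masks(ds$gm_mask, ds$wm_mask)
  if (is.null(mask)) mask <- (excl$gm | excl$wm) * 1L
  valid <- (mask != 0) * 1L
  zs <- vector("list", length(ds$modalities))
  names(zs) <- ds$modalities
  for (m in ds$modalities) {
    z <- zscore_across_subjects(ds$stacks[[m]], mask, sd_floor, modality = m)
    zs[[m]] <- z
    valid <- valid * z$valid_mask
  }
  out <- ds
  out$stacks <- lapply(zs, `[[`, "values")
  out$standardized <- TRUE
  out$analysis_mask <- valid
  out
}
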