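#' @keywords internal
#' @importFrom stats rnorm rbinom runif dnorm pf pt cor sd median quantile
#'   setNames lm.fit
#' @importFrom utils read.table write.table modifyList packageVersion
#' @importFrom graphics image
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a Gaussian FWHM to its standard deviation
#'
#' @param fwhm full width at half maximum, in voxels.
#' @return standard deviation in voxels.
#' @keywords internal
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Normalized 1D Gaussian kernel truncated at 3 sigma. fwhm <= 0 gives the
# identity kernel.
gaussian_kernel1d <- function(fwhm_vox) {
  if (fwhm_vox <= 0) return(1)
  sigma <- fwhm_to_sigma(fwhm_vox)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

# Convolve an array along one axis with zero padding outside the grid,
# implemented as a banded-matrix multiply on the axis brought to the front.
# Works for any dimensionality; only `axis` is touched, so a 4D
# (x, y, z, subject) stack is smoothed per subject in one call.
convolve_axis <- function(arr, kernel, axis) {
  nk <- length(kernel)
  if (nk == 1L) return(arr * kernel)
  d <- dim(arr)
  r <- (nk - 1L) %/% 2L
  n_ax <- d[axis]
  K <- matrix(0, n_ax, n_ax)
  for (t in seq_len(nk)) {
    off <- t - r - 1L
    i <- seq.int(max(1L, 1L - off), min(n_ax, n_ax - off))
    if (length(i)) K[cbind(i, i + off)] <- kernel[t]
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  ap <- if (axis == 1L) arr else aperm(arr, perm)
  m <- K %*% matrix(ap, n_ax)
  dim(m) <- d[perm]
  if (axis == 1L) m else aperm(m, order(perm))
}

#' Smooth the spatial axes of a 3D or 4D array with a separable Gaussian
#'
#' The first three dimensions are treated as space; any fourth dimension
#' (e.g. subjects) is left untouched. The kernel is truncated at three
#' standard deviations and zero padding is used at the grid boundary.
#'
#' @param arr 3D or 4D numeric array.
#' @param fwhm_vox kernel full width at half maximum in voxel units;
#'   `0` returns the input unchanged.
#' @return array of the same shape.
#' @export
smooth_gaussian <- function(arr, fwhm_vox) {
  stopifnot(is.array(arr), length(dim(arr)) %in% c(3L, 4L), fwhm_vox >= 0)
  if (fwhm_vox == 0) return(arr)
  k <- gaussian_kernel1d(fwhm_vox)
  for (axis in 1:3) arr <- convolve_axis(arr, k, axis)
  arr
}

# Flatten a (x, y, z, n) stack to an n x V matrix over the nonzero voxels of
# `mask`, in the order of which(mask != 0).
flatten_stack <- function(stack, mask) {
  d <- dim(stack)
  stopifnot(length(d) == 4L, all(d[1:3] == dim(mask)))
  vox <- which(mask != 0)
  n <- d[4]
  m <- matrix(stack, nrow = prod(d[1:3]), ncol = n)
  t(m[vox, , drop = FALSE])
}

# Place a V-vector of per-voxel values back into a 3D array (fill elsewhere).
unflatten <- function(values, mask, fill = NA_real_) {
  out <- array(fill, dim(mask))
  out[which(mask != 0)] <- values
  out
}

# Vectorized determinants of many small symmetric matrices. `cols` is a list
# of length p*p of V-vectors holding entry (j, k) at [[(k-1)*p + j]].
# Recursive cofactor expansion along the first row; intended for p <= 4 where
# the per-voxel 4x4 determinants of the error and total SSCP matrices must be
# computed over thousands of voxels without an R-level loop.
det_vec <- function(cols, p) {
  if (p == 1L) return(cols[[1L]])
  if (p == 2L) return(cols[[1L]] * cols[[4L]] - cols[[2L]] * cols[[3L]])
  res <- 0
  for (k in seq_len(p)) {
    keep_cols <- setdiff(seq_len(p), k)
    minor <- vector("list", (p - 1L)^2)
    for (kk in seq_along(keep_cols)) {
      for (jj in seq_len(p - 1L)) {
        minor[[(kk - 1L) * (p - 1L) + jj]] <-
          cols[[(keep_cols[kk] - 1L) * p + jj + 1L]]
      }
    }
    term <- cols[[(k - 1L) * p + 1L]] * det_vec(minor, p - 1L)
    res <- if (k %% 2L == 1L) res + term else res - term
  }
  res
}

# Deterministic derivation of stage/repetition sub-seeds from one master seed,
# kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 1009 * as.double(offset)) %%
               2147483647)
}

stop_cfg <- function(...) stop(..., call. = FALSE)

as_binary_array <- function(x, name = "mask") {
  if (inherits(x, "thresholded_map")) x <- x$binary
  if (!is.array(x)) stop_cfg(name, " must be a 3D array")
  (x != 0) * 1L
}
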