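#' Bonferroni division of a family-level alpha across maps
#'
#' When the same inference is run on m maps (e.g. 4 modalities), the
#' family-level alpha is divided by m, e.g. 0.05 / 4 = 0.0125.
#'
#' @param alpha family-level significance level in (0, 1).
#' @param m number of maps (>= 1).
#' @return per-map alpha.
#' @export
bonferroni_across_maps <- function(alpha, m) {
  if (m < 1) stop_cfg("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_cfg("alpha must lie in (0, 1)")
  alpha / m
}

#' Construct a thresholded (binary significance) map
#'
#' @param binary binary 3D array of significant voxels.
#' @param mask analysis mask.
#' @param alpha nominal FWER level.
#' @param method `"bonferroni_voxel"` or `"permutation_maxstat"`.
#' @param stat optional 3D statistic array used for cluster peaks.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param ... further fields (e.g. `threshold`, `null_max`, `p_fwer`).
#' @return object of class `thresholded_map` with `labels` and
#'   `cluster_table` filled in.
#' @export
thresholded_map <- function(binary, mask, alpha, method, stat = NULL,
                            connectivity = 18, ...) {
  binary <- (binary != 0) * 1L
  lab <- label_clusters(binary, connectivity, stat = stat)
  structure(c(list(binary = binary, labels = lab$labels,
                   cluster_table = lab$cluster_table, alpha = alpha,
                   method = method, mask = (mask != 0) * 1L,
                   connectivity = connectivity, stat = stat),
              list(...)),
            class = "thresholded_map")
}

#' @export
print.thresholded_map <- function(x, ...) {
  ct <- x$cluster_table
  nvox <- sum(x$binary)
  rng <- if (nrow(ct)) paste0(min(ct$size_voxels), "-", max(ct$size_voxels)) else "-"
  cat(sprintf("Thresholded map (%s, alpha = %g):\n", x$method, x$alpha))
  cat(sprintf("  #Clusters %d | Cluster size range %s | #Voxels %d\n",
              nrow(ct), rng, nvox))
  invisible(x)
}

#' Table 1/2-style cluster summary of a thresholded map
#'
#' @param x a `thresholded_map`.
#' @param name row label.
#' @return one-row `data.frame` with `n_clusters`, `min_size`, `max_size`,
#'   `n_voxels`.
#' @export
cluster_summary <- function(x, name = "map") {
  ct <- x$cluster_table
  data.frame(map = name, n_clusters = nrow(ct),
             min_size = if (nrow(ct)) min(ct$size_voxels) else 0L,
             max_size = if (nrow(ct)) max(ct$size_voxels) else 0L,
             n_voxels = sum(x$binary), stringsAsFactors = FALSE)
}

#' Voxel-level Bonferroni FWER thresholding
#'
#' A voxel is significant when its uncorrected p-value is below
#' `alpha / (number of in-mask voxels)`. Conservative under positive
#' dependence (smooth maps); exact FWER control is provided by
#' [fwer_permutation_maxstat()].
#'
#' @param map a `stat_map`.
#' @param alpha nominal FWER level.
#' @param connectivity cluster connectivity.
#' @return a `thresholded_map` with `method = "bonferroni_voxel"`.
#' @export
fwer_voxel_bonferroni <- function(map, alpha = 0.05, connectivity = 18) {
  stopifnot(inherits(map, "stat_map"))
  V <- sum(map$mask != 0)
  if (V == 0) stop_cfg("empty mask")
  sig <- array(0L, dim(map$mask))
  vox <- which(map$mask != 0)
  sig[vox] <- as.integer(map$p_uncorrected[vox] < alpha / V)
  thresholded_map(sig, map$mask, alpha, "bonferroni_voxel", stat = map$stat,
                  connectivity = connectivity, threshold_p = alpha / V)
}

# Fast permutation refit: precomputes the reduced-model projection for the
# Freedman-Lane scheme and reuses the vectorized Wilks engine per
# permutation. modalities = one name gives the univariate (p = 1) max-|F|.
#' Permutation max-statistic FWER thresholding
#'
#' Estimates the null distribution of the maximum statistic over the mask by
#' refitting the model under subject-level permutations applied jointly to
#' all modalities (preserving the cross-modality covariance under the null).
#' The default Freedman-Lane scheme permutes the residuals of the reduced
#' (nuisance-only) model around its fitted values; `scheme = "simple"`
#' permutes the rows of the data directly. A voxel is significant when its
#' FWER-corrected p-value, `(1 + #{null max >= stat}) / (n_perm + 1)`, is at
#' most `alpha`.
#'
#' @param ds standardized `multimodal_dataset`.
#' @param design n x k design matrix.
#' @param contrast an [mglm_contrast()]; default [age_contrast()]. With
#'   `modalities` of length 1 the statistic is the univariate F.
#' @param mask binary 3D array (default: the dataset's analysis mask).
#' @param alpha nominal FWER level; must be >= 1 / (n_perm + 1).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for reproducible permutations.
#' @param scheme `"freedman_lane"` or `"simple"`.
#' @param modalities modalities entering the model (default: all).
#' @param connectivity cluster connectivity.
#' @return a `thresholded_map` with `method = "permutation_maxstat"`, plus
#'   `null_max` (the permutation distribution of the maximum statistic),
#'   `threshold` (its 1 - alpha quantile) and `p_fwer` (3D array).
#' @export
fwer_permutation_maxstat <- function(ds, design, contrast = NULL, mask = NULL,
                                     alpha = 0.05, n_perm = 999, seed = NULL,
                                     scheme = c("freedman_lane", "simple"),
                                     modalities = NULL, connectivity = 18) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ds, "multimodal_dataset"))
  if (!isTRUE(ds$standardized))
    stop_cfg("dataset must be standardized first (standardize_dataset)")
  if (n_perm < 100) stop_cfg("n_perm must be >= 100")
  if (alpha < 1 / (n_perm + 1))
    stop_cfg("n_perm too small for alpha = ", alpha,
             " (need n_perm >= ", ceiling(1 / alpha) - 1, ")")
  mask <- (mask %||% ds$analysis_mask)
  if (is.null(mask) || sum(mask != 0) == 0) stop_cfg("empty mask")
  X <- unclass(design)
  n <- nrow(X); k <- ncol(X)
  modalities <- modalities %||% ds$modalities
  p <- length(modalities)
  contrast <- contrast %||% age_contrast(k, p)
  Ylist <- lapply(modalities, function(m) flatten_stack(ds$stacks[[m]], mask))

  obs <- wilks_map_engine(Ylist, X, contrast)

  # reduced design: drop every column the row contrast involves
  tested_cols <- which(colSums(abs(contrast$C)) > 0)
  Xred <- X[, -tested_cols, drop = FALSE]

  # apply the modality contrast once; the permutation loop then only needs
  # the tested variates
  L <- contrast$L
  Zlist <- vector("list", contrast$l)
  for (j in seq_len(contrast$l)) {
    acc <- 0
    for (m in seq_len(p)) if (L[m, j] != 0) acc <- acc + L[m, j] * Ylist[[m]]
    Zlist[[j]] <- acc
  }
  id_contrast <- mglm_contrast(contrast$C, diag(contrast$l))
  plan <- wilks_plan(X, id_contrast)
  if (!is.null(seed)) set.seed(seed)
  null_min_lambda <- maxstat_null_lambda(plan, Zlist, Xred, scheme, n_perm)
  null_max <- wilks_to_F(null_min_lambda, n, k, contrast$l, contrast$c)$F

  p_fwer <- vapply(obs$F,
                   function(f) (1 + sum(null_max >= f)) / (n_perm + 1),
                   numeric(1))
  sig <- array(0L, dim(mask))
  vox <- which(mask != 0)
  sig[vox] <- as.integer(p_fwer <= alpha)
  thresholded_map(sig, mask, alpha, "permutation_maxstat",
                  stat = unflatten(obs$F, mask),
                  connectivity = connectivity,
                  threshold = stats::quantile(null_max, 1 - alpha,
                                              names = FALSE, type = 1),
                  null_max = null_max,
                  p_fwer = unflatten(p_fwer, mask),
                  scheme = scheme, n_perm = n_perm)
}

# neighbourhood offsets for 6 (face), 18 (face+edge) or 26 (full) adjacency
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop_cfg("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  lim <- c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)]
  g[ord > 0 & ord <= lim, , drop = FALSE]
}

#' Label connected components of a binary volume
#'
#' Breadth-first flood fill under the chosen 3D neighbourhood (6 = faces,
#' 18 = faces + edges, 26 = full). The cluster table is sorted by size,
#' descending; peak statistic and coordinates are filled in when a statistic
#' volume is supplied.
#'
#' @param binary binary 3D array.
#' @param connectivity 6, 18 or 26 (default 18, common SPM practice).
#' @param stat optional 3D statistic array for peak lookup.
#' @return list with `labels` (integer 3D array, 0 outside clusters) and
#'   `cluster_table` (`cluster_id`, `size_voxels`, and `peak_stat`,
#'   `peak_x/y/z` when `stat` is given).
#' @export
label_clusters <- function(binary, connectivity = 18, stat = NULL) {
  d <- dim(binary)
  stopifnot(length(d) == 3L)
  off <- connectivity_offsets(connectivity)
  vox <- which(binary != 0)
  labels <- array(0L, d)
  nsig <- length(vox)
  empty_tab <- data.frame(cluster_id = integer(0), size_voxels = integer(0))
  if (nsig == 0)
    return(list(labels = labels, cluster_table = empty_tab))
  # rank lookup: 0 = not significant, else index into vox
  rank_of <- array(0L, d)
  rank_of[vox] <- seq_len(nsig)
  lab_vec <- integer(nsig)
  coords <- arrayInd(vox, d)
  cur <- 0L
  for (s in seq_len(nsig)) {
    if (lab_vec[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab_vec[s] <- cur
    while (length(frontier)) {
      fc <- coords[frontier, , drop = FALSE]
      nf <- nrow(fc)
      cand <- fc[rep(seq_len(nf), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), nf), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
      nb <- rank_of[lin]
      nb <- unique(nb[nb > 0L])
      nb <- nb[lab_vec[nb] == 0L]
      lab_vec[nb] <- cur
      frontier <- nb
    }
  }
  labels[vox] <- lab_vec
  sizes <- tabulate(lab_vec, cur)
  tab <- data.frame(cluster_id = seq_len(cur), size_voxels = sizes)
  if (!is.null(stat)) {
    tab$peak_stat <- NA_real_
    tab$peak_x <- NA_integer_; tab$peak_y <- NA_integer_; tab$peak_z <- NA_integer_
    sv <- stat[vox]
    for (cl in seq_len(cur)) {
      members <- which(lab_vec == cl)
      pk <- members[which.max(sv[members])]
      tab$peak_stat[cl] <- sv[pk]
      tab$peak_x[cl] <- coords[pk, 1]
      tab$peak_y[cl] <- coords[pk, 2]
      tab$peak_z[cl] <- coords[pk, 3]
    }
  }
  tab <- tab[order(-tab$size_voxels, tab$cluster_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(labels = labels, cluster_table = tab)
}

#' Write a thresholded map (binary + labels) as NIfTI plus a cluster TSV
#'
#' @param x a `thresholded_map`.
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
write_thresholded_map <- function(x, prefix) {
  f1 <- paste0(prefix, "_binary.nii.gz")
  f2 <- paste0(prefix, "_labels.nii.gz")
  f3 <- paste0(prefix, "_clusters.tsv")
  RNifti::writeNifti(RNifti::asNifti(x$binary), f1)
  RNifti::writeNifti(RNifti::asNifti(x$labels), f2)
  utils::write.table(x$cluster_table, f3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(f1, f2, f3))
}
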