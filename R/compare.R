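#' Union of thresholded statistical maps
#'
#' Voxelwise logical OR of the binary maps (e.g. the four univariate maps,
#' giving the "union of uGLMs"), with clusters re-labelled on the union.
#' Peak statistics use the voxelwise maximum of the inputs' statistics when
#' all carry one.
#'
#' @param maps list of `thresholded_map` objects on identical grids/masks.
#' @param connectivity cluster connectivity for re-labelling.
#' @return a `thresholded_map` with `method = "union"`.
#' @export
union_maps <- function(maps, connectivity = 18) {
  stopifnot(is.list(maps), length(maps) >= 1)
  d <- dim(maps[[1]]$binary)
  msk <- maps[[1]]$mask
  for (m in maps) {
    if (!all(dim(m$binary) == d)) stop_cfg("grid mismatch between maps")
    if (!all(m$mask == msk)) stop_cfg("mask mismatch between maps")
  }
  binary <- Reduce(`|`, lapply(maps, function(m) m$binary != 0)) * 1L
  stats_list <- lapply(maps, `[[`, "stat")
  stat <- if (!any(vapply(stats_list, is.null, TRUE)))
    Reduce(function(a, b) pmax(a, b, na.rm = TRUE), stats_list) else NULL
  thresholded_map(binary, msk, maps[[1]]$alpha, "union", stat = stat,
                  connectivity = connectivity)
}

#' Cohen's kappa agreement between two binary maps
#'
#' Chance-corrected agreement over the in-mask voxels:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement
#' fraction and `p_e` the agreement expected from the class marginals.
#' Restricting to the analysis mask avoids inflating agreement with empty
#' background, which matters because significant voxels are sparse. When
#' both maps are constant and equal (`p_e = 1`, `p_o = 1`) kappa is 1.
#'
#' @param a,b binary 3D arrays or `thresholded_map` objects.
#' @param mask binary 3D array; required, must be nonempty.
#' @return list with `kappa`, `observed_agreement`, `expected_agreement`,
#'   and the 2 x 2 `confusion` count matrix.
#' @export
cohens_kappa <- function(a, b, mask) {
  a <- as_binary_array(a, "a"); b <- as_binary_array(b, "b")
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(mask)))
    stop_cfg("a, b and mask must share one grid")
  vox <- which(mask != 0)
  if (!length(vox)) stop_cfg("empty mask")
  av <- a[vox]; bv <- b[vox]
  nn <- length(vox)
  conf <- matrix(c(sum(av == 0 & bv == 0), sum(av == 0 & bv == 1),
                   sum(av == 1 & bv == 0), sum(av == 1 & bv == 1)),
                 2, 2, byrow = TRUE,
                 dimnames = list(a = c("0", "1"), b = c("0", "1")))
  po <- (conf[1, 1] + conf[2, 2]) / nn
  pe <- sum(rowSums(conf) * colSums(conf)) / nn^2
  kappa <- if (pe >= 1) {
    if (po >= 1) 1 else NA_real_  # po < 1 with pe = 1 cannot occur
  } else (po - pe) / (1 - pe)
  list(kappa = kappa, observed_agreement = po, expected_agreement = pe,
       confusion = conf)
}

#' Partition the mask by mGLM / union-of-uGLMs detection
#'
#' Labels every in-mask voxel as detected by both models, only the
#' multivariate model, only the univariate union, or neither.
#'
#' @param mglm,uunion binary 3D arrays or `thresholded_map` objects.
#' @param mask binary 3D array.
#' @return list with `category` (integer 3D array: 0 neither, 1 uglm_only,
#'   2 mglm_only, 3 both; NA outside the mask), `counts` (named), and the
#'   `legend`.
#' @export
overlap_partition <- function(mglm, uunion, mask) {
  a <- as_binary_array(mglm, "mglm"); b <- as_binary_array(uunion, "uunion")
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(mask)))
    stop_cfg("grid mismatch")
  cat_arr <- array(NA_integer_, dim(mask))
  vox <- which(mask != 0)
  code <- 2L * a[vox] + b[vox]
  cat_arr[vox] <- code
  counts <- c(neither = sum(code == 0L), uglm_only = sum(code == 1L),
              mglm_only = sum(code == 2L), both = sum(code == 3L))
  list(category = cat_arr, counts = counts,
       legend = c(`0` = "neither", `1` = "uglm_only", `2` = "mglm_only",
                  `3` = "both"))
}

#' Split subjects into two disjoint halves
#'
#' Stratified by default on age quintile x scanner so both halves span the
#' age range and the scanner levels; plain random splitting is available.
#' Half sizes differ by at most one overall and within each stratum.
#'
#' @param cov covariate table.
#' @param seed integer seed.
#' @param stratify_on covariate names used for stratification (subset of
#'   `c("age", "gender", "scanner")`); `NULL` or empty for a plain split.
#' @param n_age_bins number of age quantile bins when stratifying on age.
#' @return list with integer index vectors `A` and `B`.
#' @export
split_half <- function(cov, seed = NULL, stratify_on = c("age", "scanner"),
                       n_age_bins = 5) {
  n <- nrow(cov)
  if (n < 2) stop_cfg("need at least 2 subjects to split")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(stratify_on) || !length(stratify_on)) {
    strata <- rep(1L, n)
  } else {
    parts <- lapply(stratify_on, function(s) {
      if (s == "age") {
        br <- unique(stats::quantile(cov$age, probs = seq(0, 1,
                                                          length.out = n_age_bins + 1)))
        if (length(br) < 2) rep(1L, n) else
          as.integer(cut(cov$age, br, include.lowest = TRUE))
      } else as.integer(factor(cov[[s]]))
    })
    strata <- as.integer(factor(do.call(paste, parts)))
  }
  A <- integer(0); B <- integer(0)
  for (st in sort(unique(strata))) {
    idx <- which(strata == st)
    idx <- idx[sample.int(length(idx))]
    s <- length(idx)
    if (s == 1) {
      warning("stratum of size 1; subject assigned at random")
      if (stats::runif(1) < 0.5) A <- c(A, idx) else B <- c(B, idx)
      next
    }
    half <- s %/% 2
    if (s %% 2 == 1) {
      # give the odd subject to whichever half is currently smaller
      if (length(A) > length(B)) {
        B <- c(B, idx[seq_len(half + 1)]); A <- c(A, idx[-seq_len(half + 1)])
      } else {
        A <- c(A, idx[seq_len(half + 1)]); B <- c(B, idx[-seq_len(half + 1)])
      }
    } else {
      A <- c(A, idx[seq_len(half)]); B <- c(B, idx[-seq_len(half)])
    }
  }
  list(A = sort(A), B = sort(B))
}

# Full single-tissue analysis used by the cross-validation report: z-score
# within the mask, fit the 4 uGLMs and the mGLM, threshold, union, kappa.
analyze_tissue <- function(ds, mask, alpha_mglm = 0.05, alpha_uglm = 0.0125,
                           fwer_method = c("bonferroni", "permutation"),
                           n_perm = 199, seed = NULL, connectivity = 18) {
  fwer_method <- match.arg(fwer_method)
  std <- standardize_dataset(ds, mask)
  X <- build_design(std$covariates)
  k <- ncol(X); p <- length(std$modalities)
  hc <- age_contrast(k, p)
  thr_one <- function(modality, alpha) {
    if (fwer_method == "bonferroni") {
      fwer_voxel_bonferroni(uglm_map(std, modality, X), alpha,
                            connectivity = connectivity)
    } else {
      fwer_permutation_maxstat(std, X, age_contrast(k, 1), alpha = alpha,
                               n_perm = n_perm, seed = seed,
                               modalities = modality,
                               connectivity = connectivity)
    }
  }
  uthr <- lapply(std$modalities, thr_one, alpha = alpha_uglm)
  names(uthr) <- std$modalities
  uu <- union_maps(uthr, connectivity)
  mmap <- mglm_map(std, X, hc, keep_canonical = FALSE)
  mthr <- if (fwer_method == "bonferroni") {
    fwer_voxel_bonferroni(mmap, alpha_mglm, connectivity = connectivity)
  } else {
    fwer_permutation_maxstat(std, X, hc, alpha = alpha_mglm, n_perm = n_perm,
                             seed = seed, connectivity = connectivity)
  }
  kap <- cohens_kappa(mthr, uu, std$analysis_mask)
  summaries <- rbind(
    do.call(rbind, lapply(std$modalities,
                          function(m) cluster_summary(uthr[[m]], m))),
    cluster_summary(uu, "United"),
    cluster_summary(mthr, "mGLM"))
  list(uglm_thresholded = uthr, union = uu, mglm_map = mmap,
       mglm_thresholded = mthr, kappa = kap, cluster_summaries = summaries,
       analysis_mask = std$analysis_mask, n = std$n)
}

#' Split-half cross-validation report
#'
#' Randomly divides the subjects into two disjoint halves, repeats the full
#' analysis pipeline (z-scoring, uGLMs, their union, mGLM, FWER
#' thresholding, Cohen's kappa) separately within each half and on the full
#' data, and reports the cluster summaries and agreement per analysis.
#'
#' @param ds unstandardized `multimodal_dataset`.
#' @param mask binary 3D analysis mask (default: exclusive GM mask).
#' @param alpha_mglm FWER level for the multivariate map (default 0.05).
#' @param alpha_uglm per-map FWER level for the univariate maps (default
#'   0.05 / 4).
#' @param fwer_method `"bonferroni"` or `"permutation"`.
#' @param n_perm permutations when `fwer_method = "permutation"`.
#' @param seed integer seed (controls the split and any permutations).
#' @param stratify_on see [split_half()].
#' @param connectivity cluster connectivity.
#' @return object of class `crossval_report`: per-analysis cluster summary
#'   tables and kappa values, plus the split indices.
#' @export
crossval_report <- function(ds, mask = NULL, alpha_mglm = 0.05,
                            alpha_uglm = bonferroni_across_maps(0.05, 4),
                            fwer_method = c("bonferroni", "permutation"),
                            n_perm = 199, seed = NULL,
                            stratify_on = c("age", "scanner"),
                            connectivity = 18) {
  fwer_method <- match.arg(fwer_method)
  stopifnot(inherits(ds, "multimodal_dataset"))
  if (isTRUE(ds$standardized))
    stop_cfg("crossval_report needs the raw dataset: each half is ",
             "re-standardized within itself")
  if (is.null(mask)) mask <- build_exclusive_masks(ds$gm_mask, ds$wm_mask)$gm
  halves <- split_half(ds$covariates, seed = seed, stratify_on = stratify_on)
  run <- function(sub, tag) {
    analyze_tissue(sub, mask, alpha_mglm, alpha_uglm, fwer_method,
                   n_perm = n_perm, seed = seed, connectivity = connectivity)
  }
  full <- run(ds, "full")
  a <- run(subset_dataset(ds, halves$A), "A")
  b <- run(subset_dataset(ds, halves$B), "B")
  pack <- function(x, tag) {
    s <- x$cluster_summaries
    s$analysis <- tag
    s
  }
  structure(list(
    summaries = rbind(pack(full, "full"), pack(a, "half_A"), pack(b, "half_B")),
    kappa = c(full = full$kappa$kappa, half_A = a$kappa$kappa,
              half_B = b$kappa$kappa),
    split = halves,
    alpha_mglm = alpha_mglm, alpha_uglm = alpha_uglm,
    fwer_method = fwer_method,
    details = list(full = full, half_A = a, half_B = b)),
    class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("Split-half cross-validation (", x$fwer_method, " FWER, alpha mGLM ",
      x$alpha_mglm, ", alpha uGLM ", x$alpha_uglm, ")\n", sep = "")
  cat("Cohen's kappa (mGLM vs union of uGLMs):\n")
  print(round(x$kappa, 4))
  cat("\nCluster summaries:\n")
  print(x$summaries[, c("analysis", "map", "n_clusters", "min_size",
                        "max_size", "n_voxels")], row.names = FALSE)
  invisible(x)
}
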