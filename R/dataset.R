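#' Construct a multimodal dataset container
#'
#' Holds one (x, y, z, subject) stack per modality, the GM/WM tissue masks,
#' the integer region-label volume and the subject covariate table; the
#' common input of the voxelwise analysis stages.
#'
#' @param stacks named list of 4D arrays (one per modality), all sharing one
#'   grid shape and one subject count.
#' @param gm_mask,wm_mask disjoint binary 3D arrays.
#' @param region_labels integer 3D array (0 = background).
#' @param covariates covariate table (see [generate_covariates()]).
#' @param modalities ordered modality names (defaults to `names(stacks)`).
#' @return object of class `multimodal_dataset`.
#' @export
multimodal_dataset <- function(stacks, gm_mask, wm_mask, region_labels,
                               covariates, modalities = names(stacks)) {
  stopifnot(is.list(stacks), length(stacks) >= 1)
  if (is.null(modalities)) stop_cfg("stacks must be a named list")
  d <- dim(stacks[[1]])
  if (length(d) != 4) stop_cfg("each stack must be a 4D (x,y,z,subject) array")
  for (s in stacks)
    if (!all(dim(s) == d)) stop_cfg("all stacks must share one shape")
  n <- d[4]
  if (nrow(covariates) != n)
    stop_cfg("covariate rows (", nrow(covariates),
             ") must equal stack subject count (", n, ")")
  for (nm in c("gm_mask", "wm_mask", "region_labels")) {
    a <- get(nm)
    if (!all(dim(a) == d[1:3])) stop_cfg(nm, " grid mismatch")
  }
  if (any(gm_mask != 0 & wm_mask != 0)) stop_cfg("tissue masks overlap")
  structure(list(modalities = modalities,
                 stacks = stacks[modalities],
                 gm_mask = (gm_mask != 0) * 1L,
                 wm_mask = (wm_mask != 0) * 1L,
                 region_labels = region_labels,
                 covariates = covariates,
                 grid_shape = d[1:3],
                 n = n,
                 standardized = FALSE),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("Multimodal dataset:", x$n, "subjects,",
      paste(x$grid_shape, collapse = " x "), "grid\n")
  cat("  modalities:", paste(x$modalities, collapse = ", "),
      if (isTRUE(x$standardized)) " (z-scored)" else "", "\n")
  cat("  GM voxels:", sum(x$gm_mask), " WM voxels:", sum(x$wm_mask), "\n")
  if (!is.null(x$analysis_mask))
    cat("  analysis mask:", sum(x$analysis_mask), "voxels\n")
  invisible(x)
}

#' Subset a dataset by subject indices
#'
#' @param ds a `multimodal_dataset`.
#' @param idx integer subject indices.
#' @return a `multimodal_dataset` restricted to `idx` (unstandardized).
#' @export
subset_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "multimodal_dataset"))
  stacks <- lapply(ds$stacks, function(s) s[, , , idx, drop = FALSE])
  multimodal_dataset(stacks, ds$gm_mask, ds$wm_mask, ds$region_labels,
                     ds$covariates[idx, , drop = FALSE], ds$modalities)
}

#' Write a multimodal dataset to disk
#'
#' One NIfTI volume per subject and modality (`sub-XXX_<modality>.nii.gz`),
#' the masks and region labels as NIfTI, the covariates as
#' `participants.tsv`, and a JSON sidecar with the grid and modality order.
#'
#' @param ds a `multimodal_dataset`.
#' @param directory output directory (created if missing).
#' @param spec optional [phantom_spec()] recorded in the sidecar.
#' @return invisibly, a character vector manifest of the written files.
#' @export
write_dataset <- function(ds, directory, spec = NULL) {
  stopifnot(inherits(ds, "multimodal_dataset"))
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop_cfg("cannot create output directory: ", directory)
  files <- character(0)
  wr <- function(arr, name) {
    path <- file.path(directory, name)
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    path
  }
  files <- c(files, wr(ds$gm_mask, "gm_mask.nii.gz"),
             wr(ds$wm_mask, "wm_mask.nii.gz"),
             wr(ds$region_labels, "region_labels.nii.gz"))
  for (i in seq_len(ds$n)) {
    for (m in ds$modalities) {
      nm <- sprintf("%s_%s.nii.gz", ds$covariates$participant_id[i], m)
      files <- c(files, wr(ds$stacks[[m]][, , , i], nm))
    }
  }
  tsv <- file.path(directory, "participants.tsv")
  utils::write.table(ds$covariates, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, tsv)
  side <- list(modalities = ds$modalities, grid_shape = ds$grid_shape,
               n = ds$n, standardized = isTRUE(ds$standardized))
  if (!is.null(spec))
    side$phantom <- list(seed = spec$seed,
                         noise_sd = as.list(spec$noise_sd),
                         noise_corr = spec$noise_corr,
                         smooth_fwhm_vox = spec$smooth_fwhm_vox,
                         effect_table = spec$effect_table)
  js <- file.path(directory, "dataset.json")
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA)
  files <- c(files, js)
  invisible(files)
}

#' Read a multimodal dataset written by [write_dataset()]
#'
#' @param directory dataset directory.
#' @return a `multimodal_dataset`.
#' @export
read_dataset <- function(directory) {
  js <- file.path(directory, "dataset.json")
  if (!file.exists(js)) stop_cfg("not a dataset directory (missing ", js, ")")
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  rd <- function(name) {
    path <- file.path(directory, name)
    if (!file.exists(path)) stop_cfg("missing volume: ", path)
    arr <- as.array(RNifti::readNifti(path))
    dim(arr) <- dim(arr)[1:3]
    arr
  }
  cov <- utils::read.table(file.path(directory, "participants.tsv"),
                           sep = "\t", header = TRUE,
                           colClasses = c(participant_id = "character",
                                          age = "numeric",
                                          gender = "character",
                                          tiv = "numeric",
                                          scanner = "character"))
  g <- as.integer(side$grid_shape)
  n <- as.integer(side$n)
  mods <- side$modalities
  stacks <- lapply(mods, function(m) {
    arr <- array(0, c(g, n))
    for (i in seq_len(n))
      arr[, , , i] <- rd(sprintf("%s_%s.nii.gz", cov$participant_id[i], m))
    arr
  })
  names(stacks) <- mods
  ds <- multimodal_dataset(stacks, rd("gm_mask.nii.gz"), rd("wm_mask.nii.gz"),
                           rd("region_labels.nii.gz"), cov, mods)
  ds$standardized <- isTRUE(side$standardized)
  ds
}
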