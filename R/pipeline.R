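#' Default pipeline configuration
#'
#' A desk-scale demonstration configuration: a 16^3 phantom with 40
#' subjects, GM-mask analysis, Bonferroni voxel FWER at 0.05 for the mGLM
#' and 0.05/4 per univariate map.
#'
#' @param seed master seed; per-stage sub-seeds are derived from it.
#' @param output_dir where stage artifacts are written.
#' @return named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, output_dir = tempfile("voxmanova_")) {
  list(seed = as.integer(seed),
       n = 40L,
       grid = c(16L, 16L, 16L),
       smooth_fwhm_vox = 2,
       tissue = "gm",
       alpha = 0.05,
       alpha_uglm = NULL,          # NULL -> alpha / 4
       n_perm = 199L,
       fwer_method = "bonferroni", # or "permutation"
       connectivity = 18L,
       null_effects = FALSE,
       output_dir = output_dir)
}

validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_cfg("unknown config field(s): ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  if (!config$fwer_method %in% c("bonferroni", "permutation"))
    stop_cfg("config$fwer_method must be 'bonferroni' or 'permutation'")
  if (!config$tissue %in% c("gm", "wm"))
    stop_cfg("config$tissue must be 'gm' or 'wm'")
  if (config$alpha <= 0 || config$alpha >= 1)
    stop_cfg("config$alpha must lie in (0, 1)")
  if (is.null(config$alpha_uglm))
    config$alpha_uglm <- bonferroni_across_maps(config$alpha, 4)
  config
}

write_provenance <- function(dir, stage, config) {
  jsonlite::write_json(
    list(stage = stage, config = config,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("voxmanova"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
}

write_manifest <- function(dir, files) {
  jsonlite::write_json(list(files = basename(files)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

require_stage <- function(root, stage) {
  manifest <- file.path(root, stage, "manifest.json")
  if (!file.exists(manifest))
    stop_cfg("missing upstream artifact: expected manifest ", manifest,
             " - run the '", stage, "' stage first")
  file.path(root, stage)
}

stage_dir <- function(root, stage) {
  d <- file.path(root, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

pipeline_mask <- function(ds, tissue) {
  excl <- build_exclusive_masks(ds$gm_mask, ds$wm_mask)
  excl[[tissue]]
}

#' Run the analysis pipeline stages
#'
#' Orchestrates simulate -> preprocess -> uglm + mglm -> threshold ->
#' compare -> roi -> crossval over an output directory; each stage reads the
#' previous stage's manifest from disk and writes its own, together with a
#' provenance JSON recording the configuration and seed.
#'
#' @param stage one of `"simulate"`, `"preprocess"`, `"uglm"`, `"mglm"`,
#'   `"threshold"`, `"compare"`, `"roi"`, `"crossval"`, `"all"`.
#' @param config configuration list (see [default_config()]); missing fields
#'   take their defaults.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(stage = "all", config = default_config()) {
  config <- validate_config(config)
  stages <- c("simulate", "preprocess", "uglm", "mglm", "threshold",
              "compare", "roi", "crossval")
  if (!stage %in% c(stages, "all")) stop_cfg("unknown stage: ", stage)
  todo <- if (stage == "all") stages else stage
  root <- config$output_dir
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (s in todo) do.call(paste0("stage_", s), list(config = config, root = root))
  invisible(root)
}

stage_simulate <- function(config, root) {
  d <- stage_dir(root, "simulate")
  spec <- default_phantom_spec(config$grid,
                               smooth_fwhm_vox = config$smooth_fwhm_vox,
                               seed = derive_seed(config$seed, 1),
                               null_effects = isTRUE(config$null_effects))
  cov <- generate_covariates(config$n, seed = derive_seed(config$seed, 2))
  ds <- generate_maps(cov, spec)
  files <- write_dataset(ds, file.path(d, "dataset"), spec = spec)
  write_manifest(d, c(files, "dataset"))
  write_provenance(d, "simulate", config)
  invisible(d)
}

stage_preprocess <- function(config, root) {
  up <- require_stage(root, "simulate")
  d <- stage_dir(root, "preprocess")
  ds <- read_dataset(file.path(up, "dataset"))
  std <- standardize_dataset(ds, pipeline_mask(ds, config$tissue))
  files <- write_dataset(std, file.path(d, "dataset"))
  f <- file.path(d, "analysis_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(std$analysis_mask), f)
  write_manifest(d, c(files, f))
  write_provenance(d, "preprocess", config)
  invisible(d)
}

# reload the standardized dataset with its analysis mask
load_preprocessed <- function(root) {
  up <- require_stage(root, "preprocess")
  std <- read_dataset(file.path(up, "dataset"))
  am <- as.array(RNifti::readNifti(file.path(up, "analysis_mask.nii.gz")))
  dim(am) <- dim(am)[1:3]
  std$analysis_mask <- (am != 0) * 1L
  std$standardized <- TRUE
  std
}

stage_uglm <- function(config, root) {
  std <- load_preprocessed(root)
  d <- stage_dir(root, "uglm")
  X <- build_design(std$covariates)
  files <- character(0)
  for (m in std$modalities) {
    map <- uglm_map(std, m, X)
    files <- c(files, write_stat_map(map, file.path(d, paste0("uglm_", m))))
  }
  write_manifest(d, files)
  write_provenance(d, "uglm", config)
  invisible(d)
}

stage_mglm <- function(config, root) {
  std <- load_preprocessed(root)
  d <- stage_dir(root, "mglm")
  X <- build_design(std$covariates)
  map <- mglm_map(std, X)
  files <- write_stat_map(map, file.path(d, "mglm"))
  write_manifest(d, files)
  write_provenance(d, "mglm", config)
  invisible(d)
}

# reload a stat map written by write_stat_map
read_stat_map <- function(prefix, mask) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(suffix, fill) {
    arr <- as.array(RNifti::readNifti(paste0(prefix, suffix)))
    dim(arr) <- dim(arr)[1:3]
    arr[mask == 0] <- fill
    arr
  }
  stat_map(stat = rd("_stat.nii.gz", NA_real_),
           p_uncorrected = rd("_p.nii.gz", NA_real_),
           mask = mask, df = side$df, stat_kind = side$stat_kind,
           n = side$n, k = side$k, l = side$l, c = side$c,
           modality = side$modality, modalities = side$modalities)
}

stage_threshold <- function(config, root) {
  std <- load_preprocessed(root)
  ug <- require_stage(root, "uglm")
  mg <- require_stage(root, "mglm")
  d <- stage_dir(root, "threshold")
  X <- build_design(std$covariates)
  files <- character(0)
  uthr <- list()
  for (m in std$modalities) {
    thr <- if (config$fwer_method == "bonferroni") {
      map <- read_stat_map(file.path(ug, paste0("uglm_", m)), std$analysis_mask)
      fwer_voxel_bonferroni(map, config$alpha_uglm, config$connectivity)
    } else {
      fwer_permutation_maxstat(std, X,
                               age_contrast(ncol(X), 1),
                               alpha = config$alpha_uglm,
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, 10 + match(m, std$modalities)),
                               modalities = m,
                               connectivity = config$connectivity)
    }
    uthr[[m]] <- thr
    files <- c(files, write_thresholded_map(thr, file.path(d, paste0("uglm_", m))))
  }
  uu <- union_maps(uthr, config$connectivity)
  files <- c(files, write_thresholded_map(uu, file.path(d, "uglm_union")))
  mthr <- if (config$fwer_method == "bonferroni") {
    map <- read_stat_map(file.path(mg, "mglm"), std$analysis_mask)
    fwer_voxel_bonferroni(map, config$alpha, config$connectivity)
  } else {
    fwer_permutation_maxstat(std, X, alpha = config$alpha,
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, 20),
                             connectivity = config$connectivity)
  }
  files <- c(files, write_thresholded_map(mthr, file.path(d, "mglm")))
  write_manifest(d, files)
  write_provenance(d, "threshold", config)
  invisible(d)
}

read_thresholded <- function(dir, name, mask, config) {
  bin <- as.array(RNifti::readNifti(file.path(dir, paste0(name, "_binary.nii.gz"))))
  dim(bin) <- dim(bin)[1:3]
  thresholded_map(bin, mask, config$alpha, "reloaded",
                  connectivity = config$connectivity)
}

stage_compare <- function(config, root) {
  std <- load_preprocessed(root)
  th <- require_stage(root, "threshold")
  d <- stage_dir(root, "compare")
  mthr <- read_thresholded(th, "mglm", std$analysis_mask, config)
  uu <- read_thresholded(th, "uglm_union", std$analysis_mask, config)
  kap <- cohens_kappa(mthr, uu, std$analysis_mask)
  part <- overlap_partition(mthr, uu, std$analysis_mask)
  f1 <- file.path(d, "kappa.json")
  jsonlite::write_json(list(kappa = kap$kappa,
                            observed_agreement = kap$observed_agreement,
                            expected_agreement = kap$expected_agreement,
                            confusion = kap$confusion,
                            overlap_counts = as.list(part$counts)),
                       f1, auto_unbox = TRUE, digits = NA)
  f2 <- file.path(d, "overlap_partition.nii.gz")
  cat_arr <- part$category
  cat_arr[is.na(cat_arr)] <- -1L
  RNifti::writeNifti(RNifti::asNifti(cat_arr), f2)
  f3 <- file.path(d, "overlap_legend.json")
  jsonlite::write_json(as.list(part$legend), f3, auto_unbox = TRUE)
  write_manifest(d, c(f1, f2, f3))
  write_provenance(d, "compare", config)
  invisible(d)
}

stage_roi <- function(config, root) {
  std <- load_preprocessed(root)
  mg <- require_stage(root, "mglm")
  d <- stage_dir(root, "roi")
  tab <- roi_table(std)
  f1 <- file.path(d, "roi_partial_correlations.tsv")
  utils::write.table(tab, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  # peak canonical weights per ROI from the stored weight maps
  map <- mglm_map(std, build_design(std$covariates))
  peaks <- list()
  for (r in sort(setdiff(unique(as.vector(std$region_labels)), 0))) {
    roi <- (std$region_labels == r) * 1L
    dim(roi) <- dim(std$region_labels)
    pk <- tryCatch(peak_canonical_vector(map, roi), error = function(e) NULL)
    if (!is.null(pk))
      peaks[[paste0("region", r)]] <- list(weights = as.list(pk$weights),
                                           peak = pk$peak,
                                           peak_stat = pk$peak_stat)
  }
  f2 <- file.path(d, "peak_canonical_vectors.json")
  jsonlite::write_json(peaks, f2, auto_unbox = TRUE, digits = NA)
  write_manifest(d, c(f1, f2))
  write_provenance(d, "roi", config)
  invisible(d)
}

stage_crossval <- function(config, root) {
  up <- require_stage(root, "simulate")
  d <- stage_dir(root, "crossval")
  ds <- read_dataset(file.path(up, "dataset"))
  rep <- crossval_report(ds, pipeline_mask(ds, config$tissue),
                         alpha_mglm = config$alpha,
                         alpha_uglm = config$alpha_uglm,
                         fwer_method = config$fwer_method,
                         n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 30),
                         connectivity = config$connectivity)
  f1 <- file.path(d, "crossval_report.json")
  jsonlite::write_json(list(kappa = as.list(rep$kappa),
                            summaries = rep$summaries,
                            split = rep$split),
                       f1, auto_unbox = TRUE, digits = NA)
  f2 <- file.path(d, "crossval_summaries.tsv")
  utils::write.table(rep$summaries, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(d, c(f1, f2))
  write_provenance(d, "crossval", config)
  invisible(d)
}
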