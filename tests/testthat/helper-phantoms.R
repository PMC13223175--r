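# Small phantom builders shared across test files.

# minimal custom geometry on a tiny grid: one GM slab, one WM slab, region 1
# inside GM
tiny_spec <- function(grid = c(6L, 6L, 6L), noise_sd = 1, noise_corr = NULL,
                      age_slope = 0, smooth_fwhm_vox = 0, seed = 1L,
                      baseline = 0, region_modality = "R2s") {
  gm <- array(0L, grid); wm <- array(0L, grid); lab <- array(0L, grid)
  gm[, , seq_len(floor(grid[3] / 2))] <- 1L
  wm[, , (floor(grid[3] / 2) + 1):grid[3]] <- 1L
  lab[2:(grid[1] - 1), 2:(grid[2] - 1), 2] <- 1L
  mods <- c("MTsat", "PD", "R1", "R2s")
  eff <- data.frame(region = 1, modality = mods, baseline = baseline,
                    age_slope = 0, tiv_slope = 0, gender_offset = 0,
                    scanner_offset = 0, stringsAsFactors = FALSE)
  eff$age_slope[eff$modality == region_modality] <- age_slope
  if (is.null(noise_corr)) { noise_corr <- diag(4) }
  phantom_spec(grid, lab, gm, wm, eff, noise_sd, noise_corr,
               smooth_fwhm_vox = smooth_fwhm_vox, modalities = mods,
               seed = seed)
}

# independent n x V flattening over a logical/binary mask
flatten_stack_test <- function(stack, mask) {
  vox <- which(mask != 0)
  t(matrix(stack, nrow = prod(dim(stack)[1:3]))[vox, , drop = FALSE])
}

# standardized dataset + design from any spec
standardized_fixture <- function(n, spec, seed_cov = 42L) {
  cov <- generate_covariates(n, seed = seed_cov)
  ds <- generate_maps(cov, spec)
  std <- standardize_dataset(ds, build_exclusive_masks(ds$gm_mask,
                                                       ds$wm_mask)$gm)
  list(ds = ds, std = std, X = build_design(cov), cov = cov)
}
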