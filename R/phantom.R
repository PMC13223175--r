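#' Generate a synthetic subject covariate table
#'
#' Draws ages from a truncated normal (or an optional two-component mixture
#' emulating a young/elderly cohort), a two-level gender factor, total
#' intracranial volume (TIV), and a two-level scanner assignment. Defaults
#' reproduce the summary statistics of a 19-75 year cohort with mean age
#' 46.64, sd 21 and 35.5% males.
#'
#' @param n number of subjects (`n = 0` gives an empty table).
#' @param age_range length-2 numeric; ages are resampled into this interval.
#' @param age_mean,age_sd parameters of the (untruncated) age distribution.
#' @param male_fraction probability of the "M" gender level.
#' @param tiv_mean,tiv_sd TIV distribution in millilitres.
#' @param scanner_fraction probability of the "scanner2" level. Two scanners,
#'   balanced by default; when `n >= 4` each scanner level is guaranteed at
#'   least 2 subjects.
#' @param age_mode `"truncnorm"` (default) or `"bimodal"`, a 50/50 mixture of
#'   young (mean 26, sd 4) and elderly (mean 63, sd 6) components truncated
#'   to `age_range`.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return `data.frame` with columns `participant_id`, `age`, `gender`
#'   ("F"/"M"), `tiv`, `scanner` ("scanner1"/"scanner2").
#' @export
generate_covariates <- function(n,
                                age_range = c(19, 75),
                                age_mean = 46.64,
                                age_sd = 21,
                                male_fraction = 0.355,
                                tiv_mean = 1450,
                                tiv_sd = 130,
                                scanner_fraction = 0.5,
                                age_mode = c("truncnorm", "bimodal"),
                                seed = NULL) {
  age_mode <- match.arg(age_mode)
  if (n < 0) stop_cfg("n must be >= 0")
  if (length(age_range) != 2 || diff(age_range) <= 0)
    stop_cfg("age_range must be an increasing length-2 interval")
  for (f in c(male_fraction, scanner_fraction))
    if (f < 0 || f > 1) stop_cfg("fractions must lie in [0, 1]")
  if (age_sd <= 0 || tiv_sd <= 0) stop_cfg("age_sd and tiv_sd must be positive")
  empty <- data.frame(participant_id = character(0), age = numeric(0),
                      gender = character(0), tiv = numeric(0),
                      scanner = character(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  if (!is.null(seed)) set.seed(seed)

  draw_ages <- function(m) {
    if (age_mode == "truncnorm") {
      stats::rnorm(m, age_mean, age_sd)
    } else {
      comp <- stats::rbinom(m, 1, 0.5)
      stats::rnorm(m, ifelse(comp == 1, 63, 26), ifelse(comp == 1, 6, 4))
    }
  }
  age <- draw_ages(n)
  for (iter in 1:1000) {
    bad <- which(age < age_range[1] | age > age_range[2])
    if (!length(bad)) break
    age[bad] <- draw_ages(length(bad))
  }
  age[age < age_range[1]] <- age_range[1]
  age[age > age_range[2]] <- age_range[2]

  gender <- ifelse(stats::rbinom(n, 1, male_fraction) == 1, "M", "F")
  tiv <- stats::rnorm(n, tiv_mean, tiv_sd)
  scanner <- ifelse(stats::rbinom(n, 1, scanner_fraction) == 1,
                    "scanner2", "scanner1")
  if (n >= 4) {
    for (lev in c("scanner1", "scanner2")) {
      while (sum(scanner == lev) < 2) {
        other <- which(scanner != lev)
        scanner[other[sample.int(length(other), 1)]] <- lev
      }
    }
  }
  data.frame(participant_id = sprintf("sub-%03d", seq_len(n)),
             age = age, gender = gender, tiv = tiv, scanner = scanner,
             stringsAsFactors = FALSE)
}

#' Specify a synthetic multimodal phantom
#'
#' Bundles the geometry (grid, tissue masks, region labels), the linear
#' effect model per (region, modality), and the noise model (per-modality
#' standard deviations, a cross-modality correlation matrix, and a spatial
#' Gaussian smoothing width) that [generate_maps()] instantiates.
#'
#' @param grid_shape 3 positive integers, voxels per axis.
#' @param region_labels integer 3D array; 0 = background, 1..R = regions.
#'   Every labelled voxel must lie inside a tissue mask.
#' @param gm_mask,wm_mask disjoint binary 3D arrays on the same grid.
#' @param effect_table `data.frame` with columns `region`, `modality`,
#'   `baseline`, `age_slope` (map units per year), `tiv_slope` (per mL),
#'   `gender_offset`, `scanner_offset` (map units added for the "M" and
#'   "scanner2" levels respectively).
#' @param noise_sd named per-modality positive scalars (map units).
#' @param noise_corr p x p cross-modality noise correlation matrix
#'   (unit diagonal, positive definite).
#' @param smooth_fwhm_vox non-negative Gaussian smoothing FWHM in voxels
#'   applied to each modality volume after noise injection.
#' @param modalities ordered modality names.
#' @param seed integer seed used by [generate_maps()].
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, region_labels, gm_mask, wm_mask,
                         effect_table, noise_sd, noise_corr,
                         smooth_fwhm_vox = 0,
                         modalities = c("MTsat", "PD", "R1", "R2s"),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stop_cfg("grid_shape must be 3 positive integers")
  p <- length(modalities)
  for (nm in c("region_labels", "gm_mask", "wm_mask")) {
    a <- get(nm)
    if (!is.array(a) || !all(dim(a) == grid_shape))
      stop_cfg(nm, " must be an array of dim grid_shape")
  }
  if (any(gm_mask != 0 & wm_mask != 0))
    stop_cfg("tissue masks must be disjoint (GM and WM overlap)")
  tissue <- (gm_mask != 0) | (wm_mask != 0)
  if (any(region_labels != 0 & !tissue))
    stop_cfg("every labelled region voxel must lie inside a tissue mask")
  req <- c("region", "modality", "baseline", "age_slope", "tiv_slope",
           "gender_offset", "scanner_offset")
  if (!all(req %in% names(effect_table)))
    stop_cfg("effect_table must have columns: ", paste(req, collapse = ", "))
  if (!all(effect_table$modality %in% modalities))
    stop_cfg("effect_table modalities must match spec modalities")
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, p)
  if (is.null(names(noise_sd))) names(noise_sd) <- modalities
  noise_sd <- noise_sd[modalities]
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0))
    stop_cfg("noise_sd must be non-negative per modality")
  noise_corr <- as.matrix(noise_corr)
  if (!all(dim(noise_corr) == c(p, p)) ||
      max(abs(noise_corr - t(noise_corr))) > 1e-12 ||
      max(abs(diag(noise_corr) - 1)) > 1e-12)
    stop_cfg("noise_corr must be a symmetric p x p matrix with unit diagonal")
  ch <- tryCatch(chol(noise_corr), error = function(e) NULL)
  if (is.null(ch)) stop_cfg("noise_corr must be positive definite")
  if (smooth_fwhm_vox < 0) stop_cfg("smooth_fwhm_vox must be >= 0")
  structure(list(grid_shape = grid_shape,
                 region_labels = region_labels,
                 gm_mask = (gm_mask != 0) * 1L,
                 wm_mask = (wm_mask != 0) * 1L,
                 effect_table = effect_table,
                 noise_sd = noise_sd,
                 noise_corr = noise_corr,
                 chol_corr = ch,
                 smooth_fwhm_vox = smooth_fwhm_vox,
                 modalities = modalities,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Synthetic multimodal phantom specification\n")
  cat("  grid:", paste(x$grid_shape, collapse = " x "),
      " modalities:", paste(x$modalities, collapse = ", "), "\n")
  cat("  GM voxels:", sum(x$gm_mask), " WM voxels:", sum(x$wm_mask),
      " regions:", max(x$region_labels), "\n")
  cat("  smoothing FWHM (vox):", x$smooth_fwhm_vox,
      " seed:", x$seed, "\n")
  invisible(x)
}

# Default phantom geometry on a cubic grid: a central WM core surrounded by a
# GM shell, with three designated effect regions (two GM slabs, one WM block).
default_phantom_geometry <- function(grid_shape = c(16L, 16L, 16L)) {
  g <- as.integer(grid_shape)
  wm <- array(0L, g); gm <- array(0L, g); lab <- array(0L, g)
  core <- lapply(g, function(n) seq.int(max(2L, round(n * 0.35)),
                                        min(n - 1L, round(n * 0.7))))
  shell <- lapply(g, function(n) seq.int(max(1L, round(n * 0.2)),
                                         min(n, round(n * 0.85))))
  wm[core[[1]], core[[2]], core[[3]]] <- 1L
  gm[shell[[1]], shell[[2]], shell[[3]]] <- 1L
  gm[wm == 1L] <- 0L
  z_lo <- shell[[3]][1]
  z_hi <- shell[[3]][length(shell[[3]])]
  lab[shell[[1]], shell[[2]], z_lo] <- 1L        # GM slab, bottom shell face
  lab[shell[[1]], shell[[2]], z_hi] <- 2L        # GM slab, top shell face
  mid <- lapply(core, function(ix) ix[seq.int(2L, max(2L, length(ix) - 1L))])
  lab[mid[[1]], mid[[2]], mid[[3]]] <- 3L        # WM block
  lab[gm == 0L & wm == 0L] <- 0L
  list(gm_mask = gm, wm_mask = wm, region_labels = lab)
}

#' Default phantom specification
#'
#' A cubic-grid phantom with a WM core, a GM shell and three effect regions.
#' Baselines are typical quantitative-map values (MTsat 1.8 p.u., PD 80 p.u.,
#' R1 0.65 1/s, R2* 18 1/s); noise sd is 5% of baseline per modality with a
#' cross-modality noise correlation of 0.3; age slopes are sized so that the
#' standardized effect over the cohort age sd (21 y) is about 0.4 in the
#' affected (region, modality) pairs, with the field-typical signs (MTsat and
#' PD decrease with age, R2* increases, R1 weakly increases); gender, TIV and
#' scanner act as nuisance effects.
#'
#' @param grid_shape 3 positive integers.
#' @param smooth_fwhm_vox Gaussian smoothing FWHM in voxels.
#' @param seed integer seed.
#' @param null_effects if `TRUE`, all slopes and offsets are zero (noise-only
#'   phantom used for calibration studies).
#' @return object of class `phantom_spec`.
#' @export
default_phantom_spec <- function(grid_shape = c(16L, 16L, 16L),
                                 smooth_fwhm_vox = 2,
                                 seed = 1L,
                                 null_effects = FALSE) {
  geom <- default_phantom_geometry(grid_shape)
  mods <- c("MTsat", "PD", "R1", "R2s")
  baseline <- c(MTsat = 1.8, PD = 80, R1 = 0.65, R2s = 18)
  noise_sd <- 0.05 * baseline
  # slope = standardized amplitude * noise sd / age sd (21 y)
  amp <- c(MTsat = -0.4, PD = -0.4, R1 = 0.1, R2s = 0.4)
  slope <- amp * noise_sd / 21
  eff <- do.call(rbind, lapply(1:3, function(r) {
    data.frame(region = r, modality = mods,
               baseline = unname(baseline[mods]),
               age_slope = unname(slope[mods]),
               tiv_slope = unname(0.001 * noise_sd[mods]),
               gender_offset = unname(0.3 * noise_sd[mods]),
               scanner_offset = unname(0.5 * noise_sd[mods]),
               stringsAsFactors = FALSE)
  }))
  if (null_effects) {
    eff$age_slope <- 0; eff$tiv_slope <- 0
    eff$gender_offset <- 0; eff$scanner_offset <- 0
  }
  corr <- matrix(0.3, 4, 4); diag(corr) <- 1
  phantom_spec(grid_shape, geom$region_labels, geom$gm_mask, geom$wm_mask,
               eff, noise_sd, corr, smooth_fwhm_vox = smooth_fwhm_vox,
               modalities = mods, seed = seed)
}

#' Phantom with opposite-signed age effects split across modalities
#'
#' In region 1 only, MTsat decreases and R2* increases with age at equal
#' standardized amplitude; PD and R1 carry no age effect anywhere. Used to
#' probe the sensitivity advantage of the multivariate test when individual
#' modalities change in opposite directions.
#'
#' @inheritParams default_phantom_spec
#' @param amplitude standardized age-effect amplitude over the cohort age sd.
#' @export
opposite_effects_phantom_spec <- function(grid_shape = c(16L, 16L, 16L),
                                          amplitude = 0.4,
                                          smooth_fwhm_vox = 2,
                                          seed = 1L) {
  spec <- default_phantom_spec(grid_shape, smooth_fwhm_vox, seed)
  eff <- spec$effect_table
  eff$age_slope <- 0
  sel <- eff$region == 1 & eff$modality == "MTsat"
  eff$age_slope[sel] <- -amplitude * spec$noise_sd["MTsat"] / 21
  sel <- eff$region == 1 & eff$modality == "R2s"
  eff$age_slope[sel] <- amplitude * spec$noise_sd["R2s"] / 21
  spec$effect_table <- eff
  spec
}

#' Generate multimodal parameter-map stacks from a phantom specification
#'
#' For each voxel in region r and modality m the subject-i value is
#' `baseline + age_slope * (age_i - mean age) + tiv_slope * (TIV_i - mean TIV)
#' + gender_offset * male_i + scanner_offset * scanner2_i + noise`, where the
#' noise vector across modalities has covariance
#' `diag(noise_sd) %*% noise_corr %*% diag(noise_sd)`, i.i.d. across voxels
#' and subjects. Each modality volume is then Gaussian-smoothed with
#' `smooth_fwhm_vox`. Background voxels carry noise only.
#'
#' @param cov covariate table from [generate_covariates()].
#' @param spec a [phantom_spec()].
#' @param seed optional integer overriding `spec$seed`.
#' @return object of class `multimodal_dataset`.
#' @export
generate_maps <- function(cov, spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- nrow(cov)
  g <- spec$grid_shape
  V <- prod(g)
  p <- length(spec$modalities)
  set.seed(seed %||% spec$seed)

  # correlated noise: (n*V) x p standard normals times an upper-triangular
  # factor of the covariance; diag(sd) on the right keeps zero-noise
  # modalities valid
  ch <- spec$chol_corr %*% diag(spec$noise_sd, p)
  eps <- matrix(stats::rnorm(as.double(n) * V * p), ncol = p) %*% ch

  mats <- vector("list", p)
  names(mats) <- spec$modalities
  for (m in seq_len(p)) mats[[m]] <- matrix(eps[, m], nrow = V, ncol = n)

  if (n > 0) {
    age_c <- cov$age - mean(cov$age)
    tiv_c <- cov$tiv - mean(cov$tiv)
    male <- as.numeric(cov$gender == "M")
    sc2 <- as.numeric(cov$scanner == "scanner2")
    for (i in seq_len(nrow(spec$effect_table))) {
      row <- spec$effect_table[i, ]
      vox <- which(spec$region_labels == row$region)
      if (!length(vox)) next
      subj_eff <- row$baseline + row$age_slope * age_c +
        row$tiv_slope * tiv_c + row$gender_offset * male +
        row$scanner_offset * sc2
      mats[[row$modality]][vox, ] <- mats[[row$modality]][vox, ] +
        rep(subj_eff, each = length(vox))
    }
  }

  stacks <- lapply(mats, function(m) {
    arr <- array(m, c(g, n))
    smooth_gaussian(arr, spec$smooth_fwhm_vox)
  })
  multimodal_dataset(stacks = stacks,
                     gm_mask = spec$gm_mask,
                     wm_mask = spec$wm_mask,
                     region_labels = spec$region_labels,
                     covariates = cov,
                     modalities = spec$modalities)
}
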