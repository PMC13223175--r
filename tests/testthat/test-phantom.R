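test_that("covariate generation respects range, moments and fractions", {
  cov <- generate_covariates(138, seed = 1)
  expect_equal(nrow(cov), 138)
  expect_true(all(cov$age >= 19 & cov$age <= 75))
  expect_setequal(unique(cov$gender), c("F", "M"))

  # empty case
  empty <- generate_covariates(0)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("participant_id", "age", "gender", "tiv", "scanner"))

  # law-of-large-numbers check against the configured parameters
  big <- generate_covariates(10000, seed = 1)
  expect_lt(abs(mean(big$age) - 46.64), 1.0)
  expect_lt(abs(mean(big$gender == "M") - 0.355), 0.02)

  # determinism and the minimum-2-per-scanner guarantee
  expect_identical(generate_covariates(25, seed = 9),
                   generate_covariates(25, seed = 9))
  for (s in 1:20) {
    sc <- generate_covariates(4, seed = s)$scanner
    expect_gte(min(table(factor(sc, c("scanner1", "scanner2")))), 2)
  }

  expect_error(generate_covariates(10, male_fraction = 1.2), "fractions")
  expect_error(generate_covariates(10, age_range = c(50, 30)), "age_range")
})

test_that("bimodal age mode stays within range and is reproducible", {
  cov <- generate_covariates(500, age_mode = "bimodal", seed = 3)
  expect_true(all(cov$age >= 19 & cov$age <= 75))
  # mixture should put mass in both the young and elderly lobes
  expect_gt(mean(cov$age < 35), 0.25)
  expect_gt(mean(cov$age > 50), 0.25)
})

test_that("phantom spec validation enforces its invariants", {
  geom <- voxmanova:::default_phantom_geometry(c(8L, 8L, 8L))
  eff <- data.frame(region = 1, modality = "MTsat", baseline = 1,
                    age_slope = 0, tiv_slope = 0, gender_offset = 0,
                    scanner_offset = 0)
  ok_corr <- diag(4)
  # overlapping tissue masks rejected
  expect_error(phantom_spec(c(8, 8, 8), geom$region_labels, geom$gm_mask,
                            geom$gm_mask, eff, 1, ok_corr),
               "disjoint")
  # region outside tissue rejected
  lab <- array(0L, c(8, 8, 8)); lab[1, 1, 1] <- 1L
  expect_error(phantom_spec(c(8, 8, 8), lab, geom$gm_mask, geom$wm_mask,
                            eff, 1, ok_corr),
               "tissue mask")
  # non-positive-definite noise correlation rejected
  bad <- matrix(0.99, 4, 4); bad[1, 2] <- bad[2, 1] <- -0.99; diag(bad) <- 1
  expect_error(phantom_spec(c(8, 8, 8), geom$region_labels, geom$gm_mask,
                            geom$wm_mask, eff, 1, bad),
               "positive definite")
})

test_that("zero-noise zero-slope phantom reproduces the baseline exactly", {
  spec <- tiny_spec(noise_sd = 0, baseline = 2.5)
  cov <- generate_covariates(4, seed = 2)
  ds <- generate_maps(cov, spec)
  vox <- which(spec$region_labels == 1)
  for (i in 1:4) {
    vol <- ds$stacks$R2s[, , , i]
    expect_equal(unname(vol[vox]), rep(2.5, length(vox)))
    expect_equal(unname(vol[spec$region_labels == 0]),
                 rep(0, sum(spec$region_labels == 0)))
  }
})

test_that("injected age slope is recovered by per-voxel OLS", {
  spec <- tiny_spec(grid = c(8L, 8L, 8L), age_slope = 0.5, seed = 7)
  cov <- generate_covariates(200, seed = 7)
  ds <- generate_maps(cov, spec)
  age_c <- cov$age - mean(cov$age)
  Y <- flatten_stack_test(ds$stacks$R2s, spec$region_labels == 1)
  slopes <- apply(Y, 2, function(y) sum(y * age_c) / sum(age_c^2))
  expect_lt(abs(mean(slopes) - 0.5), 0.05)
})

test_that("cross-modality noise correlation is reproduced at background voxels", {
  corr <- diag(4); corr[1, 2] <- corr[2, 1] <- 0.8
  spec <- tiny_spec(grid = c(4L, 4L, 4L), noise_corr = corr, seed = 11)
  cov <- generate_covariates(2000, seed = 11)
  ds <- generate_maps(cov, spec)
  bg <- which(spec$region_labels == 0)[1]
  ijk <- arrayInd(bg, c(4, 4, 4))
  a <- ds$stacks$MTsat[ijk[1], ijk[2], ijk[3], ]
  b <- ds$stacks$PD[ijk[1], ijk[2], ijk[3], ]
  expect_lt(abs(cor(a, b) - 0.8), 0.05)
})

test_that("map generation is deterministic given (spec, seed)", {
  spec <- default_phantom_spec(c(8L, 8L, 8L), seed = 5)
  cov <- generate_covariates(6, seed = 5)
  expect_identical(generate_maps(cov, spec), generate_maps(cov, spec))
})

test_that("gaussian smoothing matches a direct shift-and-add convolution", {
  set.seed(1)
  arr <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  expect_equal(smooth_gaussian(arr, 2), oracle_smooth3d(arr, 2),
               tolerance = 1e-12)
  expect_identical(smooth_gaussian(arr, 0), arr)
})

test_that("dataset write/read round-trips arrays, masks and covariates", {
  spec <- tiny_spec(grid = c(5L, 5L, 4L), seed = 3)
  cov <- generate_covariates(2, seed = 3)
  ds <- generate_maps(cov, spec)
  dir <- tempfile("ds_")
  write_dataset(ds, dir, spec = spec)
  back <- read_dataset(dir)
  for (m in ds$modalities) expect_equal(back$stacks[[m]], ds$stacks[[m]])
  expect_identical(back$gm_mask, ds$gm_mask)
  expect_identical(back$wm_mask, ds$wm_mask)
  expect_equal(back$covariates$age, ds$covariates$age)
  expect_identical(back$covariates$gender, ds$covariates$gender)
  # disjointness preserved through the round trip
  expect_true(all(back$gm_mask * back$wm_mask == 0))
  unlink(dir, recursive = TRUE)
})

test_that("dataset manifest has one volume per subject x modality", {
  spec <- default_phantom_spec(c(16L, 16L, 16L), seed = 4)
  cov <- generate_covariates(20, seed = 4)
  ds <- generate_maps(cov, spec)
  dir <- tempfile("ds_")
  files <- write_dataset(ds, dir)
  subject_vols <- grep("sub-\\d+_", basename(files), value = TRUE)
  expect_length(subject_vols, 20 * 4)
  expect_length(grep("mask|labels", basename(files)), 3)
  expect_length(grep("participants.tsv", basename(files)), 1)
  unlink(dir, recursive = TRUE)

  # empty dataset: masks only, no subject files
  ds0 <- generate_maps(generate_covariates(0), tiny_spec())
  dir0 <- tempfile("ds0_")
  files0 <- write_dataset(ds0, dir0)
  expect_length(grep("sub-", basename(files0)), 0)
  unlink(dir0, recursive = TRUE)
})
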