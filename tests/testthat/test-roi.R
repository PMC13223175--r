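test_that("fisher z and its standard error behave as documented", {
  expect_equal(fisher_z(0), 0)
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(tanh(fisher_z(rs)), rs, tolerance = 1e-12)
  expect_equal(fisher_z_se(138), 1 / sqrt(135))
  expect_equal(fisher_z_se(138, 3, adjusted = TRUE), 1 / sqrt(132))
  expect_error(fisher_z_se(3), "too few")
})

test_that("ROI medians match a direct recomputation", {
  spec <- tiny_spec(grid = c(6L, 6L, 6L), seed = 61)
  fx <- standardized_fixture(15, spec)
  roi <- (fx$ds$region_labels == 1) * 1L
  dim(roi) <- dim(fx$ds$region_labels)
  med <- extract_roi_medians(fx$std, roi)
  expect_equal(dim(med), c(15L, 4L))
  m <- (roi != 0) & (fx$std$analysis_mask != 0)
  for (mod in fx$std$modalities) {
    Y <- flatten_stack_test(fx$std$stacks[[mod]], m)
    expect_equal(unname(med[, mod]), unname(apply(Y, 1, median)),
                 tolerance = 1e-12)
  }

  # single-voxel ROI returns that voxel's values
  one <- array(0L, dim(roi))
  vox <- which(m)[1]
  one[vox] <- 1L
  ijk <- arrayInd(vox, dim(roi))[1, ]
  med1 <- extract_roi_medians(fx$std, one)
  expect_equal(unname(med1[, "MTsat"]),
               fx$std$stacks$MTsat[ijk[1], ijk[2], ijk[3], ])

  # robustness of the median to an outlying voxel
  expect_equal(median(c(1, 2, 100)), 2)
  empty <- array(0L, dim(roi))
  expect_error(extract_roi_medians(fx$std, empty, roi_name = "cerebellum"),
               "cerebellum")
})

test_that("partial correlation equals plain Pearson without nuisance and
           matches the inverse-correlation oracle with it", {
  set.seed(62)
  n <- 80
  age <- runif(n, 19, 75)
  tiv <- rnorm(n, 1450, 130)
  gender <- sample(c("F", "M"), n, replace = TRUE)
  y <- -0.02 * age + 0.002 * tiv + rnorm(n, 0, 0.5)

  pc0 <- partial_correlation(y, age)
  ct <- cor.test(y, age)
  expect_equal(pc0$r_partial, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc0$p_value, ct$p.value, tolerance = 1e-10)

  nuis <- data.frame(gender = gender, tiv = tiv)
  pc <- partial_correlation(y, age, nuis)
  Z <- cbind(as.numeric(factor(gender)), tiv)
  expect_equal(pc$r_partial, oracle_partial_cor(y, age, Z), tolerance = 1e-10)
  expect_equal(pc$fisher_z, atanh(pc$r_partial), tolerance = 1e-12)
  expect_equal(pc$df, n - 2 - 2)

  # invariance to affine rescaling of both variables
  pc2 <- partial_correlation(10 * y + 3, age, nuis)
  expect_equal(pc2$r_partial, pc$r_partial, tolerance = 1e-10)
  pc3 <- partial_correlation(y, 2 * age - 5, nuis)
  expect_equal(pc3$r_partial, pc$r_partial, tolerance = 1e-10)

  expect_error(partial_correlation(rep(1, n), age, nuis), "zero-variance")
})

test_that("linear age trend matches lm and its sign matches the
           correlation", {
  set.seed(63)
  age <- runif(40, 19, 75)
  y <- 1.5 - 0.03 * age + rnorm(40, 0, 0.2)
  tr <- linear_age_trend(y, age)
  ref <- coef(lm(y ~ age))
  expect_equal(tr$intercept, unname(ref[1]), tolerance = 1e-10)
  expect_equal(tr$slope, unname(ref[2]), tolerance = 1e-10)
  expect_equal(sign(tr$slope), sign(cor(y, age)))
  # exactly linear data leave zero residuals
  tr0 <- linear_age_trend(2 + 0.5 * age, age)
  expect_lt(max(abs(2 + 0.5 * age - tr0$fitted)), 1e-10)
  expect_error(linear_age_trend(y, rep(40, 40)), "constant")
})

test_that("peak canonical vector flags the effect-carrying modality", {
  spec <- tiny_spec(grid = c(8L, 8L, 8L), age_slope = 1 / 21, seed = 64,
                    region_modality = "MTsat")
  fx <- standardized_fixture(300, spec, seed_cov = 64)
  map <- mglm_map(fx$std, fx$X)
  roi <- (fx$ds$region_labels == 1) * 1L
  dim(roi) <- dim(fx$ds$region_labels)
  pk <- peak_canonical_vector(map, roi)
  expect_equal(names(which.max(pk$weights)), "MTsat")
  expect_equal(sum(pk$weights^2), 1, tolerance = 1e-10)
  expect_true(all(pk$weights >= 0))

  # single-voxel ROI: that voxel is the peak
  one <- array(0L, dim(roi))
  vox <- which((roi != 0) & (map$mask != 0))[3]
  one[vox] <- 1L
  pk1 <- peak_canonical_vector(map, one)
  expect_equal(pk1$peak, arrayInd(vox, dim(roi))[1, ], ignore_attr = TRUE)
  expect_error(peak_canonical_vector(map, array(0L, dim(roi))), "intersect")
})

test_that("the ROI table mirrors the region x modality layout", {
  spec <- tiny_spec(grid = c(6L, 6L, 6L), age_slope = 0.6 / 21, seed = 65)
  fx <- standardized_fixture(60, spec, seed_cov = 65)
  tab <- roi_table(fx$std)
  expect_equal(nrow(tab), length(unique(tab$roi)) * 4)
  expect_named(tab, c("roi", "modality", "r", "p", "fisher_z", "se_z", "n"))
  expect_true(all(abs(tab$r) <= 1))
  expect_equal(tab$fisher_z, atanh(tab$r), tolerance = 1e-12)
  expect_equal(unique(tab$se_z), 1 / sqrt(60 - 3))
  # the injected R2* effect in region 1 should give its largest |r| there
  r2s <- tab[tab$modality == "R2s" & tab$roi == "region1", "r"]
  expect_gt(r2s, 0.3)
})
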