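test_that("bonferroni across maps divides the level", {
  expect_equal(bonferroni_across_maps(0.05, 4), 0.0125)
  expect_equal(bonferroni_across_maps(0.05, 1), 0.05)
  expect_equal(bonferroni_across_maps(0.01, 2), 0.005)
  expect_error(bonferroni_across_maps(1.5, 2), "alpha")
  expect_error(bonferroni_across_maps(0.05, 0), "m must")
})

test_that("voxel bonferroni thresholds at alpha over the mask size", {
  mask <- array(1L, c(4, 4, 2))
  p <- array(1, c(4, 4, 2))
  stat <- array(0, c(4, 4, 2))
  m1 <- stat_map(stat, p, mask, c(1, 30), "F_uni")
  thr1 <- fwer_voxel_bonferroni(m1, 0.05)
  expect_equal(sum(thr1$binary), 0)
  expect_equal(nrow(thr1$cluster_table), 0)

  p[2, 3, 1] <- 0.04 / 32               # just below alpha / V
  m2 <- stat_map(stat, p, mask, c(1, 30), "F_uni")
  thr2 <- fwer_voxel_bonferroni(m2, 0.05)
  expect_equal(sum(thr2$binary), 1)
  expect_equal(thr2$binary[2, 3, 1], 1L)

  expect_error(fwer_voxel_bonferroni(
    stat_map(stat, p, array(0L, c(4, 4, 2)), c(1, 30), "F_uni"), 0.05),
    "empty mask")
})

test_that("lowering alpha never adds significant voxels", {
  spec <- tiny_spec(grid = c(8L, 8L, 8L), age_slope = 0.25, seed = 41)
  fx <- standardized_fixture(60, spec)
  map <- mglm_map(fx$std, fx$X, keep_canonical = FALSE)
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  counts <- sapply(alphas, function(a) sum(fwer_voxel_bonferroni(map, a)$binary))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster labelling follows the chosen 3D connectivity", {
  empty <- array(0L, c(5, 5, 5))
  out <- label_clusters(empty)
  expect_equal(nrow(out$cluster_table), 0)
  expect_equal(sum(out$labels), 0)

  # two voxels sharing a face form one cluster under connectivity 6
  b <- array(0L, c(5, 5, 5)); b[2, 2, 2] <- 1L; b[3, 2, 2] <- 1L
  out6 <- label_clusters(b, 6)
  expect_equal(nrow(out6$cluster_table), 1)
  expect_equal(out6$cluster_table$size_voxels, 2)

  # two blobs of sizes 3 and 4 touching only diagonally: merged under 26,
  # separate under 6
  bb <- array(0L, c(5, 5, 5))
  bb[1:3, 1, 1] <- 1L                        # blob of 3
  bb[4, 2, 2] <- 1L; bb[5, 2, 2] <- 1L       # blob of 4
  bb[4, 3, 2] <- 1L; bb[5, 3, 2] <- 1L
  out26 <- label_clusters(bb, 26)
  expect_equal(nrow(out26$cluster_table), 1)
  expect_equal(out26$cluster_table$size_voxels, 7)
  out6b <- label_clusters(bb, 6)
  expect_equal(sort(out6b$cluster_table$size_voxels), c(3, 4))

  # cluster sizes always sum to the number of significant voxels
  set.seed(41)
  rnd <- array(rbinom(6^3, 1, 0.25), c(6, 6, 6))
  for (conn in c(6, 18, 26)) {
    o <- label_clusters(rnd, conn)
    expect_equal(sum(o$cluster_table$size_voxels), sum(rnd))
    expect_equal(sum(o$labels > 0), sum(rnd))
  }
  expect_error(label_clusters(rnd, 7), "connectivity")
})

test_that("cluster peaks carry the maximal statistic of each component", {
  b <- array(0L, c(4, 4, 1)); b[1:2, 1, 1] <- 1L; b[4, 4, 1] <- 1L
  s <- array(0, c(4, 4, 1)); s[1, 1, 1] <- 3; s[2, 1, 1] <- 9; s[4, 4, 1] <- 5
  out <- label_clusters(b, 6, stat = s)
  tab <- out$cluster_table
  expect_equal(tab$peak_stat[tab$size_voxels == 2], 9)
  expect_equal(tab$peak_x[tab$size_voxels == 2], 2)
  expect_equal(tab$peak_stat[tab$size_voxels == 1], 5)
})

test_that("permutation thresholding is reproducible and validates inputs", {
  spec <- tiny_spec(grid = c(6L, 6L, 6L), seed = 42)
  fx <- standardized_fixture(24, spec)
  t1 <- fwer_permutation_maxstat(fx$std, fx$X, alpha = 0.05, n_perm = 120,
                                 seed = 77)
  t2 <- fwer_permutation_maxstat(fx$std, fx$X, alpha = 0.05, n_perm = 120,
                                 seed = 77)
  expect_identical(t1$null_max, t2$null_max)
  expect_identical(t1$binary, t2$binary)
  expect_error(fwer_permutation_maxstat(fx$std, fx$X, n_perm = 50), "n_perm")
  expect_error(fwer_permutation_maxstat(fx$std, fx$X, alpha = 0.001,
                                        n_perm = 150), "too small")
})

test_that("single-modality permutation thresholding uses the univariate
           statistic", {
  spec <- tiny_spec(grid = c(6L, 6L, 6L), seed = 44)
  fx <- standardized_fixture(24, spec)
  thr <- fwer_permutation_maxstat(fx$std, fx$X, alpha = 0.05, n_perm = 120,
                                  seed = 5, modalities = "R2s")
  um <- uglm_map(fx$std, "R2s", fx$X)
  idx <- which(fx$std$analysis_mask != 0)
  expect_equal(thr$stat[idx], um$stat[idx], tolerance = 1e-8)
})

test_that("a strong injected effect survives permutation FWER with high
           power", {
  # standardized age slope 1.2 over the age sd explains well over 25% of
  # the variance at n = 100
  spec <- tiny_spec(grid = c(8L, 8L, 8L), age_slope = 1.2 / 21, seed = 43)
  fx <- standardized_fixture(100, spec, seed_cov = 43)
  thr <- fwer_permutation_maxstat(fx$std, fx$X, alpha = 0.05, n_perm = 199,
                                  seed = 43)
  region <- (fx$ds$region_labels == 1) & (fx$std$analysis_mask == 1)
  expect_gt(mean(thr$binary[region]), 0.8)
})

test_that("permutation is at least as powerful as bonferroni on smooth maps", {
  wins <- 0
  for (r in 1:10) {
    spec <- default_phantom_spec(seed = 400 + r)
    fx <- standardized_fixture(50, spec, seed_cov = 500 + r)
    map <- mglm_map(fx$std, fx$X, keep_canonical = FALSE)
    nb <- sum(fwer_voxel_bonferroni(map, 0.05)$binary)
    np <- sum(fwer_permutation_maxstat(fx$std, fx$X, alpha = 0.05,
                                       n_perm = 199, seed = 600 + r)$binary)
    if (np >= nb) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
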