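test_that("multivariate fit reduces to univariate columns and matches the
           oracle covariance", {
  cov <- generate_covariates(40, seed = 21)
  X <- build_design(cov)
  set.seed(21)
  Y <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(NULL, c("MTsat", "PD", "R1", "R2s")))
  fit <- mglm(Y, X)
  ufit <- fit_uglm(Y, X)
  expect_equal(unname(coef(fit)), unname(ufit$beta), tolerance = 1e-12)
  orc <- oracle_mglm(Y, unclass(X))
  expect_equal(unname(fit$sigma), unname(orc$Sigma), tolerance = 1e-10)
  # residuals orthogonal to the design's column space
  expect_lt(max(abs(t(unclass(X)) %*% residuals(fit))), 1e-8)

  # noiseless data recovered exactly
  B0 <- matrix(rnorm(20), 5, 4)
  fit0 <- mglm(unclass(X) %*% B0, X)
  expect_equal(unname(coef(fit0)), B0, tolerance = 1e-10)
  expect_lt(max(abs(fit0$sigma)), 1e-16)

  expect_error(mglm(matrix(rnorm(8 * 4), 8, 4), X[1:8, ]), "deficit")
})

test_that("wilks test reports the exact df and honours the null identity", {
  cov <- generate_covariates(138, seed = 22)
  X <- build_design(cov)
  set.seed(22)
  Y <- matrix(rnorm(138 * 4), 138, 4)
  wt <- wilks_test(mglm(Y, X), age_contrast(5, 4))
  expect_equal(c(wt$df1, wt$df2), c(4, 130))
  expect_true(wt$exact)
  expect_true(wt$lambda > 0 && wt$lambda <= 1)

  # data residualized on the whole design: C B L = 0 exactly -> lambda 1, F 0
  Y0 <- qr.resid(qr(unclass(X)), Y)
  wt0 <- wilks_test(mglm(Y0, X), age_contrast(5, 4))
  expect_equal(wt0$lambda, 1, tolerance = 1e-12)
  expect_equal(wt0$F, 0, tolerance = 1e-10)
  expect_equal(wt0$p.value, 1)
})

test_that("wilks lambda matches determinant and eigenvalue oracles", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(25:45, 1)
    p <- sample(2:4, 1)
    cov <- generate_covariates(n, seed = 23 + rep)
    X <- build_design(cov)
    Y <- matrix(rnorm(n * p), n, p)
    hc <- age_contrast(5, p)
    wt <- wilks_test(mglm(Y, X), hc)
    orc <- oracle_wilks(Y, unclass(X), hc$C, hc$L)
    expect_equal(wt$lambda, orc$lambda_det, tolerance = 1e-10)
    expect_equal(wt$lambda, orc$lambda_eig, tolerance = 1e-10)
    expect_equal(wt$F, orc$F, tolerance = 1e-10)
  }
})

test_that("wilks test agrees with car::linearHypothesis on the age effect", {
  cov <- generate_covariates(60, seed = 24)
  X <- build_design(cov)
  set.seed(24)
  Y <- matrix(rnorm(60 * 4), 60, 4)
  wt <- wilks_test(mglm(Y, X), age_contrast(5, 4))
  Xm <- unclass(X)
  mfit <- lm(Y ~ Xm[, -1])
  lh <- car::linearHypothesis(mfit, "Xm[, -1]age = 0", test = "Wilks")
  expect_equal(unname(wt$H), unname(lh$SSPH), tolerance = 1e-8)
  expect_equal(unname(wt$E_sscp), unname(lh$SSPE), tolerance = 1e-8)
  expect_equal(wt$lambda, det(lh$SSPE) / det(lh$SSPE + lh$SSPH),
               tolerance = 1e-10)
  # the printed car summary carries the same Wilks statistic and df
  txt <- capture.output(print(lh))
  wilks_line <- grep("^Wilks", txt, value = TRUE)
  toks <- strsplit(trimws(sub("^Wilks", "", wilks_line)), "\\s+")[[1]]
  nums <- suppressWarnings(as.numeric(toks))
  expect_equal(wt$lambda, nums[2], tolerance = 1e-4)
  expect_equal(wt$F, nums[3], tolerance = 1e-3)
  expect_equal(c(wt$df1, wt$df2), nums[4:5])
})

test_that("p = 1 wilks F reduces to the univariate F", {
  cov <- generate_covariates(35, seed = 25)
  X <- build_design(cov)
  set.seed(25)
  y <- rnorm(35)
  wt <- wilks_test(mglm(y, X), age_contrast(5, 1))
  fu <- f_test(fit_uglm(y, X), c(0, 1, 0, 0, 0))
  expect_equal(wt$F, unname(fu$F), tolerance = 1e-10)
  expect_equal(wt$df2, fu$df2)
})

test_that("a multi-row contrast uses Rao's approximation consistently", {
  cov <- generate_covariates(45, seed = 26)
  X <- build_design(cov)
  set.seed(26)
  Y <- matrix(rnorm(45 * 3), 45, 3)
  C <- rbind(c(0, 1, 0, 0, 0), c(0, 0, 1, 0, 0))
  hc <- mglm_contrast(C, diag(3))
  wt <- wilks_test(mglm(Y, X), hc)
  orc <- oracle_wilks(Y, unclass(X), C, diag(3))
  expect_equal(wt$lambda, orc$lambda_det, tolerance = 1e-10)
  # Rao df1 = l*c; F recovers lambda through the stated transform
  expect_equal(wt$df1, 6)
  tt <- sqrt((9 * 4 - 4) / (9 + 4 - 5))
  m <- 45 - 5 - (3 - 2 + 1) / 2
  df2 <- m * tt - 3 + 1
  expect_equal(wt$df2, df2, tolerance = 1e-10)
  lam_t <- wt$lambda^(1 / tt)
  expect_equal(wt$F, (1 - lam_t) / lam_t * df2 / 6, tolerance = 1e-10)
})

test_that("wilks inference is invariant to invertible modality mixing", {
  cov <- generate_covariates(50, seed = 27)
  X <- build_design(cov)
  set.seed(27)
  Y <- matrix(rnorm(50 * 4), 50, 4)
  A <- matrix(rnorm(16), 4, 4) + diag(4) * 2
  hc <- age_contrast(5, 4)
  w1 <- wilks_test(mglm(Y, X), hc)
  w2 <- wilks_test(mglm(Y %*% A, X), hc)
  expect_equal(w1$lambda, w2$lambda, tolerance = 1e-8)
  expect_equal(w1$F, w2$F, tolerance = 1e-8)
  expect_equal(w1$p.value, w2$p.value, tolerance = 1e-8)
})

test_that("canonical decomposition has the documented structure", {
  cov <- generate_covariates(138, seed = 28)
  X <- build_design(cov)
  set.seed(28)
  Y <- matrix(rnorm(138 * 4), 138, 4)
  cv <- canonical_vectors(mglm(Y, X), age_contrast(5, 4))
  # 4 dependent variables vs 4 non-intercept regressors -> 4 possible variates
  expect_equal(cv$n_variates, 4)
  # rank-1 hypothesis: exactly one nonzero eigenvalue
  expect_gt(cv$eigenvalues[1], 0)
  expect_lt(max(abs(cv$eigenvalues[-1])), 1e-10)
  # unit Euclidean norm columns
  expect_equal(unname(colSums(cv$weights^2)), rep(1, 4), tolerance = 1e-10)
  # lambda factorizes over the eigenvalues
  wt <- wilks_test(mglm(Y, X), age_contrast(5, 4))
  expect_equal(wt$lambda, prod(1 / (1 + cv$eigenvalues)), tolerance = 1e-10)
  # error-scaled normalization satisfies v' Sigma v = 1
  cve <- canonical_vectors(mglm(Y, X), age_contrast(5, 4), normalize = "error")
  fit <- mglm(Y, X)
  q <- diag(t(cve$weights) %*% fit$sigma %*% cve$weights)
  expect_equal(unname(q), rep(1, 4), tolerance = 1e-8)
})

test_that("the dominant canonical weight points at the effect-carrying
           modality", {
  cov <- generate_covariates(500, seed = 29)
  X <- build_design(cov)
  set.seed(129)  # stream independent of the covariate draws
  age_c <- unclass(X)[, "age"]
  Y <- matrix(rnorm(500 * 4), 500, 4)
  Y[, 1] <- Y[, 1] + 0.03 * age_c     # only modality 1 carries the effect
  cv <- canonical_vectors(mglm(Y, X), age_contrast(5, 4))
  expect_equal(which.max(abs(cv$weights[, 1])), 1L, ignore_attr = TRUE)
})
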