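# Vectorized voxelwise Wilks machinery -----------------------------------
#
# Ylist: list of l' = p modality matrices (n x V). The contrast's L matrix is
# applied first (forming l tested variates); the per-voxel error and
# hypothesis SSCP matrices are then accumulated as V-vectors per (j, k)
# entry, and lambda = det(E)/det(E + H) is evaluated with the vectorized
# small-matrix determinants, so no per-voxel R loop is needed.
wilks_map_engine <- function(Ylist, X, contrast, keep_parts = FALSE) {
  X <- unclass(X)
  n <- nrow(X); k <- ncol(X)
  C <- contrast$C; L <- contrast$L
  cc <- contrast$c; l <- contrast$l
  p <- length(Ylist)
  if (nrow(L) != p) stop_cfg("L has ", nrow(L), " rows; data has p = ", p)
  if (ncol(C) != k) stop_cfg("C has ", ncol(C), " columns; design has k = ", k)
  if (n <= k + l - 1) stop_cfg("n must exceed k + l - 1 (df deficit)")
  qx <- qr(X)
  if (qx$rank < k) stop_cfg("design matrix is rank deficient")
  xtx_inv <- chol2inv(qr.R(qx))
  W <- C %*% xtx_inv %*% t(C)
  Wi <- solve(W)

  # tested variates Z_j = sum_m L[m, j] * Y_m
  Z <- vector("list", l)
  for (j in seq_len(l)) {
    acc <- 0
    for (m in seq_len(p)) if (L[m, j] != 0) acc <- acc + L[m, j] * Ylist[[m]]
    Z[[j]] <- acc
  }
  G <- vector("list", l)          # G[[j]]: c x V hypothesis estimates C B_j
  R <- vector("list", l)          # residual matrices n x V
  for (j in seq_len(l)) {
    B <- qr.coef(qx, Z[[j]])
    G[[j]] <- C %*% B
    R[[j]] <- Z[[j]] - X %*% B
  }
  pp <- l * l
  Ecols <- vector("list", pp)
  Tcols <- vector("list", pp)
  for (j in seq_len(l)) {
    for (kk in j:l) {
      e_jk <- colSums(R[[j]] * R[[kk]])
      h_jk <- 0
      for (a in seq_len(cc)) for (b in seq_len(cc))
        h_jk <- h_jk + Wi[a, b] * G[[j]][a, ] * G[[kk]][b, ]
      Ecols[[(kk - 1L) * l + j]] <- e_jk
      Ecols[[(j - 1L) * l + kk]] <- e_jk
      Tcols[[(kk - 1L) * l + j]] <- e_jk + h_jk
      Tcols[[(j - 1L) * l + kk]] <- e_jk + h_jk
    }
  }
  detE <- det_vec(Ecols, l)
  detT <- det_vec(Tcols, l)
  bad <- which(!(detE > 0))
  if (length(bad))
    stop_cfg("singular error SSCP at voxel index ", bad[1],
             " of the mask; check mask hygiene / valid-mask construction")
  lambda <- pmin(detE / detT, 1)
  fr <- wilks_to_F(lambda, n, k, l, cc)
  out <- list(lambda = lambda, F = fr$F, df1 = fr$df1, df2 = fr$df2,
              p = stats::pf(fr$F, fr$df1, fr$df2, lower.tail = FALSE),
              exact = fr$exact, n = n, k = k, l = l, c = cc)
  if (keep_parts) {
    out$Ecols <- Ecols
    out$G <- G
    out$Wi <- Wi
  }
  out
}

# Precomputed projection plan for repeated Wilks evaluations on one design
# (the permutation loop): thin Q of X for the error SSCP and the n x c
# matrix A = X (X'X)^-1 C' whose columns turn data into hypothesis
# estimates (G = A' Z).
wilks_plan <- function(X, contrast) {
  X <- unclass(X)
  n <- nrow(X); k <- ncol(X)
  C <- contrast$C; L <- contrast$L
  qx <- qr(X)
  if (qx$rank < k) stop_cfg("design matrix is rank deficient")
  xtx_inv <- chol2inv(qr.R(qx))
  W <- C %*% xtx_inv %*% t(C)
  list(Q = qr.Q(qx), A = X %*% xtx_inv %*% t(C), Wi = solve(W),
       n = n, k = k, l = contrast$l, cc = contrast$c, L = L)
}

# Smallest Wilks lambda over the voxels (the maximum statistic), computed
# without per-voxel p-values or residual matrices: E = Z'Z - (Q'Z)'(Q'Z).
lambda_min_fast <- function(plan, Zlist) {
  l <- plan$l; cc <- plan$cc
  n <- plan$n; k <- plan$k
  V <- ncol(Zlist[[1]])
  QtZ <- lapply(Zlist, function(Z) crossprod(plan$Q, Z))
  G <- vector("list", l)
  for (j in seq_len(l)) G[[j]] <- crossprod(plan$A, Zlist[[j]])  # cc x V
  Ecols <- vector("list", l * l)
  Tcols <- vector("list", l * l)
  for (j in seq_len(l)) {
    for (kk in j:l) {
      e_jk <- .colSums(Zlist[[j]] * Zlist[[kk]], n, V) -
        .colSums(QtZ[[j]] * QtZ[[kk]], k, V)
      h_jk <- 0
      for (a in seq_len(cc)) for (b in seq_len(cc))
        h_jk <- h_jk + plan$Wi[a, b] * G[[j]][a, ] * G[[kk]][b, ]
      Ecols[[(kk - 1L) * l + j]] <- e_jk
      Ecols[[(j - 1L) * l + kk]] <- e_jk
      Tcols[[(kk - 1L) * l + j]] <- e_jk + h_jk
      Tcols[[(j - 1L) * l + kk]] <- e_jk + h_jk
    }
  }
  min(pmin(det_vec(Ecols, l) / det_vec(Tcols, l), 1))
}

# Null distribution of the minimum Wilks lambda over the mask under
# subject-level permutations. The permuted data never materialize: with
# Zstar = Zhat + P Zres (Freedman-Lane; Zhat = 0, Zres = Z for the simple
# scheme), every needed projection U' P Zres equals (P^-1 U)' Zres, so each
# permutation only permutes the small n x (k_red + k + c) projection basis
# and runs one GEMM per variate. The per-voxel error SSCP follows from
#   Zstar'Zstar = Fh'Fh + Zres'Zres + Fh'(Qred' P Zres) + (…)' ,
# with Fh = Qred'Z and Qred the orthonormal basis of the reduced design.
maxstat_null_lambda <- function(plan, Zlist, Xred, scheme, n_perm) {
  l <- plan$l; cc <- plan$cc
  n <- plan$n; k <- plan$k
  V <- ncol(Zlist[[1]])
  fl <- scheme == "freedman_lane"
  if (fl) {
    Qred <- qr.Q(qr(Xred))
    kred <- ncol(Qred)
    Fh <- lapply(Zlist, function(Z) crossprod(Qred, Z))          # kred x V
    Zres <- lapply(seq_len(l), function(j) Zlist[[j]] - Qred %*% Fh[[j]])
    QtQred <- crossprod(plan$Q, Qred)                             # k x kred
    AtQred <- crossprod(plan$A, Qred)                             # c x kred
    QtZhat <- lapply(Fh, function(f) QtQred %*% f)
    AtZhat <- lapply(Fh, function(f) AtQred %*% f)
  } else {
    kred <- 0L
    Zres <- Zlist
  }
  U <- if (fl) cbind(Qred, plan$Q, plan$A) else cbind(plan$Q, plan$A)
  i_red <- seq_len(kred)
  i_q <- kred + seq_len(k)
  i_a <- kred + k + seq_len(cc)
  # permutation-invariant pair sums: Zres'Zres plus (Freedman-Lane) the
  # Zhat'Zhat block
  cBB <- vector("list", l * l)
  for (j in seq_len(l)) for (kk in j:l) {
    s <- .colSums(Zres[[j]] * Zres[[kk]], n, V)
    if (fl) s <- s + .colSums(Fh[[j]] * Fh[[kk]], kred, V)
    cBB[[(kk - 1L) * l + j]] <- s
  }
  qzs <- vector("list", l); gs <- vector("list", l); reds <- vector("list", l)
  out <- numeric(n_perm)
  Ecols <- vector("list", l * l)
  Tcols <- vector("list", l * l)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    Up <- U[perm, , drop = FALSE]
    for (j in seq_len(l)) {
      proj <- crossprod(Up, Zres[[j]])
      qzs[[j]] <- if (fl) proj[i_q, , drop = FALSE] + QtZhat[[j]] else
        proj[i_q, , drop = FALSE]
      gs[[j]] <- if (fl) proj[i_a, , drop = FALSE] + AtZhat[[j]] else
        proj[i_a, , drop = FALSE]
      if (fl) reds[[j]] <- proj[i_red, , drop = FALSE]
    }
    for (j in seq_len(l)) {
      for (kk in j:l) {
        e_jk <- cBB[[(kk - 1L) * l + j]] -
          .colSums(qzs[[j]] * qzs[[kk]], k, V)
        if (fl) {
          e_jk <- e_jk + .colSums(Fh[[j]] * reds[[kk]], kred, V) +
            .colSums(reds[[j]] * Fh[[kk]], kred, V)
        }
        h_jk <- 0
        for (a in seq_len(cc)) for (bb in seq_len(cc))
          h_jk <- h_jk + plan$Wi[a, bb] * gs[[j]][a, ] * gs[[kk]][bb, ]
        Ecols[[(kk - 1L) * l + j]] <- e_jk
        Ecols[[(j - 1L) * l + kk]] <- e_jk
        Tcols[[(kk - 1L) * l + j]] <- e_jk + h_jk
        Tcols[[(j - 1L) * l + kk]] <- e_jk + h_jk
      }
    }
    out[b] <- min(pmin(det_vec(Ecols, l) / det_vec(Tcols, l), 1))
  }
  out
}

# First canonical weight vector per voxel for a rank-1 hypothesis:
# v proportional to E^-1 g (g the c=1 hypothesis estimate vector), scaled to
# unit norm. Small per-voxel solves; only run when the store is requested.
first_canonical_store <- function(parts, l) {
  V <- length(parts$Ecols[[1]])
  g <- vapply(seq_len(l), function(j) parts$G[[j]][1, ], numeric(V))
  wts <- matrix(NA_real_, V, l)
  Ev <- matrix(0, l, l)
  for (v in seq_len(V)) {
    for (j in seq_len(l)) for (kk in seq_len(l))
      Ev[j, kk] <- parts$Ecols[[(kk - 1L) * l + j]][v]
    w <- solve(Ev, g[v, ])
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) wts[v, ] <- w / nrm
  }
  wts
}

#' Voxelwise multivariate GLM map with Wilks' lambda inference
#'
#' Fits the multivariate GLM at every in-mask voxel, tests the contrast
#' `C B L = 0` through Wilks' lambda with its (exact or Rao-approximate) F
#' transform, and (for rank-1 hypotheses) stores the first canonical weight
#' vector at every voxel so that modality contributions can be queried at
#' any location, e.g. at an ROI's peak voxel.
#'
#' @param ds standardized `multimodal_dataset`.
#' @param design n x k design matrix.
#' @param contrast an [mglm_contrast()]; default [age_contrast()].
#' @param mask binary 3D array (default: the dataset's analysis mask).
#' @param keep_canonical store per-voxel first canonical weights (rank-1
#'   hypotheses only).
#' @return a `stat_map` with `stat_kind = "wilks_F"`, plus `lambda` (3D),
#'   and `canonical` (x, y, z, p array of signed unit-norm weights) when
#'   requested.
#' @export
mglm_map <- function(ds, design, contrast = NULL, mask = NULL,
                     keep_canonical = TRUE) {
  stopifnot(inherits(ds, "multimodal_dataset"))
  if (!isTRUE(ds$standardized))
    stop_cfg("dataset must be standardized first (standardize_dataset)")
  mask <- (mask %||% ds$analysis_mask)
  if (is.null(mask)) stop_cfg("no mask supplied and dataset has no analysis_mask")
  if (sum(mask != 0) == 0) stop_cfg("empty mask")
  X <- unclass(design)
  p <- length(ds$modalities)
  contrast <- contrast %||% age_contrast(ncol(X), p)
  Ylist <- lapply(ds$modalities, function(m) flatten_stack(ds$stacks[[m]], mask))
  keep <- keep_canonical && contrast$c == 1L
  eng <- wilks_map_engine(Ylist, X, contrast, keep_parts = keep)
  can <- NULL
  if (keep) {
    wts <- first_canonical_store(eng, contrast$l)
    can <- array(NA_real_, c(dim(mask), contrast$l))
    vox <- which(mask != 0)
    for (j in seq_len(contrast$l)) {
      sl <- array(NA_real_, dim(mask))
      sl[vox] <- wts[, j]
      can[, , , j] <- sl
    }
  }
  stat_map(stat = unflatten(eng$F, mask),
           p_uncorrected = unflatten(eng$p, mask),
           mask = (mask != 0) * 1L,
           df = c(eng$df1, eng$df2),
           stat_kind = "wilks_F",
           lambda = unflatten(eng$lambda, mask),
           canonical = can,
           n = eng$n, k = eng$k, l = eng$l, c = eng$c,
           exact = eng$exact,
           modalities = ds$modalities)
}

#' Query the stored first canonical weight vector at one voxel
#'
#' @param map a `stat_map` from [mglm_map()] with a canonical store.
#' @param voxel length-3 integer voxel coordinate.
#' @param absolute return absolute weights (the interpretable magnitude for
#'   F-derived vectors).
#' @return named numeric vector of length p (unit Euclidean norm).
#' @export
canonical_at <- function(map, voxel, absolute = TRUE) {
  if (is.null(map$canonical))
    stop_cfg("map carries no canonical store (keep_canonical = FALSE?)")
  w <- map$canonical[voxel[1], voxel[2], voxel[3], ]
  if (anyNA(w)) stop_cfg("voxel (", paste(voxel, collapse = ", "),
                         ") is outside the analysis mask")
  names(w) <- map$modalities
  if (absolute) abs(w) else w
}
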