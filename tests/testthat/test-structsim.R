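# Pre-alignment, ICP registration and the 6D D2 score.

test_that("prealign recovers rigid motions of the HLA frame", {
  ref <- make_synthetic_phla("EVDPIGHLY", seed = 1)
  # identical complexes -> identity
  tf0 <- prealign(ref, ref)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-9)
  # rigidly moved copy -> recovered inverse, post-alignment RMSD ~ 0
  applied <- rigid_transform(rotation_about_axis(c(1, 0, 2), 0.6), c(3, -2, 8))
  moved <- pepsim:::apply_transform_complex(ref, applied)
  rec <- prealign(ref, moved)
  back <- pepsim:::apply_transform_complex(moved, rec)
  rmsd <- sqrt(mean((as.matrix(back$atoms[, c("x", "y", "z")]) -
                       as.matrix(ref$atoms[, c("x", "y", "z")]))^2))
  expect_lt(rmsd, 1e-6)
  # noisy copy: alignment cannot be worse than no alignment
  noisy <- moved
  set.seed(4)
  noisy$atoms$x <- noisy$atoms$x + rnorm(nrow(noisy$atoms), 0, 0.1)
  noisy$atoms$y <- noisy$atoms$y + rnorm(nrow(noisy$atoms), 0, 0.1)
  noisy$atoms$z <- noisy$atoms$z + rnorm(nrow(noisy$atoms), 0, 0.1)
  rec2 <- prealign(ref, noisy)
  aligned <- pepsim:::apply_transform_complex(noisy, rec2)
  rmsd_after <- sqrt(mean((as.matrix(aligned$atoms[, c("x", "y", "z")]) -
                             as.matrix(ref$atoms[, c("x", "y", "z")]))^2))
  rmsd_before <- sqrt(mean((as.matrix(noisy$atoms[, c("x", "y", "z")]) -
                              as.matrix(ref$atoms[, c("x", "y", "z")]))^2))
  expect_lte(rmsd_after, rmsd_before)
})

test_that("prealign refuses complexes with too little HLA overlap", {
  ref <- make_synthetic_phla("EVDPIGHLY", seed = 1)
  chopped <- ref
  keep <- chopped$atoms$chain_id != "A" | chopped$atoms$residue_index <= 40
  chopped$atoms <- chopped$atoms[keep, ]
  expect_error(prealign(ref, chopped), "insufficient HLA overlap")
})

test_that("icp on identical clouds is an exact identity fit", {
  pair <- make_synthetic_cloud_pair(80, 0, c(0, 0, 0), 0, seed = 3)
  icp <- icp_align(pair$source, pair$target)
  expect_true(icp$converged)
  expect_equal(icp$final_D, 0, tolerance = 1e-12)
  expect_equal(nrow(icp$correspondences), 80)
  expect_equal(d2_score(pair$source, pair$target, icp), 0,
               tolerance = 1e-12)
})

test_that("icp recovers known transforms and respects Kabsch optimality", {
  set.seed(42)
  for (i in 1:50) {
    ang <- runif(1, 0, 30)
    tr <- runif(3, -2 / sqrt(3), 2 / sqrt(3))
    pair <- make_synthetic_cloud_pair(100, ang, tr, 0, seed = i)
    icp <- icp_align(pair$source, pair$target)
    rot_err <- rotation_angle(t(pair$transform$rotation) %*%
                                icp$transform$rotation)
    tr_err <- sqrt(sum((icp$transform$translation -
                          pair$transform$translation)^2))
    expect_lt(rot_err, 1e-3)
    expect_lt(tr_err, 1e-2)
    expect_lte(icp$iterations, 30)
    # the Kabsch step never increases D over the fixed correspondence set
    expect_true(all(icp$D_trace <= icp$D_pre_trace + 1e-9))
    # paired distances respect the epsilon cutoff under the final pose
    moved <- apply_transform(icp$transform, pair$source$points)
    pd <- sqrt(rowSums((moved[icp$correspondences[, 1], , drop = FALSE] -
                          pair$target$points[icp$correspondences[, 2], ,
                                             drop = FALSE])^2))
    expect_lte(max(pd), 2)
  }
})

test_that("well-separated clouds are flagged non-overlapping, not errors", {
  pair <- make_synthetic_cloud_pair(50, 0, c(0, 0, 0), 0, seed = 5)
  far <- feature_cloud(pair$source$points + 100, pair$source$features, "far")
  icp <- icp_align(pair$source, far)
  expect_true(icp$non_overlapping)
  expect_equal(icp$final_D, Inf)
  expect_equal(nrow(icp$correspondences), 0)
  expect_equal(d2_score(pair$source, far, icp), Inf)
})

test_that("d2 reproduces analytic single-pair and feature-offset cases", {
  cfg <- icp_config(feature_scaling = "none")
  # two single-point clouds at 3D offset d: D2 = d^2
  d <- 1.3
  c1 <- feature_cloud(rbind(c(0, 0, 0)), rbind(c(0.5, -0.2, 1.0)), "a")
  c2 <- feature_cloud(rbind(c(d, 0, 0)), rbind(c(0.5, -0.2, 1.0)), "b")
  manual_icp <- structure(list(transform = rigid_transform(),
                               correspondences = cbind(source = 1L,
                                                       target = 1L),
                               final_D = d^2, D_trace = d^2,
                               D_pre_trace = d^2, iterations = 1,
                               converged = TRUE, non_overlapping = FALSE),
                          class = "icp_result")
  expect_equal(d2_score(c1, c2, manual_icp, cfg), d^2, tolerance = 1e-9)
  # identical geometry, one feature column offset by delta: D2 = delta^2
  delta <- 0.7
  pair <- make_synthetic_cloud_pair(60, 0, c(0, 0, 0), 0, seed = 8)
  shifted <- feature_cloud(pair$source$points,
                           pair$source$features +
                             cbind(rep(delta, 60), 0, 0),
                           "shifted")
  icp <- icp_align(pair$source, shifted, cfg)
  expect_equal(d2_score(pair$source, shifted, icp, cfg), delta^2,
               tolerance = 1e-9)
})

test_that("d2 is invariant under a common rigid transform of both clouds", {
  pair <- make_synthetic_cloud_pair(70, 12, c(1, 1, 0), 0, seed = 10)
  cfg <- icp_config(feature_scaling = "none")
  icp1 <- icp_align(pair$source, pair$target, cfg)
  s1 <- d2_score(pair$source, pair$target, icp1, cfg)
  tf <- rigid_transform(rotation_about_axis(c(2, -1, 1), 0.9), c(4, 4, -6))
  src2 <- pepsim:::transform_cloud(pair$source, tf)
  tgt2 <- pepsim:::transform_cloud(pair$target, tf)
  icp2 <- icp_align(src2, tgt2, cfg)
  expect_equal(d2_score(src2, tgt2, icp2, cfg), s1, tolerance = 1e-6)
})

test_that("alignment is feature-blind: permuting features moves D2 only", {
  pair <- make_synthetic_cloud_pair(60, 15, c(0.5, -0.5, 1), 0.3, seed = 12)
  icp1 <- icp_align(pair$source, pair$target)
  permuted <- pair$source
  permuted$features <- pair$source$features[, c(3, 1, 2)]
  icp2 <- icp_align(permuted, pair$target)
  expect_equal(icp1$transform$rotation, icp2$transform$rotation,
               tolerance = 1e-12)
  expect_equal(icp1$transform$translation, icp2$transform$translation,
               tolerance = 1e-12)
})

test_that("the structural matrix is a symmetrized cross-check of d2", {
  set.seed(20)
  clouds <- lapply(1:3, function(i) {
    pair <- make_synthetic_cloud_pair(50, runif(1, 0, 10),
                                      runif(3, -1, 1), 0.2,
                                      seed = 100 + i)
    feature_cloud(pair$target$points, pair$target$features,
                  paste0("c", i))
  })
  cfg <- icp_config()
  m <- structural_matrix(clouds, cfg)
  expect_equal(attr(m, "orientation"), "distance")
  expect_true(isSymmetric(unclass(m)))
  expect_equal(unname(diag(unclass(m))), rep(0, 3))
  stats_ref <- pepsim:::feature_stats(lapply(clouds, function(x) x$features))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      dij <- d2_score(clouds[[i]], clouds[[j]],
                      icp_align(clouds[[i]], clouds[[j]], cfg), cfg,
                      stats_ref)
      dji <- d2_score(clouds[[j]], clouds[[i]],
                      icp_align(clouds[[j]], clouds[[i]], cfg), cfg,
                      stats_ref)
      expect_equal(unclass(m)[i, j], mean(c(dij, dji)), tolerance = 1e-9)
    }
  }
  # n copies of one cloud -> zero matrix
  copies <- list(clouds[[1]], clouds[[1]], clouds[[1]])
  names(copies) <- c("x", "y", "z")
  mz <- structural_matrix(copies, cfg)
  expect_true(all(abs(unclass(mz)) < 1e-12))
})

test_that("disjoint clouds get the sentinel replacement", {
  base <- make_synthetic_cloud_pair(40, 0, c(0, 0, 0), 0, seed = 30)$source
  shifted1 <- feature_cloud(base$points + 100, base$features, "far1")
  shifted2 <- feature_cloud(base$points - 100, base$features, "far2")
  m <- structural_matrix(list(a = base, b = shifted1, c = shifted2))
  off <- unclass(m)[row(unclass(m)) != col(unclass(m))]
  expect_true(all(is.finite(off)))
  expect_true(all(off > 0))
  expect_error(
    structural_matrix(list(base,
                           feature_cloud(base$points[1:3, ],
                                         base$features[1:3, ], "tiny"))),
    "tiny")
})
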