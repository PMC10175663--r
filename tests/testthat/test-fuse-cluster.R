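# Fusion (z-normalization, sign-adjusted summation) and downstream
# evaluation: clustering, KNN, confusion metrics, ranking, NMDS.

test_that("znorm matches the hand-computed 2x2 case and its contract", {
  m <- pepsim_matrix(matrix(c(0, 2, 2, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b"))),
                     "hamming", "distance")
  z <- znorm(m)
  expect_equal(as.matrix(z), matrix(c(-1, 1, 1, -1), 2, 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))))
  # mean 0 / population sd 1 on random matrices
  for (seed in 1:5) {
    z <- znorm(random_fused_matrix(8, seed))
    v <- as.numeric(unclass(z))
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
    expect_true(isSymmetric(unclass(z)))
  }
  const <- pepsim_matrix(matrix(3, 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b"))),
                         "hamming", "distance")
  expect_error(znorm(const), "degenerate")
})

test_that("combine sums components element-wise with sign adjustment", {
  ids <- c("a", "b", "c")
  d1 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(ids, ids))
  s1 <- matrix(c(5, 4, 1, 4, 5, 2, 1, 2, 5), 3, 3,
               dimnames = list(ids, ids))
  md <- pepsim_matrix(d1, "hamming", "distance")
  ms <- pepsim_matrix(s1, "blosum62", "similarity")
  fused <- combine(list(hamming = md, blosum62 = ms))
  # similarity component is negated; weights default to 1
  expect_equal(as.matrix(fused), d1 - s1)
  expect_equal(attr(fused, "orientation"), "distance")
  # weighted version against hand arithmetic
  fused2 <- combine(list(hamming = md, blosum62 = ms),
                    weights = c(hamming = 2, blosum62 = 0.5))
  expect_equal(as.matrix(fused2), 2 * d1 - 0.5 * s1)
  # single distance component with weight 1 passes through unchanged
  expect_equal(as.matrix(combine(list(md))), d1)
  expect_error(combine(list(md, ms), weights = c(0, 0)), "zero")
  ms_wrong <- pepsim_matrix(s1[c(2, 1, 3), c(2, 1, 3)], "blosum62",
                            "similarity")
  expect_error(combine(list(md, ms_wrong)), "mismatched")
})

test_that("fused orientation is low-score-is-similar: duplicates rank first", {
  # peptide set with a near-duplicate pair; all four components enabled
  peps <- c("EVDPIGHLY", "EVDPIGHLF", "RKWQNNATC", "GGGGGGGGG", "MMWWFFYYV")
  mats <- sequence_matrices(peps)
  fused <- combine(lapply(mats, znorm))
  rk <- rank_targets(fused, "EVDPIGHLY")
  expect_equal(rk$peptide[1], "EVDPIGHLF")
  expect_true(all(diff(rk$score) >= 0))
})

test_that("2-cluster agglomerative clustering recovers separated groups", {
  # two tight groups with inter/intra margin >= 5
  set.seed(14)
  base <- c(rep(0, 6), rep(50, 6))
  pts <- base + runif(12, 0, 1)
  ids <- sprintf("p%02d", 1:12)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(ids, ids)
  fused <- pepsim_matrix(m, "fused", "distance")
  for (linkage in c("ward", "average")) {
    cl <- cluster_agglomerative(fused, linkage, n_clusters = 2)
    expect_equal(unname(cl$labels[1:6]), rep(cl$labels[[1]], 6))
    expect_equal(unname(cl$labels[7:12]), rep(cl$labels[[7]], 6))
    expect_false(cl$labels[[1]] == cl$labels[[7]])
    expect_match(cl$newick, "^\\(.*\\);$")
  }
})

test_that("average-linkage merge order matches a manual trace", {
  ids <- letters[1:4]
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["a", "b"] <- D["b", "a"] <- 1
  D["c", "d"] <- D["d", "c"] <- 2
  D["a", "c"] <- D["c", "a"] <- 5
  D["a", "d"] <- D["d", "a"] <- 6
  D["b", "c"] <- D["c", "b"] <- 7
  D["b", "d"] <- D["d", "b"] <- 8
  cl <- cluster_agglomerative(pepsim_matrix(D, "fused", "distance"),
                              "average", n_clusters = 2)
  # merges: {a,b} at 1, {c,d} at 2, then the two pairs at (5+6+7+8)/4
  expect_equal(cl$hclust$height, c(1, 2, 6.5))
  expect_equal(unname(cl$labels), c(1, 1, 2, 2))
})

test_that("ties in a constant off-diagonal matrix cluster deterministically", {
  ids <- letters[1:4]
  m <- matrix(1, 4, 4, dimnames = list(ids, ids))
  diag(m) <- 0
  fused <- pepsim_matrix(m, "fused", "distance")
  cl1 <- cluster_agglomerative(fused, "average", n_clusters = 2)
  cl2 <- cluster_agglomerative(fused, "average", n_clusters = 2)
  expect_identical(cl1$labels, cl2$labels)
  expect_equal(sort(unique(unname(cl1$labels))), c(1, 2))
})

test_that("knn leave-one-out agrees with brute-force enumeration", {
  for (seed in 1:4) {
    n <- c(8, 12, 20, 30)[seed]
    fused <- random_fused_matrix(n, seed + 50)
    set.seed(seed)
    labels <- stats::setNames(sample(c(TRUE, FALSE), n, TRUE,
                                     prob = c(0.4, 0.6)),
                              rownames(fused))
    while (sum(labels) < 2 || sum(!labels) < 2) {
      labels <- stats::setNames(sample(c(TRUE, FALSE), n, TRUE),
                                rownames(fused))
    }
    res <- knn_loo_classify(fused, labels, k_values = 1:7)
    m <- unclass(fused)
    for (k in 1:7) {
      pred <- brute_knn_loo(m, labels, k)
      tp <- sum(pred & labels)
      fn <- sum(!pred & labels)
      tn <- sum(!pred & !labels)
      fp <- sum(pred & !labels)
      row <- res[res$k == k, ]
      expect_equal(row$sensitivity, tp / (tp + fn))
      expect_equal(row$specificity, tn / (tn + fp))
    }
  }
})

test_that("knn handles forced misclassification and separated groups", {
  # two well-separated groups, k = 1: perfect sensitivity and specificity
  set.seed(9)
  pts <- c(rnorm(6, 0, 0.3), rnorm(6, 30, 0.3))
  ids <- sprintf("p%02d", 1:12)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(ids, ids)
  fused <- pepsim_matrix(m, "fused", "distance")
  labels <- stats::setNames(rep(c(TRUE, FALSE), each = 6), ids)
  res <- knn_loo_classify(fused, labels, k_values = 1)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)
  # a lone positive among negatives is always misclassified at k = 1
  labels2 <- stats::setNames(c(TRUE, rep(FALSE, 11)), ids)
  res2 <- knn_loo_classify(fused, labels2, k_values = 1)
  expect_equal(res2$sensitivity, 0)
  expect_error(knn_loo_classify(fused, labels[1:4]), "missing")
  expect_error(knn_loo_classify(fused, labels, k_values = 12), "max k")
})

test_that("confusion metrics satisfy their definitional identities", {
  set.seed(33)
  ids <- sprintf("p%02d", 1:40)
  for (rep in 1:20) {
    labels <- stats::setNames(sample(c(TRUE, FALSE), 40, TRUE), ids)
    if (all(labels) || !any(labels)) next
    predicted <- sample(ids, sample(0:40, 1))
    cm <- confusion_metrics(predicted, labels)
    expect_equal(cm$tp + cm$fn, sum(labels))
    expect_equal(cm$tn + cm$fp, sum(!labels))
    expect_gte(cm$sensitivity, 0); expect_lte(cm$sensitivity, 100)
    expect_gte(cm$specificity, 0); expect_lte(cm$specificity, 100)
    expect_equal(cm$sensitivity, round(100 * cm$tp / (cm$tp + cm$fn), 2))
    # the reported assignment maximises TP + TN over the two options
    c1 <- pepsim:::confusion_counts(predicted, labels)
    c2 <- pepsim:::confusion_counts(setdiff(ids, predicted), labels)
    expect_equal(cm$tp + cm$tn, max(c1$tp + c1$tn, c2$tp + c2$tn))
  }
  labels <- stats::setNames(rep(TRUE, 4), ids[1:4])
  expect_error(confusion_metrics(ids[1:2], labels), "positive")
})

test_that("perfect separation scores 100/100", {
  labels <- stats::setNames(rep(c(TRUE, FALSE), c(5, 7)),
                            sprintf("p%02d", 1:12))
  cm <- confusion_metrics(sprintf("p%02d", 1:5), labels)
  expect_equal(cm$sensitivity, 100)
  expect_equal(cm$specificity, 100)
  expect_equal(cm$fn + cm$fp, 0)
})

test_that("target ranking orders ascending with lexicographic ties", {
  ids <- c("tgt", "bb", "aa", "cc")
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m["tgt", "bb"] <- m["bb", "tgt"] <- 1
  m["tgt", "aa"] <- m["aa", "tgt"] <- 1
  m["tgt", "cc"] <- m["cc", "tgt"] <- 0.5
  m["aa", "bb"] <- m["bb", "aa"] <- 2
  m["aa", "cc"] <- m["cc", "aa"] <- 2
  m["bb", "cc"] <- m["cc", "bb"] <- 2
  fused <- pepsim_matrix(m, "fused", "distance")
  rk <- rank_targets(fused, "tgt")
  expect_equal(rk$peptide, c("cc", "aa", "bb"))  # tie aa/bb -> id order
  expect_equal(rk$rank, 1:3)
  expect_false("tgt" %in% rk$peptide)
  # n = 2: the single other peptide is rank 1
  two <- pepsim_matrix(matrix(c(0, 3, 3, 0), 2, 2,
                              dimnames = list(c("x", "y"), c("x", "y"))),
                       "fused", "distance")
  expect_equal(rank_targets(two, "x")$peptide, "y")
  expect_error(rank_targets(fused, "nope"), "available ids")
})

test_that("nmds embeds equidistant points symmetrically, duplicates together", {
  ids <- c("a", "b", "c")
  m <- matrix(3, 3, 3, dimnames = list(ids, ids))
  diag(m) <- 0
  e <- nmds_embed(pepsim_matrix(m, "fused", "distance"), seed = 4)
  d <- as.numeric(dist(as.matrix(e[, c("x", "y")])))
  expect_lt(max(d) - min(d), 1e-3)
  # embedding is deterministic for a fixed seed
  e2 <- nmds_embed(pepsim_matrix(m, "fused", "distance"), seed = 4)
  expect_identical(e$x, e2$x)
  # duplicate peptides (zero distance) land on the same spot
  ids4 <- letters[1:4]
  m4 <- matrix(c(0, 0, 4, 4, 0, 0, 4, 4, 4, 4, 0, 3, 4, 4, 3, 0), 4, 4,
               dimnames = list(ids4, ids4))
  e4 <- nmds_embed(pepsim_matrix(m4, "fused", "distance"), seed = 4)
  expect_lt(sqrt(sum((e4[1, c("x", "y")] - e4[2, c("x", "y")])^2)), 1e-9)
  expect_error(nmds_embed(pepsim_matrix(m[1:2, 1:2], "fused", "distance",
                                        ids = c("a", "b"))),
               ">= 3")
})
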