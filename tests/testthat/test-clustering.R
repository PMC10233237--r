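# Affinity propagation subtyping: distances, similarities, preference,
# message passing vs exhaustive oracles, agglomeration, silhouette, metric
# selection.

test_that("pairwise distances follow their definitions", {
  pts <- rbind(c(0, 0), c(3, 4))
  expect_equal(pairwise_distance(pts, "euclidean")[1, 2], 5)
  expect_equal(pairwise_distance(rbind(c(0, 0), c(1, 1)), "manhattan")[1, 2], 2)

  prof <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  Dc <- pairwise_distance(prof, "correlation")
  expect_equal(Dc[1, 2], 0)
  expect_equal(Dc[1, 3], 2)
  expect_true(all(diag(Dc) == 0))

  expect_error(pairwise_distance(cbind(c(1, 2)), "correlation"), "at least 2")
  expect_error(pairwise_distance(rbind(c(1, 1), c(1, 2)), "correlation"),
               "constant")
})

test_that("similarities are negative squared distances, order-reversing", {
  D <- matrix(c(0, 2, 2, 0), 2)
  S <- similarity_from_distance(D)
  expect_equal(S[1, 2], -4)
  expect_true(is.na(S[1, 1]))
  withr::local_seed(1)
  D2 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  S2 <- similarity_from_distance(D2)
  off <- upper.tri(D2)
  expect_equal(order(S2[off]), rev(order(D2[off])))
})

test_that("preference quantile matches the interpolation oracle", {
  S <- matrix(-4, 4, 4); diag(S) <- NA
  expect_equal(preference_from_quantile(S, 0.1), -4)
  expect_equal(preference_from_quantile(S, 0.9), -4)

  S2 <- matrix(0, 2, 2)
  S2[1, 2] <- -1; S2[2, 1] <- -2
  # [DERIVED] off-diagonal set {-1,-2}: interpolated median is -1.5
  expect_equal(preference_from_quantile(S2, 0.5), -1.5)
  # the spec's example set {-1,-2,-3,-4} -> interpolated median -2.5
  expect_equal(unname(quantile(c(-1, -2, -3, -4), 0.5)), -2.5)
  expect_error(preference_from_quantile(S2, 0), "in \\(0, 1\\)")
  expect_error(preference_from_quantile(S2, 1.2), "in \\(0, 1\\)")
})

test_that("AP on coincident points yields one cluster with net = preference", {
  pts <- rbind(c(1, 1), c(1, 1))
  S <- similarity_from_distance(pairwise_distance(pts, "euclidean"))
  res <- affinity_propagation(S, preference = -2, seed = 1)
  expect_equal(res$n_clusters, 1L)
  expect_equal(res$net_similarity, -2)
  expect_equal(res$labels, c(1L, 1L))
  expect_equal(res$labels[res$exemplars], 1L) # exemplar labels itself
})

test_that("AP separates two tight pairs and matches exhaustive search", {
  pts <- cbind(c(0, 0.1, 10, 10.1), 0)
  D <- pairwise_distance(pts, "euclidean")
  S <- similarity_from_distance(D)
  pref <- preference_from_quantile(S, 0.1)
  res <- affinity_propagation(S, preference = pref, seed = 1)
  expect_equal(res$n_clusters, 2L)
  expect_equal(res$labels, c(1L, 1L, 2L, 2L))
  Sp <- S; diag(Sp) <- pref
  opt <- ap_exhaustive_optimum(Sp)
  expect_setequal(res$exemplars, opt$exemplars)
  expect_equal(res$net_similarity, opt$net)
})

test_that("AP recovers planted well-separated clusters with ARI 1", {
  pl <- planted_score_clusters(seed = 77, sizes = c(21L, 19L, 7L, 5L))
  sel <- select_metric(pl$scores, metrics = "euclidean", seed = 1)
  expect_equal(sel$best$n_clusters, 4L)
  expect_equal(adjusted_rand_index(sel$best$labels, pl$labels), 1.0)
})

test_that("AP validates input and is deterministic under a seed", {
  S <- similarity_from_distance(as.matrix(dist(matrix(rnorm(20), 10, 2))))
  expect_error(affinity_propagation(S, preference = -1, damping = 0.3), "damping")
  expect_error(affinity_propagation(S), "preference")
  r1 <- affinity_propagation(S, preference = -1, seed = 9)
  r2 <- affinity_propagation(S, preference = -1, seed = 9)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$n_iterations, r2$n_iterations)
})

test_that("clustering is invariant under sign flips of score components", {
  pl <- planted_score_clusters(seed = 13, sizes = c(8L, 7L, 5L))
  flipped <- pl$scores
  flipped[, 2] <- -flipped[, 2]; flipped[, 5] <- -flipped[, 5]
  for (metric in c("euclidean", "manhattan", "correlation")) {
    a <- select_metric(pl$scores, metrics = metric, seed = 1)$best$labels
    b <- select_metric(flipped, metrics = metric, seed = 1)$best$labels
    expect_equal(adjusted_rand_index(a, b), 1.0)
  }
})

test_that("exemplar agglomeration matches the exhaustive best-pair oracle", {
  withr::local_seed(23)
  pl <- planted_score_clusters(seed = 23, sizes = c(6L, 5L, 4L, 3L), k = 3L)
  Z <- scale(pl$scores)
  D <- pairwise_distance(Z, "euclidean")
  S <- similarity_from_distance(D)
  pref <- preference_from_quantile(S, 0.1)
  res <- affinity_propagation(S, preference = pref, seed = 1)
  expect_gte(res$n_clusters, 2L)
  Sp <- S; diag(Sp) <- pref
  tree <- agglomerate_exemplars(Sp, res)
  expect_equal(nrow(tree), res$n_clusters - 1L)
  # joint similarity is monotone non-increasing along the merge sequence
  expect_true(all(diff(tree$joint_similarity) <= 1e-12))

  # first merge agrees with the exhaustive oracle
  members <- split(seq_along(res$labels), res$labels)
  oracle <- best_merge_oracle(Sp, members)
  expect_equal(tree$joint_similarity[1], oracle$val)
  expect_setequal(abs(c(tree$a[1], tree$b[1])), c(oracle$i, oracle$j))
})

test_that("two clusters agglomerate in exactly one merge, order permutation-proof", {
  pts <- cbind(c(0, 0.2, 5, 5.2), 0)
  S <- similarity_from_distance(pairwise_distance(pts, "euclidean"))
  pref <- preference_from_quantile(S, 0.1)
  res <- affinity_propagation(S, preference = pref, seed = 1)
  expect_equal(res$n_clusters, 2L)
  Sp <- S; diag(Sp) <- pref
  tree <- agglomerate_exemplars(Sp, res)
  expect_equal(nrow(tree), 1L)
  expect_equal(tree$size, 4L)

  # relabeling clusters does not change which subject sets merge when
  res2 <- res
  res2$labels <- 3L - res$labels # swap labels 1 <-> 2
  res2$exemplars <- rev(res$exemplars)
  tree2 <- agglomerate_exemplars(Sp, res2)
  expect_equal(tree2$joint_similarity, tree$joint_similarity)
})

test_that("silhouette matches hand computation and brute force", {
  # [DERIVED] line clusters {0,1} and {10,11}: a(0)=1, b(0)=10.5
  D <- as.matrix(dist(c(0, 1, 10, 11)))
  sil <- silhouette_score(D, c(1, 1, 2, 2))
  expect_equal(sil$values[1], (10.5 - 1) / 10.5, tolerance = 1e-12)
  expect_true(all(sil$values >= -1 & sil$values <= 1))

  # coincident points in 2 clusters: 0 with a warning
  D0 <- matrix(0, 4, 4)
  expect_warning(s0 <- silhouette_score(D0, c(1, 1, 2, 2)), "coincident")
  expect_equal(s0$mean, 0)

  expect_error(silhouette_score(D, rep(1, 4)), "single cluster")

  # brute-force double-loop oracle on random instances
  withr::local_seed(3)
  for (i in 1:15) {
    n <- sample(5:30, 1)
    Dr <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
    labs <- sample(1:3, n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    expect_equal(silhouette_score(Dr, labs)$values, silhouette_oracle(Dr, labs),
                 tolerance = 1e-14)
  }
})

test_that("metric selection reports all metrics and picks by silhouette", {
  pl <- planted_score_clusters(seed = 5, sizes = c(10L, 9L, 8L))
  sel <- select_metric(pl$scores, seed = 1)
  expect_equal(length(sel$silhouettes), 3L)
  expect_named(sel$silhouettes, c("euclidean", "manhattan", "correlation"))
  # the winner is the argmax of the reported silhouettes
  expect_equal(unname(sel$silhouettes[sel$best_metric]),
               max(sel$silhouettes, na.rm = TRUE))
  expect_equal(sel$best_metric, sel$best$metric)
  # on spherical well-separated clusters every metric recovers the partition
  for (m in names(sel$results)) {
    expect_equal(adjusted_rand_index(sel$results[[m]]$labels, pl$labels), 1.0)
  }
  expect_error(select_metric(pl$scores, metrics = character(0)), "empty")
})

test_that("shape-only clusters at equal magnitude select the correlation metric", {
  withr::local_seed(41)
  shapes <- rbind(c(1, 1, -1, -1, 1, -1), c(-1, 1, 1, -1, -1, 1))
  shapes <- shapes / sqrt(rowSums(shapes^2))
  n_per <- c(12L, 12L)
  labels <- rep(1:2, n_per)
  # each subject: its cluster's shape at (nearly) equal magnitude
  mags <- 1.5 + runif(sum(n_per), -0.05, 0.05)
  scores <- shapes[labels, ] * mags + matrix(rnorm(24 * 6, sd = 0.04), 24, 6)
  sel <- select_metric(scores, seed = 1)
  expect_equal(sel$best_metric, "correlation")
  expect_equal(adjusted_rand_index(sel$best$labels, labels), 1.0)
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1.0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               adjusted_rand_index(c(1, 2, 1, 2), c(1, 1, 2, 2)))
  withr::local_seed(55)
  a <- sample(1:3, 60, replace = TRUE)
  b <- sample(1:3, 60, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.2) # independent labelings ~ 0
})
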