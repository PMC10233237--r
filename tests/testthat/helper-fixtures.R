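# Shared fixtures and independent oracles. Fixtures are generated in code at
# test time; expensive ones are cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small template for fast unit tests (~1200 masked voxels)
small_template <- function() {
  cached("small_template", function() make_template(c(16L, 18L, 16L)))
}

# small cohort: 4 subtypes on a small grid, 4 planted factors
small_cohort <- function() {
  cached("small_cohort", function() {
    simulate_cohort(n_per_cluster = c(8L, 7L, 3L, 3L), n_controls = 10L,
                    shape = c(16L, 18L, 16L), k_factors = 4L, seed = 42L)
  })
}

# the 8 balanced latent-group loading design used for factor-recovery checks:
# Hadamard sign patterns (the 6 non-constant columns of H8), descending
# amplitudes matching the default second-moment schedule
hadamard_groups <- function(k = 6L) {
  stopifnot(k <= 6L)
  H <- matrix(c(1, -1, 1, -1, 1, -1, 1, -1,
                1, 1, -1, -1, 1, 1, -1, -1,
                1, -1, -1, 1, 1, -1, -1, 1,
                1, 1, 1, 1, -1, -1, -1, -1,
                1, -1, 1, -1, -1, 1, -1, 1,
                1, 1, -1, -1, -1, -1, 1, 1), 8L, 6L)
  m2 <- c(710, 417, 245, 144, 85, 50)[seq_len(k)]
  list(centroids = H[, seq_len(k), drop = FALSE] %*% diag(sqrt(m2 - 9), k),
       sizes = c(7L, 7L, 7L, 7L, 6L, 6L, 6L, 6L),
       loading_sd = 3, m2 = m2)
}

# full-size recovery cohort (criterion 2 world); built once
recovery_cohort <- function() {
  cached("recovery_cohort", function() {
    tmpl <- make_template()
    fac <- make_factors(tmpl$brain, 6L, 2.5, seed = 42L)
    hg <- hadamard_groups()
    pats <- simulate_patients(fac, tmpl$brain, hg$centroids,
                              n_per_cluster = hg$sizes,
                              loading_sd = hg$loading_sd, noise_sd = 0.12,
                              seed = 43L)
    list(template = tmpl, factors = fac, patients = pats)
  })
}

# matched absolute spatial correlation between estimated and true factors:
# each true factor matched to its best-correlated estimate
matched_abs_correlation <- function(estimated, truth) {
  C <- abs(stats::cor(t(estimated), t(truth)))
  vapply(seq_len(ncol(C)), function(j) max(C[, j]), numeric(1))
}

# --- independent oracles -----------------------------------------------------

# silhouette by the definition, double loop, no vectorization
silhouette_oracle <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    same <- which(labels == own & seq_len(n) != i)
    if (length(same) == 0L) { s[i] <- 0; next }
    a <- 0
    for (j in same) a <- a + D[i, j]
    a <- a / length(same)
    b <- Inf
    for (l in setdiff(unique(labels), own)) {
      m <- which(labels == l)
      bl <- 0
      for (j in m) bl <- bl + D[i, j]
      bl <- bl / length(m)
      if (bl < b) b <- bl
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# exact exemplar-set optimum by exhaustive enumeration (n <= ~12)
ap_exhaustive_optimum <- function(S) {
  n <- nrow(S)
  best <- list(net = -Inf, exemplars = integer(0))
  for (code in seq_len(2^n - 1L)) {
    E <- which(bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    net <- sum(diag(S)[E])
    for (i in setdiff(seq_len(n), E)) {
      net <- net + max(S[i, E])
    }
    if (net > best$net) best <- list(net = net, exemplars = E)
  }
  best
}

# net similarity of a given partition with optimal exemplar per cluster
partition_net_similarity <- function(S, labels) {
  tot <- 0
  for (cl in unique(labels)) {
    m <- which(labels == cl)
    best <- -Inf
    for (e in m) {
      v <- sum(S[setdiff(m, e), e]) + S[e, e]
      if (v > best) best <- v
    }
    tot <- tot + best
  }
  tot
}

# best merge pair by exhaustive evaluation of the joint-cluster criterion
best_merge_oracle <- function(S, members_list) {
  joint <- function(m) {
    best <- -Inf
    for (e in m) {
      others <- setdiff(m, e)
      v <- if (length(others) == 0L) S[e, e] else mean(S[others, e])
      if (v > best) best <- v
    }
    best
  }
  best <- list(val = -Inf, i = NA, j = NA)
  for (i in seq_along(members_list)) {
    for (j in seq_along(members_list)) {
      if (j <= i) next
      v <- joint(c(members_list[[i]], members_list[[j]]))
      if (v > best$val) best <- list(val = v, i = i, j = j)
    }
  }
  best
}

# 6-D score-space world of acceptance criterion 5: four clusters of sizes
# 21/19/7/5, centroid separation >= 8x the within-cluster sd
planted_score_clusters <- function(seed, sizes = c(21L, 19L, 7L, 5L),
                                   within_sd = 0.25, k = 6L) {
  withr::local_seed(seed)
  centroids <- matrix(stats::rnorm(length(sizes) * k), length(sizes), k)
  # scale so the minimum pairwise centroid distance comfortably exceeds 8x
  # the within-cluster sd
  dmin <- min(stats::dist(centroids))
  centroids <- centroids * (8 * within_sd * sqrt(2 * k) / dmin)
  labels <- rep(seq_along(sizes), times = sizes)
  scores <- centroids[labels, ] +
    matrix(stats::rnorm(sum(sizes) * k, sd = within_sd), sum(sizes), k)
  list(scores = scores, labels = labels, centroids = centroids)
}
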