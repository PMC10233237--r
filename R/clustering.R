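# Data-driven subtyping of subjects from their factor scores:
# pairwise distances -> negative-squared-distance similarities -> affinity
# propagation (responsibility/availability message passing) -> exemplar
# agglomeration into a merge tree, with the distance metric selected by mean
# silhouette. The preference (similarity-matrix diagonal) is set to a low
# quantile of the off-diagonal similarities to discourage many small clusters.

#' Pairwise distances between subject score profiles
#'
#' @param scores subjects x K numeric matrix. Callers are expected to
#'   standardize score columns first (see [select_metric()], which does).
#' @param metric `"euclidean"`, `"manhattan"` or `"correlation"`
#'   (1 - Pearson r across components; requires K >= 2 and non-constant rows).
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(scores, metric = c("euclidean", "manhattan", "correlation")) {
  metric <- match.arg(metric)
  scores <- as.matrix(scores)
  if (ncol(scores) < 1L) stop("need at least one score column")
  if (metric == "correlation") {
    if (ncol(scores) < 2L) stop("correlation distance requires at least 2 components")
    rowsd <- apply(scores, 1L, stats::sd)
    if (any(rowsd == 0)) {
      stop("constant score profile(s) for correlation distance: row ",
           paste(which(rowsd == 0), collapse = ", "))
    }
    D <- 1 - stats::cor(t(scores))
    diag(D) <- 0
    D
  } else {
    as.matrix(stats::dist(scores, method = metric))
  }
}

#' Similarities as negative squared distances
#'
#' Off-diagonal similarity `s(i, k) = -d(i, k)^2`; the diagonal (the
#' preference) is left `NA` until set by [preference_from_quantile()] or by
#' [affinity_propagation()]'s `preference` argument.
#'
#' @param D symmetric distance matrix.
#' @return similarity matrix with `NA` diagonal.
#' @export
similarity_from_distance <- function(D) {
  D <- as.matrix(D)
  S <- -(D^2)
  diag(S) <- NA_real_
  S
}

#' Shared preference from a quantile of the similarities
#'
#' Sets the self-similarity (diagonal) to the `q`-quantile of the
#' off-diagonal similarities; lower preference yields fewer clusters. The
#' default `q = 0.1` (the 10% quantile) discourages solutions with many small
#' clusters.
#'
#' @param S similarity matrix (off-diagonal entries used).
#' @param q quantile in (0, 1).
#' @return the preference value (scalar).
#' @export
preference_from_quantile <- function(S, q = 0.1) {
  if (q <= 0 || q >= 1) stop("preference quantile must be in (0, 1)")
  off <- S[row(S) != col(S)]
  stats::quantile(off, probs = q, names = FALSE, type = 7)
}

#' Affinity propagation clustering
#'
#' Frey-Dueck message passing on a similarity matrix. Responsibilities and
#' availabilities are updated with damping until the exemplar set is stable
#' for `conv_iter` consecutive sweeps:
#' \deqn{r(i,k) \leftarrow s(i,k) - \max_{k' \ne k} [a(i,k') + s(i,k')]}
#' \deqn{a(i,k) \leftarrow \min(0,\; r(k,k) + \sum_{i' \notin \{i,k\}} \max(0, r(i',k))), i \ne k}
#' \deqn{a(k,k) \leftarrow \sum_{i' \ne k} \max(0, r(i',k))}
#' Exemplars are the points with `r(k,k) + a(k,k) > 0`; every other point is
#' assigned to its most similar exemplar. A tiny seeded noise
#' (1e-12 x similarity range) is added to break degeneracies; the seed is
#' recorded so runs are reproducible.
#'
#' @param S similarity matrix. Its diagonal is taken as the preference; if the
#'   diagonal is `NA`, `preference` must be supplied.
#' @param preference optional scalar preference overriding the diagonal.
#' @param damping damping factor in \[0.5, 1).
#' @param max_iter maximum number of sweeps.
#' @param conv_iter sweeps of exemplar-set stability required for convergence.
#' @param seed seed for the degeneracy-breaking noise.
#' @return an object of class `clustering_result`: `labels` (cluster index
#'   per subject), `exemplars` (subject indices, one per cluster; each
#'   exemplar labels itself), `n_iterations`, `converged`, `net_similarity`
#'   (sum of similarities of points to their exemplars plus exemplar
#'   preferences), `preference`, and `silhouette`/`merge_tree` slots filled by
#'   downstream helpers.
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 max_iter = 2000L, conv_iter = 200L, seed = 1L) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n < 2L) stop("need at least 2 points")
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  if (!is.null(preference)) {
    diag(S) <- preference
  }
  if (anyNA(diag(S))) stop("preference not set (NA diagonal and no 'preference')")
  S0 <- S # noiseless copy for reporting/assignment

  rng <- range(S[is.finite(S)])
  noise_scale <- 1e-12 * max(rng[2] - rng[1], .Machine$double.eps)
  withr::local_seed(seed)
  S <- S + matrix(stats::rnorm(n * n), n, n) * noise_scale

  R <- A <- matrix(0, n, n)
  idx <- seq_len(n)
  ex_prev <- integer(0)
  stable <- 0L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    i1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(idx, i1)]
    AS[cbind(idx, i1)] <- -Inf
    m2 <- AS[cbind(idx, max.col(AS, ties.method = "first"))]
    Rnew <- S - m1
    Rnew[cbind(idx, i1)] <- S[cbind(idx, i1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(R) + diag(A) > 0)
    if (length(ex) > 0L && identical(ex, ex_prev)) {
      stable <- stable + 1L
      if (stable >= conv_iter) { converged <- TRUE; break }
    } else {
      stable <- 0L
    }
    ex_prev <- ex
  }
  exemplars <- which(diag(R) + diag(A) > 0)
  if (length(exemplars) == 0L) {
    exemplars <- which.max(diag(R) + diag(A))
  }
  # final assignment on the noiseless similarities, followed by the standard
  # k-medoids refinement (best exemplar within each cluster, reassign, repeat
  # until stable) as in the reference implementation
  assign_to <- exemplars[max.col(S0[, exemplars, drop = FALSE], ties.method = "first")]
  assign_to[exemplars] <- exemplars
  for (polish in 1:50) {
    new_ex <- vapply(unique(assign_to), function(e) {
      m <- which(assign_to == e)
      within <- vapply(m, function(cand) {
        S0[cand, cand] + sum(S0[setdiff(m, cand), cand])
      }, numeric(1))
      m[which.max(within)]
    }, integer(1))
    new_ex <- sort(new_ex)
    new_assign <- new_ex[max.col(S0[, new_ex, drop = FALSE], ties.method = "first")]
    new_assign[new_ex] <- new_ex
    if (identical(new_assign, assign_to)) break
    assign_to <- new_assign
  }
  exemplars <- sort(unique(assign_to))
  labels <- match(assign_to, exemplars)
  net <- sum(S0[cbind(which(assign_to != idx), assign_to[assign_to != idx])]) +
    sum(diag(S0)[exemplars])

  structure(
    list(labels = labels, exemplars = exemplars, n_iterations = it,
         converged = converged, net_similarity = net,
         preference = diag(S0)[1], n_clusters = length(exemplars),
         merge_tree = NULL, silhouette = NULL, silhouette_mean = NA_real_,
         seed = as.integer(seed)),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("clustering_result:", x$n_clusters, "clusters, exemplars:",
      paste(x$exemplars, collapse = ", "),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (!is.na(x$silhouette_mean)) {
    cat("  mean silhouette:", sprintf("%.3f", x$silhouette_mean), "\n")
  }
  invisible(x)
}

#' Agglomerate affinity-propagation clusters into a merge tree
#'
#' Repeatedly merges the pair of clusters maximizing the joint-cluster
#' criterion — the average similarity of the merged members to the best joint
#' exemplar (self-similarity excluded) — until one cluster remains.
#'
#' @param S similarity matrix used for clustering (with preference diagonal).
#' @param result a `clustering_result` with at least 2 clusters.
#' @return a data frame with one row per merge: `a`, `b` (negative values are
#'   original cluster indices, positive values earlier merge steps, as in
#'   `hclust$merge`), `joint_similarity` and `size` of the merged cluster.
#' @export
agglomerate_exemplars <- function(S, result) {
  S <- as.matrix(S)
  k <- result$n_clusters
  if (k < 2L) stop("need at least 2 clusters to agglomerate")
  members <- split(seq_along(result$labels), result$labels)
  active <- lapply(seq_len(k), function(j) list(id = -j, members = members[[j]]))

  joint_sim <- function(m) {
    best <- -Inf
    for (e in m) {
      others <- setdiff(m, e)
      val <- if (length(others) == 0L) S[e, e] else mean(S[others, e])
      if (val > best) best <- val
    }
    best
  }

  merges <- data.frame(a = integer(0), b = integer(0),
                       joint_similarity = numeric(0), size = integer(0))
  step <- 0L
  while (length(active) > 1L) {
    best <- list(val = -Inf, i = NA, j = NA, key = Inf)
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (j <= i) next
        m <- c(active[[i]]$members, active[[j]]$members)
        v <- joint_sim(m)
        key <- min(m) # permutation-invariant tie-break on subject identity
        if (v > best$val || (v == best$val && key < best$key)) {
          best <- list(val = v, i = i, j = j, key = key)
        }
      }
    }
    step <- step + 1L
    merged <- list(id = step,
                   members = c(active[[best$i]]$members, active[[best$j]]$members))
    merges <- rbind(merges, data.frame(
      a = active[[best$i]]$id, b = active[[best$j]]$id,
      joint_similarity = best$val, size = length(merged$members)))
    active <- c(active[-c(best$i, best$j)], list(merged))
  }
  merges
}

#' Silhouette coefficients for a clustering
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean intra-cluster
#' distance (excluding self) and `b` the minimum over other clusters of the
#' mean distance to that cluster. Singletons score 0; if both `a` and `b` are
#' zero (coincident points) the value is 0 with a warning.
#'
#' @param D symmetric distance matrix.
#' @param labels cluster labels (>= 2 distinct, all clusters non-empty).
#' @return list with `values` (per subject) and `mean`.
#' @export
silhouette_score <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (length(labels) != n) stop("labels length does not match distance matrix")
  labs <- unique(labels)
  if (length(labs) < 2L) stop("silhouette undefined for a single cluster")
  s <- numeric(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(labs, labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    denom <- max(a, b)
    if (denom == 0) {
      s[i] <- 0
      warned <- TRUE
    } else {
      s[i] <- (b - a) / denom
    }
  }
  if (warned) warning("coincident points: silhouette set to 0 where a = b = 0")
  list(values = s, mean = mean(s))
}

#' Cluster subjects per candidate metric and select the best by silhouette
#'
#' Standardizes the score columns (z-score per component — the "scaled
#' eigenvalues"), then for each candidate metric builds distances,
#' negative-squared-distance similarities with a `q`-quantile preference,
#' runs affinity propagation, computes silhouettes on the distances, and
#' agglomerates exemplars into a merge tree. The metric with the highest mean
#' silhouette wins; ties go to the first metric in the documented order.
#'
#' @param scores subjects x K matrix of retained component scores.
#' @param metrics candidate metrics, tried in order.
#' @param q preference quantile (default 0.1).
#' @param damping,max_iter,conv_iter,seed passed to [affinity_propagation()].
#' @return list with `best_metric`, `best` (its `clustering_result`),
#'   `results` (per-metric results), `silhouettes` (named mean silhouettes,
#'   `NA` where fewer than 2 clusters emerged).
#' @export
select_metric <- function(scores,
                          metrics = c("euclidean", "manhattan", "correlation"),
                          q = 0.1, damping = 0.9, max_iter = 2000L,
                          conv_iter = 200L, seed = 1L) {
  if (length(metrics) < 1L) stop("empty metric list")
  Z <- zscore_cols(as.matrix(scores), what = "score column")
  results <- list()
  sils <- stats::setNames(rep(NA_real_, length(metrics)), metrics)
  for (m in metrics) {
    D <- pairwise_distance(Z, m)
    S <- similarity_from_distance(D)
    pref <- preference_from_quantile(S, q)
    res <- affinity_propagation(S, preference = pref, damping = damping,
                                max_iter = max_iter, conv_iter = conv_iter,
                                seed = seed)
    res$metric <- m
    if (res$n_clusters >= 2L) {
      sil <- silhouette_score(D, res$labels)
      res$silhouette <- sil$values
      res$silhouette_mean <- sil$mean
      diag(S) <- pref
      res$merge_tree <- agglomerate_exemplars(S, res)
      sils[m] <- sil$mean
    }
    results[[m]] <- res
  }
  if (all(is.na(sils))) {
    stop("no candidate metric produced at least 2 clusters")
  }
  best_metric <- metrics[which.max(replace(sils, is.na(sils), -Inf))]
  list(best_metric = best_metric, best = results[[best_metric]],
       results = results, silhouettes = sils)
}
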