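# Spectral decomposition of the subject-by-voxel matrix.
#
# The subject matrix X (n subjects x p voxels, p >> n) is submitted to an SVD
# X = U D V'. Rows of V' restricted to the mask are the latent spatial factors
# ("eigenbrains"); U D are the per-subject scores (the per-subject loading a
# clinician would call that subject's "eigenvalue" on a factor). For p >> n
# the decomposition is computed in the dual (subject-by-subject Gram) form.

.full_spectrum <- function(X) {
  n <- nrow(X); p <- ncol(X)
  if (p >= n) {
    ev <- eigen(tcrossprod(X), symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  }
  sqrt(pmax(ev, 0))
}

# component variances rescaled so the mean over the min(n-1, p) spectrum is 1
.latent_roots <- function(sv, n, p) {
  tot <- sum(sv^2)
  if (tot <= 0) stop("all singular values are zero")
  sv^2 * min(n - 1L, p) / tot
}

.values_of <- function(x) {
  if (inherits(x, "subject_matrix")) x$values else as.matrix(x)
}

#' Decompose a subject matrix into eigenbrains and subject scores
#'
#' Singular value decomposition of the subject-by-voxel matrix. Each retained
#' component consists of a unit-norm voxel-loading map (eigenbrain) and one
#' score per subject. A deterministic sign convention is applied: each
#' eigenbrain is oriented so its largest-magnitude voxel loading is positive
#' (direction is otherwise arbitrary and carries no meaning).
#'
#' @param x a `subject_matrix` (see [build_subject_matrix()]) or plain numeric
#'   matrix (subjects in rows).
#' @param k_max maximum number of components to return (default: full rank).
#' @param method `"auto"` picks the dual (Gram-matrix) form when voxels
#'   outnumber subjects, `"dual"` or `"direct"` force a form (they agree to
#'   numerical precision; the direct form is the small-matrix oracle).
#' @param center_voxels if `TRUE`, voxel columns are mean-centered before the
#'   SVD. Default `FALSE`: the only preprocessing is the per-subject robust
#'   scaling already recorded in the subject matrix.
#' @return an object of class `eb_decomposition` with fields `eigenbrains`
#'   (K x voxels, orthonormal rows), `scores` (subjects x K, orthogonal
#'   columns), `singular_values` (length K, descending),
#'   `variance_fraction` (share of total covariance per retained component),
#'   `latent_roots` (full spectrum, scaled to mean ~1), `n_subjects`,
#'   `n_voxels`, `rank`.
#' @export
eb_decompose <- function(x, k_max = NULL, method = c("auto", "dual", "direct"),
                         center_voxels = FALSE) {
  method <- match.arg(method)
  X <- .values_of(x)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 subjects")
  if (center_voxels) X <- sweep(X, 2L, colMeans(X), "-")
  kfull <- min(n, p)
  if (is.null(k_max)) k_max <- kfull
  if (k_max > kfull) stop("k_max exceeds min(n_subjects, n_voxels)")

  if (method == "auto") method <- if (p > n) "dual" else "direct"
  if (method == "dual") {
    eg <- eigen(tcrossprod(X), symmetric = TRUE)
    lambda <- pmax(eg$values[seq_len(kfull)], 0)
    sv <- sqrt(lambda)
    U <- eg$vectors[, seq_len(kfull), drop = FALSE]
  } else {
    sv_d <- svd(X, nu = kfull, nv = 0)
    sv <- sv_d$d[seq_len(kfull)]
    U <- sv_d$u
  }
  # numerical rank: discard components indistinguishable from zero
  tol <- sv[1] * 1e-7
  rank <- sum(sv > tol)
  k <- min(k_max, rank)
  if (k < 1L) stop("matrix has numerical rank 0")

  sv_k <- sv[seq_len(k)]
  U_k <- U[, seq_len(k), drop = FALSE]
  # V_k = X' U_k / sv_k ; eigenbrains are rows of V_k'
  V <- crossprod(X, U_k)
  V <- sweep(V, 2L, sv_k, "/")
  eigenbrains <- t(V)
  scores <- sweep(U_k, 2L, sv_k, "*")

  # sign convention: dominant-magnitude voxel loading positive
  for (j in seq_len(k)) {
    peak <- which.max(abs(eigenbrains[j, ]))
    if (eigenbrains[j, peak] < 0) {
      eigenbrains[j, ] <- -eigenbrains[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(X)

  tot <- sum(sv^2)
  structure(
    list(eigenbrains = eigenbrains, scores = scores,
         singular_values = sv_k,
         singular_values_full = sv,
         variance_fraction = sv_k^2 / tot,
         latent_roots = .latent_roots(sv, n, p),
         n_subjects = n, n_voxels = p, rank = rank,
         center_voxels = center_voxels),
    class = "eb_decomposition"
  )
}

#' @export
print.eb_decomposition <- function(x, ...) {
  cat("eb_decomposition:", length(x$singular_values), "components,",
      x$n_subjects, "subjects x", x$n_voxels, "voxels\n")
  cat("  variance fraction (first 6):",
      paste(sprintf("%.3f", utils::head(x$variance_fraction, 6)), collapse = " "), "\n")
  invisible(x)
}

#' Covariance fraction explained per component
#'
#' @param singular_values nonnegative, descending singular values.
#' @return vector of fractions \eqn{s_i^2 / \sum_j s_j^2}.
#' @export
variance_explained <- function(singular_values) {
  if (any(singular_values < 0)) stop("singular values must be nonnegative")
  if (is.unsorted(rev(singular_values))) stop("singular values must be descending")
  tot <- sum(singular_values^2)
  if (tot <= 0) stop("all singular values are zero")
  singular_values^2 / tot
}

.retention_result <- function(n_retained, rule, null_roots = NULL,
                              seed = NA_integer_, observed_roots = NULL) {
  structure(list(n_retained = as.integer(n_retained), rule = rule,
                 null_roots = null_roots, seed = seed,
                 observed_roots = observed_roots),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat("retention_result:", x$n_retained, "components retained (rule:", x$rule, ")\n")
  invisible(x)
}

#' Latent-root (Kaiser-style) component retention
#'
#' Components whose latent root exceeds 1 are retained, where latent roots are
#' the component variances rescaled so that their mean over the spectrum of a
#' same-dimension random matrix is 1. Retention is taken as a prefix of the
#' descending spectrum.
#'
#' @param decomp an `eb_decomposition`.
#' @return a `retention_result` with `rule = "latent_root_gt1"`.
#' @export
latent_root_retention <- function(decomp) {
  lr <- decomp$latent_roots
  above <- lr > 1
  n_ret <- if (!above[1]) 0L else which.min(c(above, FALSE)) - 1L
  .retention_result(n_ret, "latent_root_gt1", observed_roots = lr)
}

#' Horn's parallel analysis (Monte-Carlo) component retention
#'
#' Compares the observed latent roots component-wise against a percentile of
#' the latent roots of `n_iter` standard-normal matrices of identical
#' dimensions. The longest prefix of components exceeding their null
#' threshold is retained.
#'
#' @param x a `subject_matrix` or numeric matrix (subjects in rows).
#' @param n_iter number of null matrices (>= 100).
#' @param percentile null percentile in (50, 100); default 95.
#' @param seed integer seed making the null draws reproducible.
#' @return a `retention_result` with `rule = "parallel_analysis"` and
#'   `null_roots` holding the per-component thresholds.
#' @export
parallel_analysis <- function(x, n_iter = 500L, percentile = 95, seed = 1L) {
  if (n_iter < 100L) stop("n_iter must be at least 100")
  if (percentile <= 50 || percentile >= 100) stop("percentile must be in (50, 100)")
  X <- .values_of(x)
  n <- nrow(X); p <- ncol(X)
  kfull <- min(n, p)
  observed <- .latent_roots(.full_spectrum(X), n, p)

  null_roots <- matrix(NA_real_, nrow = n_iter, ncol = kfull)
  withr::local_seed(seed)
  for (it in seq_len(n_iter)) {
    Z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
    null_roots[it, ] <- .latent_roots(.full_spectrum(Z), n, p)
  }
  thr <- apply(null_roots, 2L, stats::quantile, probs = percentile / 100,
               names = FALSE, type = 7)
  above <- observed > thr
  n_ret <- if (!above[1]) 0L else which.min(c(above, FALSE)) - 1L
  .retention_result(n_ret, "parallel_analysis", null_roots = thr,
                    seed = as.integer(seed), observed_roots = observed)
}

#' Project new subjects onto an existing decomposition
#'
#' Returns `new_rows %*% t(eigenbrains)`. Rows must live in the same masked
#' voxel space and have been scaled with the same procedure as the training
#' matrix.
#'
#' @param decomp an `eb_decomposition`.
#' @param new_rows matrix (or vector) of masked, scaled voxel rows.
#' @return scores matrix, one row per new subject.
#' @export
eb_project <- function(decomp, new_rows) {
  if (is.null(dim(new_rows))) new_rows <- matrix(new_rows, nrow = 1L)
  if (ncol(new_rows) != decomp$n_voxels) {
    stop("new rows have ", ncol(new_rows), " voxels; decomposition has ",
         decomp$n_voxels)
  }
  new_rows %*% t(decomp$eigenbrains)
}

#' Rescale score columns to 0-100 within-cohort percentiles
#'
#' Rank-based linear rescaling per component: the lowest score maps to 0, the
#' highest to 100, the median to 50; ties share the mean of their ranks.
#'
#' @param scores subjects x components numeric matrix (>= 2 subjects).
#' @return matrix of the same shape with values in \[0, 100\].
#' @export
rescale_scores_percentile <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need at least 2 subjects")
  apply(scores, 2L, function(col) {
    if (max(col) == min(col)) stop("constant score column cannot be rescaled")
    (rank(col, ties.method = "average") - 1) / (length(col) - 1) * 100
  })
}
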