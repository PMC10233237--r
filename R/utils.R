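#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Equals 1 for identical partitions (up to label permutation), is close to 0
#' for independent ones, and can be negative.
#'
#' @param a,b vectors of cluster labels (any type coercible to factor),
#'   same length.
#' @return a single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have the same length")
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) stop("need at least 2 items")
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1) # both partitions trivial (all singletons/all one)
  (sij - expected) / (maxi - expected)
}

# column z-scoring with sample sd; errors on constant columns
zscore_cols <- function(m, what = "column") {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  if (any(sd == 0 | !is.finite(sd))) {
    stop("constant or degenerate ", what, "(s): ",
         paste(which(sd == 0 | !is.finite(sd)), collapse = ", "))
  }
  sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number")
  }
  invisible(x)
}
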