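# Relating per-subject factor scores to clinical and cognitive variables:
# standardized multivariable regression (one model per outcome), group
# comparisons (one-way ANOVA with Tukey-Kramer post-hocs, chi-square for
# categorical variables), and descriptive spatial decoding of factor maps.

#' Cognitive-domain composite score
#'
#' Arithmetic mean of the available scaled scores within one domain; missing
#' tests are ignored. A fully missing set yields `NA`. Discontinued tests are
#' expected to already be coded at the floor scaled score before entry.
#'
#' @param test_scores numeric vector of scaled scores (may contain `NA`).
#' @return the composite (single numeric), or `NA` if all scores are missing.
#' @export
composite_score <- function(test_scores) {
  if (all(is.na(test_scores))) return(NA_real_)
  mean(test_scores, na.rm = TRUE)
}

#' Standardized multivariable regression of an outcome on factor scores
#'
#' Ordinary least squares of the z-scored outcome on z-scored component
#' scores, after listwise deletion of rows with any missing value. The
#' coefficients are standardized betas; with orthogonal score columns each
#' beta equals the simple correlation between that component and the outcome.
#'
#' @param scores subjects x K numeric matrix of retained component scores.
#' @param outcome numeric vector (one value per subject; `NA` allowed).
#' @param outcome_name label carried into the result.
#' @return an object of class `regression_result`: `outcome`, `n_used`,
#'   `betas`, `beta_pvalues`, `r2`, `r2_adj`, `model_pvalue`.
#' @export
fit_multivariable <- function(scores, outcome, outcome_name = "outcome") {
  scores <- as.matrix(scores)
  if (length(outcome) != nrow(scores)) {
    stop("outcome length does not match number of subjects")
  }
  k <- ncol(scores)
  keep <- stats::complete.cases(scores, outcome)
  n_used <- sum(keep)
  if (n_used < k + 2L) {
    stop("insufficient complete cases for '", outcome_name, "': ", n_used,
         " (need at least ", k + 2L, ")")
  }
  y <- outcome[keep]
  X <- scores[keep, , drop = FALSE]
  if (stats::sd(y) == 0) stop("constant outcome '", outcome_name, "'")
  yz <- as.vector(scale(y))
  Xz <- zscore_cols(X, what = "predictor column")

  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xz), yz)
  betas <- fit$coefficients[-1L]
  names(betas) <- colnames(scores) %||% paste0("EB", seq_len(k))
  df_res <- n_used - k - 1L
  rss <- sum(fit$residuals^2)
  tss <- sum(yz^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n_used - 1L) / df_res
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(fit$qr$qr[seq_len(k + 1L), , drop = FALSE])
  se <- sqrt(pmax(diag(XtXinv)[-1L] * sigma2, 0))
  tval <- ifelse(se > 0, betas / se, Inf * sign(betas))
  beta_p <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  fstat <- (r2 / k) / ((1 - r2) / df_res)
  model_p <- stats::pf(fstat, k, df_res, lower.tail = FALSE)
  if (!is.finite(fstat)) model_p <- 0 # perfect fit

  structure(
    list(outcome = outcome_name, n_used = n_used, betas = betas,
         beta_pvalues = beta_p, r2 = r2, r2_adj = r2_adj,
         model_pvalue = model_p),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("regression_result: %s (n = %d)  R2 = %.3f  R2adj = %.3f  p = %.3g\n",
              x$outcome, x$n_used, x$r2, x$r2_adj, x$model_pvalue))
  print(round(x$betas, 3))
  invisible(x)
}

#' One-way ANOVA with Tukey-Kramer post-hoc comparisons
#'
#' Omnibus F test across groups plus all pairwise comparisons adjusted with
#' Tukey's honestly-significant-difference procedure (Tukey-Kramer form for
#' unbalanced groups, via the studentized range distribution).
#'
#' @param values numeric vector (`NA` allowed).
#' @param labels group labels, same length as `values`.
#' @param variable label carried into the result.
#' @return an object of class `group_comparison`: `variable`, `groups`
#'   (per-group n/mean/sd), `statistic` (F), `df`, `p_value`, `pairwise`
#'   (data frame of Tukey-adjusted pairwise comparisons).
#' @export
compare_groups_anova <- function(values, labels, variable = "variable") {
  if (length(values) != length(labels)) stop("values and labels differ in length")
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  g <- factor(labels[keep])
  counts <- table(g)
  all_groups <- levels(g)
  missing_groups <- setdiff(unique(as.character(labels[!is.na(labels)])), all_groups[counts > 0])
  if (any(counts == 0) || length(missing_groups) > 0) {
    warning("group(s) entirely missing for '", variable, "': ",
            paste(c(all_groups[counts == 0], missing_groups), collapse = ", "))
    g <- droplevels(g)
    counts <- table(g)
  }
  if (length(levels(g)) < 2L || sum(counts >= 2L) < 2L) {
    stop("need at least 2 groups with at least 2 non-missing values each for '",
         variable, "'")
  }
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1L]]
  fstat <- an[["F value"]][1L]
  pval <- an[["Pr(>F)"]][1L]
  if (is.na(fstat)) { # zero residual variance with zero between variance
    fstat <- 0; pval <- 1
  }
  tuk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(
    pair = rownames(tuk), diff = tuk[, "diff"],
    p_adjusted = tuk[, "p adj"], row.names = NULL,
    stringsAsFactors = FALSE
  )
  per_group <- data.frame(
    group = levels(g),
    n = as.integer(counts),
    mean = as.vector(tapply(values, g, mean)),
    sd = as.vector(tapply(values, g, stats::sd)),
    stringsAsFactors = FALSE
  )
  structure(
    list(variable = variable, groups = per_group, statistic = fstat,
         df = c(an$Df[1L], an$Df[2L]), p_value = pval, pairwise = pairwise,
         test = "anova"),
    class = "group_comparison"
  )
}

#' Pearson chi-square test on a contingency table
#'
#' @param counts r x c matrix of nonnegative integer counts.
#' @param variable label carried into the result.
#' @return a `group_comparison` with the chi-square `statistic`, `df` and
#'   `p_value`.
#' @export
compare_groups_chisq <- function(counts, variable = "variable") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (sum(counts) <= 0) stop("empty contingency table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) stop("expected cell count of zero for '", variable, "'")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(
    list(variable = variable, groups = NULL,
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, pairwise = NULL, test = "chisq"),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- if (x$test == "anova") "F" else "chi-square"
  cat(sprintf("group_comparison: %s  %s = %.3f (df %s)  p = %.3g\n",
              x$variable, lab, x$statistic, paste(x$df, collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Descriptive spatial decoding of a factor map against reference maps
#'
#' Pearson correlation within the mask between one eigenbrain and each named
#' reference map. Purely descriptive: no significance testing is performed,
#' and interpretation should weigh direction and relative strength rather
#' than absolute coefficient size.
#'
#' @param eigenbrain numeric vector of masked voxel loadings, or a 3D array
#'   (then `mask` is required).
#' @param reference_maps named list of vectors/3D arrays in the same space.
#' @param mask optional [brain_mask()] used to extract masked values from 3D
#'   inputs.
#' @return named numeric vector of correlations.
#' @export
spatial_decode <- function(eigenbrain, reference_maps, mask = NULL) {
  pick <- function(m) {
    if (!is.null(dim(m)) && length(dim(m)) == 3L) {
      if (is.null(mask)) stop("a mask is required for 3D map inputs")
      as.double(m[mask$voxel_index])
    } else {
      as.double(m)
    }
  }
  eb <- pick(eigenbrain)
  if (stats::sd(eb) == 0) stop("constant eigenbrain map")
  out <- vapply(reference_maps, function(m) {
    v <- pick(m)
    if (length(v) != length(eb)) stop("reference map length mismatch")
    if (stats::sd(v) == 0) stop("constant reference map")
    stats::cor(eb, v)
  }, numeric(1))
  out
}
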