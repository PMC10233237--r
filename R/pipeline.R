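# Single-config orchestration of the full analysis:
# normalize -> subject matrix -> decompose -> retain -> regress -> cluster ->
# Z maps -> group comparisons -> manifest. Any stage failure aborts with a
# stage-named error and leaves a FAILED marker next to the partial outputs.

#' Build a pipeline configuration
#'
#' @param patients,controls directories of per-subject NIfTI volumes.
#' @param brain_mask,reference_mask NIfTI mask paths (nonzero = included).
#' @param clinical optional CSV path with a `subject_id` column.
#' @param outcomes clinical outcome column names to regress/compare.
#' @param categorical clinical categorical column names for chi-square
#'   comparisons across subtypes.
#' @param scale apply per-subject robust scaling to the subject matrix.
#' @param retention_rule `"latent_root_gt1"` or `"parallel_analysis"`.
#' @param pa_iter,pa_percentile parallel-analysis settings.
#' @param metrics candidate clustering distance metrics.
#' @param q preference quantile.
#' @param damping,max_iter,conv_iter affinity-propagation settings.
#' @param zmap_threshold optional Z display threshold (with `zmap_direction`).
#' @param zmap_direction `"below"`, `"above"` or `"two_sided"`.
#' @param na_token missing-value token in the clinical CSV.
#' @param seed master seed recorded in every artifact.
#' @return a `pipeline_config` list (validate with [validate_config()]).
#' @export
pipeline_config <- function(patients, controls, brain_mask, reference_mask,
                            clinical = NULL, outcomes = character(0),
                            categorical = character(0), scale = TRUE,
                            retention_rule = "latent_root_gt1",
                            pa_iter = 500L, pa_percentile = 95,
                            metrics = c("euclidean", "manhattan", "correlation"),
                            q = 0.1, damping = 0.9, max_iter = 2000L,
                            conv_iter = 200L, zmap_threshold = NULL,
                            zmap_direction = "below", na_token = "NA",
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every path, range, and enum; fills defaults for missing optional
#' fields; aggregates all problems into one human-readable error.
#'
#' @param config a `pipeline_config` or plain named list (e.g. from JSON).
#' @return the validated config (classed, defaults filled).
#' @export
validate_config <- function(config) {
  config <- as.list(config)
  defaults <- list(outcomes = character(0), categorical = character(0),
                   scale = TRUE, retention_rule = "latent_root_gt1",
                   pa_iter = 500L, pa_percentile = 95,
                   metrics = c("euclidean", "manhattan", "correlation"),
                   q = 0.1, damping = 0.9, max_iter = 2000L, conv_iter = 200L,
                   zmap_threshold = NULL, zmap_direction = "below",
                   na_token = "NA", seed = 1L, clinical = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[nm] <- list(defaults[[nm]])
  }
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  for (nm in c("patients", "controls")) {
    need(!is.null(config[[nm]]) && dir.exists(config[[nm]]),
         paste0("'", nm, "' must be an existing directory"))
  }
  for (nm in c("brain_mask", "reference_mask")) {
    need(!is.null(config[[nm]]) && file.exists(config[[nm]]),
         paste0("'", nm, "' must be an existing file"))
  }
  if (!is.null(config$clinical)) {
    need(file.exists(config$clinical), "'clinical' file does not exist")
  }
  need(length(config$metrics) >= 1, "empty metric list")
  need(all(config$metrics %in% c("euclidean", "manhattan", "correlation")),
       "unknown metric in 'metrics'")
  need(config$q > 0 && config$q < 1, "'q' must be in (0, 1)")
  need(config$damping >= 0.5 && config$damping < 1, "'damping' must be in [0.5, 1)")
  need(config$retention_rule %in% c("latent_root_gt1", "parallel_analysis"),
       "unknown 'retention_rule'")
  need(config$pa_percentile > 50 && config$pa_percentile < 100,
       "'pa_percentile' must be in (50, 100)")
  need(config$zmap_direction %in% c("below", "above", "two_sided"),
       "unknown 'zmap_direction'")
  need(is.numeric(config$seed) && length(config$seed) == 1,
       "'seed' must be a single integer")
  if (length(errs) > 0) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  class(config) <- "pipeline_config"
  config
}

.list_volumes <- function(dir, shape = NULL) {
  paths <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(paths) == 0L) stop("no NIfTI volumes found in ", dir)
  lapply(paths, read_volume, expected_shape = shape)
}

#' Run the full pipeline from a validated configuration
#'
#' Produces, in order: eigenbrain NIfTIs and a variance table; the retention
#' result; a tidy regression CSV (one row per outcome/term); per-metric
#' clustering with silhouettes, the selected solution and a linkage-style
#' merge table; subtype-vs-control Z maps; a group-comparison CSV; and a JSON
#' manifest with seeds, package version, parameter values and input
#' checksums. Any stage failure aborts with a stage-named error and a FAILED
#' marker file in `out_dir`.
#'
#' @param config a `pipeline_config` (validated on entry).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  stages_done <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(c(name, conditionMessage(e)), failed_marker)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stages_done <<- c(stages_done, name)
    message("[eigenbrains] stage '", name, "' completed")
    res
  }

  inputs <- stage("load", {
    mask <- read_mask(config$brain_mask)
    reference <- read_mask(config$reference_mask, expected_shape = mask$dim)
    patients <- .list_volumes(config$patients, shape = mask$dim)
    controls <- .list_volumes(config$controls, shape = mask$dim)
    clinical <- if (!is.null(config$clinical)) {
      utils::read.csv(config$clinical, na.strings = config$na_token,
                      stringsAsFactors = FALSE)
    }
    list(mask = mask, reference = reference, patients = patients,
         controls = controls, clinical = clinical)
  })

  normalized <- stage("normalize", {
    list(patients = lapply(inputs$patients, suvr_normalize, reference = inputs$reference),
         controls = lapply(inputs$controls, suvr_normalize, reference = inputs$reference))
  })

  sm <- stage("matrix", {
    build_subject_matrix(normalized$patients, inputs$mask, scale = config$scale)
  })

  decomp <- stage("decompose", {
    d <- eb_decompose(sm)
    vt <- data.frame(component = seq_along(d$singular_values),
                     singular_value = d$singular_values,
                     variance_fraction = d$variance_fraction,
                     latent_root = d$latent_roots[seq_along(d$singular_values)])
    utils::write.csv(vt, file.path(out_dir, "variance_table.csv"), row.names = FALSE)
    d
  })

  retention <- stage("retain", {
    r <- if (config$retention_rule == "parallel_analysis") {
      parallel_analysis(sm, n_iter = config$pa_iter,
                        percentile = config$pa_percentile, seed = config$seed)
    } else {
      latent_root_retention(decomp)
    }
    if (r$n_retained < 1L) stop("no components retained")
    jsonlite::write_json(
      list(rule = r$rule, n_retained = r$n_retained, seed = r$seed,
           observed_roots = r$observed_roots, null_roots = r$null_roots),
      file.path(out_dir, "retention.json"), auto_unbox = TRUE, digits = NA)
    r
  })

  k <- retention$n_retained
  scores <- decomp$scores[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("EB", seq_len(k))

  stage("export_eigenbrains", {
    for (j in seq_len(k)) {
      write_nifti(unflatten_row(decomp$eigenbrains[j, ], inputs$mask),
                  file.path(out_dir, sprintf("eigenbrain_%d.nii.gz", j)))
    }
    utils::write.csv(
      data.frame(subject_id = sm$subject_ids, scores, check.names = FALSE),
      file.path(out_dir, "scores.csv"), row.names = FALSE)
  })

  regressions <- stage("regress", {
    rows <- list()
    if (!is.null(inputs$clinical) && length(config$outcomes) > 0) {
      cl <- inputs$clinical[match(sm$subject_ids, inputs$clinical$subject_id), ,
                            drop = FALSE]
      for (oc in config$outcomes) {
        if (!oc %in% names(cl)) stop("outcome '", oc, "' not in clinical table")
        fit <- fit_multivariable(scores, cl[[oc]], outcome_name = oc)
        rows[[oc]] <- data.frame(
          outcome = oc, n_used = fit$n_used, r2 = fit$r2, r2_adj = fit$r2_adj,
          model_pvalue = fit$model_pvalue, term = names(fit$betas),
          beta = unname(fit$betas), beta_pvalue = unname(fit$beta_pvalues))
      }
      utils::write.csv(do.call(rbind, rows),
                       file.path(out_dir, "regression_table.csv"),
                       row.names = FALSE)
    }
    rows
  })

  clustering <- stage("cluster", {
    sel <- select_metric(scores, metrics = config$metrics, q = config$q,
                         damping = config$damping, max_iter = config$max_iter,
                         conv_iter = config$conv_iter, seed = config$seed)
    utils::write.csv(
      data.frame(subject_id = sm$subject_ids, subtype = sel$best$labels,
                 exemplar_id = sm$subject_ids[sel$best$exemplars[sel$best$labels]],
                 silhouette = sel$best$silhouette),
      file.path(out_dir, "subtypes.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(metric = names(sel$silhouettes),
                 mean_silhouette = unname(sel$silhouettes),
                 n_clusters = vapply(sel$results, function(r) r$n_clusters, integer(1)),
                 converged = vapply(sel$results, function(r) r$converged, logical(1)),
                 selected = names(sel$silhouettes) == sel$best_metric),
      file.path(out_dir, "metric_selection.csv"), row.names = FALSE)
    utils::write.csv(sel$best$merge_tree, file.path(out_dir, "merge_tree.csv"),
                     row.names = FALSE)
    sel
  })

  stage("zmaps", {
    ref <- control_reference(normalized$controls, inputs$mask)
    for (cl_idx in sort(unique(clustering$best$labels))) {
      zm <- zmap_group(normalized$patients[clustering$best$labels == cl_idx],
                       ref, id = paste0("subtype_", cl_idx))
      if (!is.null(config$zmap_threshold)) {
        zm <- threshold_map(zm, config$zmap_threshold, config$zmap_direction)
      }
      write_nifti(zm$values,
                  file.path(out_dir, sprintf("zmap_subtype_%d.nii.gz", cl_idx)))
    }
  })

  stage("group_comparisons", {
    if (!is.null(inputs$clinical)) {
      cl <- inputs$clinical[match(sm$subject_ids, inputs$clinical$subject_id), ,
                            drop = FALSE]
      labels <- clustering$best$labels
      rows <- list()
      for (oc in config$outcomes) {
        gc <- tryCatch(compare_groups_anova(cl[[oc]], labels, variable = oc),
                       error = function(e) NULL)
        if (!is.null(gc)) {
          rows[[oc]] <- data.frame(variable = oc, test = "anova",
                                   statistic = gc$statistic, p_value = gc$p_value)
        }
      }
      for (cv in config$categorical) {
        if (!cv %in% names(cl)) next
        tab <- table(cl[[cv]], labels)
        gc <- tryCatch(compare_groups_chisq(tab, variable = cv),
                       error = function(e) NULL)
        if (!is.null(gc)) {
          rows[[cv]] <- data.frame(variable = cv, test = "chisq",
                                   statistic = gc$statistic, p_value = gc$p_value)
        }
      }
      if (length(rows) > 0) {
        utils::write.csv(do.call(rbind, rows),
                         file.path(out_dir, "group_comparisons.csv"),
                         row.names = FALSE)
      }
    }
  })

  manifest <- stage("manifest", {
    input_files <- c(config$brain_mask, config$reference_mask, config$clinical,
                     list.files(config$patients, full.names = TRUE),
                     list.files(config$controls, full.names = TRUE))
    m <- list(
      package = "eigenbrains",
      version = as.character(utils::packageVersion("eigenbrains")),
      seed = config$seed,
      parameters = config[setdiff(names(config), c("patients", "controls",
                                                   "brain_mask", "reference_mask",
                                                   "clinical"))],
      n_patients = length(inputs$patients),
      n_controls = length(inputs$controls),
      n_voxels = inputs$mask$n_voxels,
      n_retained = k,
      retention_rule = retention$rule,
      best_metric = clustering$best_metric,
      n_subtypes = clustering$best$n_clusters,
      subtype_sizes = as.integer(table(clustering$best$labels)),
      variance_fraction_retained = sum(decomp$variance_fraction[seq_len(k)]),
      mean_silhouette = clustering$best$silhouette_mean,
      input_checksums = as.list(tools::md5sum(input_files)),
      stages = c(stages_done, "manifest")
    )
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  invisible(manifest)
}
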