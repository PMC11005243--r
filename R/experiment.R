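# Configured, seeded experiment runs over the full grid: (merged vs
# single-study vs merged subset) x (pair features vs raw genes) x the
# three classifier families, each producing a result bundle on disk
# (metrics JSON, ROC TSV, selection-profile TSV, consistency TSV,
# manifest JSON) that compare_runs() can lay out as a summary grid.

#' Configure an experiment run
#'
#' Paths point at the plain-text layout written by [write_simulation()]
#' (or any files with the same columns): per-study expression TSVs, a
#' combined metadata TSV with `sample_id`, `study_id`,
#' `response_annotation`, an optional gene-length TSV (required for
#' counts input) and an optional panel TSV.
#'
#' @param expression_paths Named character vector, study id -> expression
#'   TSV (genes in rows).
#' @param metadata_path Metadata TSV path.
#' @param units Unit per study: a single string or a named vector aligned
#'   with `expression_paths` (default `"TPM"`).
#' @param panel_path Optional panel TSV (default: packaged panel).
#' @param lengths_path Optional gene-length TSV (`gene_id`, `length_kb`).
#' @param mapping_path Optional response-mapping TSV.
#' @param feature_mode `"pair_features"` (binary pair indicators) or
#'   `"raw_genes"` (log2(TPM+1) of every common gene; when combined with
#'   a multi-study dataset mode, [batch_standardize()] is applied first).
#' @param dataset_mode `"merged"`, `"single:<study>"`, or
#'   `"merged_subset:<id1+id2>"`.
#' @param methods Classifier families to evaluate (default all three).
#' @param folds,replicates,seed Cross-validation settings (defaults 10,
#'   10, 1).
#' @param out_dir Output bundle directory.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(expression_paths, metadata_path,
                              units = "TPM", panel_path = NULL,
                              lengths_path = NULL, mapping_path = NULL,
                              feature_mode = c("pair_features", "raw_genes"),
                              dataset_mode = "merged",
                              methods = icb_methods,
                              folds = 10, replicates = 10, seed = 1,
                              out_dir = tempfile("icb_run_")) {
  feature_mode <- match.arg(feature_mode)
  if (is.null(names(expression_paths)) || any(names(expression_paths) == "")) {
    abort("expression_paths must be named by study id")
  }
  if (length(units) == 1) {
    units <- setNames(rep(units, length(expression_paths)),
                      names(expression_paths))
  }
  missing <- c(expression_paths, metadata_path, panel_path, lengths_path,
               mapping_path)
  missing <- missing[!file.exists(missing)]
  if (length(missing) > 0) {
    abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(methods, icb_methods)
  if (length(bad) > 0) {
    abort(paste0("unsupported method(s): ", paste(bad, collapse = ", ")))
  }
  if (folds < 2) abort("folds must be >= 2")
  parse_dataset_mode(dataset_mode, names(expression_paths))
  structure(list(
    expression_paths = expression_paths, metadata_path = metadata_path,
    units = units, panel_path = panel_path, lengths_path = lengths_path,
    mapping_path = mapping_path, feature_mode = feature_mode,
    dataset_mode = dataset_mode, methods = methods, folds = folds,
    replicates = replicates, seed = as.integer(seed), out_dir = out_dir
  ), class = "experiment_config")
}

parse_dataset_mode <- function(mode, study_ids) {
  if (identical(mode, "merged")) return(study_ids)
  if (grepl("^single:", mode)) {
    id <- sub("^single:", "", mode)
    if (!id %in% study_ids) abort(paste0("unknown study in dataset_mode: ", id))
    return(id)
  }
  if (grepl("^merged_subset:", mode)) {
    ids <- strsplit(sub("^merged_subset:", "", mode), "+", fixed = TRUE)[[1]]
    bad <- setdiff(ids, study_ids)
    if (length(bad) > 0) {
      abort(paste0("unknown study in dataset_mode: ", paste(bad, collapse = ", ")))
    }
    return(ids)
  }
  abort(paste0("invalid dataset_mode: ", mode))
}

load_configured_studies <- function(config) {
  mapping <- if (is.null(config$mapping_path)) default_response_mapping()
             else default_response_mapping(config$mapping_path)
  lengths <- if (is.null(config$lengths_path)) NULL
             else readr::read_tsv(config$lengths_path, comment = "#",
                                  show_col_types = FALSE, progress = FALSE)
  metadata <- readr::read_tsv(config$metadata_path, comment = "#",
                              show_col_types = FALSE, progress = FALSE)
  metadata <- standardize_response(metadata, mapping)
  imap(config$expression_paths, function(path, id) {
    expr <- read_expression(path, unit = config$units[[id]])
    expr <- to_tpm(expr, lengths)
    md <- metadata |>
      filter(.data$study_id == id) |>
      select("sample_id", "response_annotation", "label")
    md <- md[match(expr_samples(expr), md$sample_id), ]
    if (anyNA(md$sample_id)) {
      abort(paste0("metadata missing samples for study ", id))
    }
    study_dataset(id, expr, md)
  })
}

#' Run a configured experiment end to end
#'
#' Load -> harmonize units -> standardize responses -> merge (per
#' `dataset_mode`) -> build the feature matrix (pair indicators, or
#' log2(TPM+1) raw genes with [batch_standardize()] applied when several
#' studies are combined) -> [cross_validate()] each method -> write the
#' result bundle. Any stage error aborts the run with a stage-tagged
#' message and removes partial outputs.
#'
#' Bundle contents: `metrics.json` (per-replicate and mean AUCs per
#' method), `roc_<method>.tsv` (mean ROC points), `selection.tsv`
#' (feature, method, probability), `consistency.tsv` (Spearman matrix,
#' when >= 2 methods) and `manifest.json` (config echo plus the defaults
#' actually used).
#'
#' @param config An [experiment_config()].
#' @return Invisibly, a list of class `icb_experiment` with the fitted
#'   `cv` objects (one per method), the selection `profile`, the
#'   `consistency` matrix and `out_dir`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  created <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  result <- tryCatch({
    stage <- "load"
    studies <- load_configured_studies(config)
    keep <- parse_dataset_mode(config$dataset_mode, names(studies))
    stage <- "merge"
    merged <- merge_studies(studies[keep])

    stage <- "features"
    if (config$feature_mode == "pair_features") {
      panel <- if (is.null(config$panel_path)) checkpoint_panel()
               else checkpoint_panel(config$panel_path)
      pairs <- enumerate_pairs(panel)
      features <- encode_pair_features(merged$expression, pairs)
    } else {
      expr <- merged$expression
      if (length(keep) > 1) {
        expr <- batch_standardize(expr, merged$metadata$study_id)
      }
      m <- log2(t(expr_values(expr)) + 1)
      features <- bind_cols(tibble(sample_id = rownames(m)),
                            as_tibble(m, .name_repair = "minimal"))
    }

    stage <- "cross-validation"
    cvs <- map(setNames(config$methods, config$methods), function(mth) {
      cross_validate(features, merged$metadata$label, method = mth,
                     folds = config$folds, replicates = config$replicates,
                     seed = config$seed)
    })

    stage <- "selection profiling"
    profile <- selection_profile(cvs)
    consistency <- if (length(cvs) >= 2) {
      suppressWarnings(selection_consistency(profile))
    } else NULL

    stage <- "write outputs"
    metrics <- list(
      dataset_mode = config$dataset_mode,
      feature_mode = config$feature_mode,
      n_samples = nrow(merged$metadata),
      n_features = length(cvs[[1]]$feature_names),
      folds_used = cvs[[1]]$folds,
      methods = map(cvs, function(cv) list(
        mean_auc = cv$mean_auc,
        sd_auc = sd(cv$per_replicate$auc),
        per_replicate_auc = cv$per_replicate$auc))
    )
    jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (mth in names(cvs)) {
      readr::write_tsv(cvs[[mth]]$mean_roc,
                       file.path(out, paste0("roc_", mth, ".tsv")))
    }
    readr::write_tsv(profile, file.path(out, "selection.tsv"))
    if (!is.null(consistency)) {
      readr::write_tsv(
        bind_cols(tibble(method = rownames(consistency)),
                  as_tibble(consistency, .name_repair = "minimal")),
        file.path(out, "consistency.tsv"))
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("icbpairs")),
      r_version = R.version.string,
      seed = config$seed,
      folds_requested = config$folds,
      folds_used = cvs[[1]]$folds,
      replicates = config$replicates,
      stratified = TRUE,
      lasso_lambda_rule = "min",
      rf_selection_rule = "importance above mean",
      feature_mode = config$feature_mode,
      dataset_mode = config$dataset_mode,
      studies = keep,
      units = as.list(config$units[keep])
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    structure(list(cv = cvs, profile = profile, consistency = consistency,
                   metrics = metrics, out_dir = out),
              class = "icb_experiment")
  }, error = function(e) {
    if (created) unlink(out, recursive = TRUE)
    else unlink(file.path(out, c("metrics.json", "manifest.json",
                                 "selection.tsv", "consistency.tsv")))
    abort(paste0("experiment failed at stage [", stage, "]: ",
                 conditionMessage(e)))
  })
  invisible(result)
}

#' @export
print.icb_experiment <- function(x, ...) {
  cat(sprintf("<icb_experiment %s / %s -> %s>\n",
              x$metrics$dataset_mode, x$metrics$feature_mode, x$out_dir))
  for (m in names(x$cv)) print(x$cv[[m]])
  invisible(x)
}

#' Lay out several result bundles as a comparison grid
#'
#' Reads the `metrics.json` of each bundle and emits one row per
#' (dataset mode, feature mode) with the mean and per-replicate spread of
#' AUC for every method -- the summary-table layout for contrasting
#' merged against single-study runs and pair features against raw genes.
#'
#' @param bundles Character vector of bundle directories (from
#'   [run_experiment()]) or a list of `icb_experiment` objects.
#' @return A tibble with columns `dataset_mode`, `feature_mode`,
#'   `n_samples`, then `<method>_auc` and `<method>_sd` per method.
#' @export
compare_runs <- function(bundles) {
  if (length(bundles) == 0) abort("no bundles to compare")
  metrics <- map(bundles, function(b) {
    if (inherits(b, "icb_experiment")) return(b$metrics)
    jsonlite::read_json(file.path(b, "metrics.json"), simplifyVector = FALSE)
  })
  methods <- map(metrics, function(m) sort(names(m$methods)))
  if (length(unique(methods)) != 1) {
    abort("bundles must share the same set of methods")
  }
  purrr::map_dfr(metrics, function(m) {
    row <- tibble(dataset_mode = m$dataset_mode,
                  feature_mode = m$feature_mode,
                  n_samples = m$n_samples)
    for (mth in names(m$methods)) {
      row[[paste0(mth, "_auc")]] <- m$methods[[mth]]$mean_auc
      row[[paste0(mth, "_sd")]] <-
        sd(unlist(m$methods[[mth]]$per_replicate_auc))
    }
    row
  })
}
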