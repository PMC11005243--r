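# Study containers. A study dataset couples a TPM expression table with
# per-sample metadata (study id, raw annotation, binary label); merging
# concatenates studies over the exact intersection of their gene sets,
# prefixing sample ids with the study id so they cannot collide.

#' Bundle one study's expression and labels
#'
#' @param study_id Identifier of the study/batch.
#' @param expression An expression table with unit `"TPM"`.
#' @param metadata A data frame with columns `sample_id` and `label`
#'   (`"response"` / `"non-response"`; typically from
#'   [standardize_response()]), one row per expression sample, same order.
#' @return A list of class `study_dataset` with elements `study_id`,
#'   `expression` and `metadata` (a tibble gaining a `study_id` column).
#' @export
study_dataset <- function(study_id, expression, metadata) {
  if (!identical(expr_unit(expression), "TPM")) {
    abort("study expression must be in TPM; convert with to_tpm()")
  }
  metadata <- as_tibble(metadata)
  if (!all(c("sample_id", "label") %in% names(metadata))) {
    abort("metadata must have columns sample_id and label")
  }
  if (!identical(as.character(metadata$sample_id), expr_samples(expression))) {
    abort("metadata sample_id must match expression samples in the same order")
  }
  bad <- setdiff(unique(metadata$label), c("response", "non-response"))
  if (length(bad) > 0) {
    abort(paste0("labels must be response/non-response, got: ",
                 paste(bad, collapse = ", ")))
  }
  metadata$study_id <- as.character(study_id)
  structure(
    list(study_id = as.character(study_id), expression = expression,
         metadata = metadata),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset '%s': %d genes x %d samples, %d responders>\n",
              x$study_id, length(expr_genes(x$expression)),
              nrow(x$metadata), sum(x$metadata$label == "response")))
  invisible(x)
}

#' Merge studies over their common genes
#'
#' Restricts every study to the exact intersection of gene sets and
#' concatenates samples in study order. Sample ids are prefixed
#' `"studyid:sampleid"` so ids cannot collide across studies. TPM columns
#' are deliberately *not* re-normalized after subsetting to common genes:
#' pair features are unaffected either way (they are per-sample
#' scale-invariant), and re-normalizing would silently change raw-gene
#' baselines.
#'
#' @param studies A list of [study_dataset()] objects (a single study
#'   passes through with batch labels attached).
#' @return A list of class `merged_dataset` with `expression` (common
#'   genes, all samples) and `metadata` (columns `sample_id`, `study_id`,
#'   `label`).
#' @export
merge_studies <- function(studies) {
  if (inherits(studies, "study_dataset")) studies <- list(studies)
  if (length(studies) < 1) abort("no studies to merge")
  ok <- vapply(studies, inherits, logical(1), "study_dataset")
  if (!all(ok)) abort("all elements must be study_dataset objects")
  units <- vapply(studies, function(s) expr_unit(s$expression), character(1))
  if (!all(units == "TPM")) abort("all studies must be in TPM before merging")
  ids <- vapply(studies, function(s) s$study_id, character(1))
  if (anyDuplicated(ids)) abort("duplicated study ids")

  common <- reduce(map(studies, function(s) expr_genes(s$expression)),
                   intersect)
  if (length(common) == 0) abort("empty gene intersection across studies")

  mats <- map(studies, function(s) {
    m <- expr_values(s$expression)[common, , drop = FALSE]
    colnames(m) <- paste0(s$study_id, ":", colnames(m))
    m
  })
  m <- do.call(cbind, mats)
  metadata <- bind_rows(map(studies, function(s) {
    mutate(s$metadata,
           sample_id = paste0(s$study_id, ":", .data$sample_id))
  })) |>
    select("sample_id", "study_id", "label", everything())

  expression <- new_expression(
    bind_cols(tibble(gene_id = common),
              as_tibble(m, .name_repair = "minimal")),
    "TPM")
  structure(list(expression = expression, metadata = metadata),
            class = "merged_dataset")
}

#' @export
print.merged_dataset <- function(x, ...) {
  cat(sprintf(
    "<merged_dataset: %d common genes x %d samples from %d studies>\n",
    length(expr_genes(x$expression)), nrow(x$metadata),
    length(unique(x$metadata$study_id))))
  invisible(x)
}
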