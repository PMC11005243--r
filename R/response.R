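# Clinical response harmonization. Different ICB cohorts annotate outcome
# in different vocabularies (RECIST categories, free text, abbreviations);
# modelling needs one binary outcome. Annotations that the mapping does
# not cover are rejected loudly -- never silently imputed.

#' Default response annotation mapping
#'
#' Complete and partial response map to `"response"`; progressive disease,
#' stable disease and the common non-response spellings map to
#' `"non-response"`. Shipped as an editable TSV so that cohorts with other
#' vocabularies can extend it.
#'
#' @param path Optional path to a custom two-column TSV
#'   (`annotation`, `label`); defaults to the packaged mapping.
#' @return A tibble with columns `annotation` (lower-case,
#'   whitespace-normalized) and `label` (`"response"` / `"non-response"`).
#' @export
default_response_mapping <- function(path = NULL) {
  path <- path %||% system.file("extdata", "response_mapping.tsv",
                                package = "icbpairs", mustWork = TRUE)
  map <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("annotation", "label") %in% names(map))) {
    abort("response mapping must have columns annotation and label")
  }
  bad <- setdiff(unique(map$label), c("response", "non-response"))
  if (length(bad) > 0) {
    abort(paste0("mapping labels must be response/non-response, got: ",
                 paste(bad, collapse = ", ")))
  }
  map$annotation <- normalize_annotation(map$annotation)
  if (anyDuplicated(map$annotation)) abort("duplicated annotations in mapping")
  as_tibble(map)
}

normalize_annotation <- function(x) {
  tolower(trimws(gsub("[[:space:]]+", " ", x)))
}

#' Standardize clinical response annotations to a binary label
#'
#' Matches annotations against the mapping case-insensitively after
#' whitespace normalization. Any annotation the mapping does not cover is
#' an error that names the offending string(s).
#'
#' @param x A character vector of raw annotations, or a data frame with a
#'   `response_annotation` column (a `label` column is appended).
#' @param mapping An annotation mapping, by default
#'   [default_response_mapping()].
#' @return For vector input, a character vector of `"response"` /
#'   `"non-response"`; for data frame input, the tibble with a `label`
#'   column added.
#' @export
#' @examples
#' standardize_response(c("Complete Response", "progressive disease"))
standardize_response <- function(x, mapping = default_response_mapping()) {
  if (is.data.frame(x)) {
    if (!"response_annotation" %in% names(x)) {
      abort("metadata must have a response_annotation column")
    }
    out <- as_tibble(x)
    out$label <- standardize_response(out$response_annotation, mapping)
    return(out)
  }
  key <- normalize_annotation(as.character(x))
  idx <- match(key, mapping$annotation)
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    abort(paste0("unmapped response annotation(s): ",
                 paste(sprintf("'%s'", bad), collapse = ", ")))
  }
  mapping$label[idx]
}
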