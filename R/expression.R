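# Expression tables are tibbles with a `gene_id` column followed by one
# numeric column per sample; the measurement unit travels as an attribute
# so that unit conversions can refuse mislabelled input instead of
# guessing.

expr_units <- c("counts", "FPKM", "TPM", "normalized")

# TPM columns must sum to 1e6 within this relative tolerance
tpm_rel_tol <- 1e-6

new_expression <- function(tbl, unit) {
  attr(tbl, "unit") <- unit
  class(tbl) <- unique(c("icb_expr", class(tbl)))
  tbl
}

#' Construct an expression table
#'
#' An expression table holds a genes-by-samples expression matrix in tidy
#' form: a `gene_id` column followed by one numeric column per sample.
#' Values must be non-negative, identifiers unique, and when `unit` is
#' `"TPM"` every sample column must sum to one million (within relative
#' tolerance `1e-6`).
#'
#' @param tbl A data frame with a `gene_id` column of unique identifiers and
#'   numeric sample columns.
#' @param unit Measurement unit: `"counts"`, `"FPKM"`, `"TPM"` or
#'   `"normalized"` (the latter is produced by [batch_standardize()] and is
#'   not a valid input to unit conversion).
#' @return A tibble of class `icb_expr` carrying `unit` as an attribute
#'   (query it with [expr_unit()]).
#' @seealso [read_expression()], [fpkm_to_tpm()], [counts_to_tpm()]
#' @export
#' @examples
#' expression_table(tibble::tibble(gene_id = "A", s1 = 5), unit = "counts")
expression_table <- function(tbl, unit) {
  unit <- match.arg(unit, expr_units)
  tbl <- as_tibble(tbl)
  validate_expression(tbl, unit)
  new_expression(tbl, unit)
}

validate_expression <- function(tbl, unit) {
  if (!"gene_id" %in% names(tbl) || names(tbl)[1] != "gene_id") {
    abort("expression table must have `gene_id` as its first column")
  }
  if (ncol(tbl) < 2) abort("expression table has no sample columns")
  if (anyDuplicated(tbl$gene_id)) {
    dup <- unique(tbl$gene_id[duplicated(tbl$gene_id)])
    abort(paste0("duplicated gene ids: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(names(tbl))) {
    abort("duplicated sample ids in expression table")
  }
  vals <- tbl[-1]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("all sample columns must be numeric")
  }
  m <- as.matrix(vals)
  if (anyNA(m)) abort("expression values contain NA")
  if (any(m < 0)) abort("expression values must be non-negative")
  if (unit == "TPM") {
    cs <- colSums(m)
    if (any(abs(cs - 1e6) > tpm_rel_tol * 1e6)) {
      abort("unit is TPM but sample columns do not sum to 1e6")
    }
  }
  invisible(tbl)
}

#' Measurement unit of an expression table
#' @param x An expression table created by [expression_table()] or
#'   [read_expression()].
#' @return A character scalar.
#' @export
expr_unit <- function(x) attr(x, "unit", exact = TRUE)

#' @rdname expr_unit
#' @export
expr_genes <- function(x) x$gene_id

#' @rdname expr_unit
#' @export
expr_samples <- function(x) names(x)[-1]

#' Expression values as a genes-by-samples matrix
#' @inheritParams expr_unit
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
expr_values <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene_id
  m
}

# rebuild an expression table from a values matrix, preserving id order
expression_from_matrix <- function(m, unit) {
  tbl <- as_tibble(m, .name_repair = "minimal")
  tbl <- bind_cols(tibble(gene_id = rownames(m)), tbl)
  expression_table(tbl, unit)
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV with a header of identifiers. In the canonical
#' `genes-in-rows` orientation the first column holds gene ids and the
#' remaining columns are samples; `samples-in-rows` reads the transposed
#' layout and returns the same canonical table. The unit is declared by
#' the caller, never guessed from the file.
#'
#' @param path Path to a tab-separated file. Lines starting with `#` are
#'   treated as comments.
#' @param unit Declared unit of the stored values (`"counts"`, `"FPKM"` or
#'   `"TPM"`).
#' @param orientation `"genes-in-rows"` (default) or `"samples-in-rows"`.
#' @return An expression table (see [expression_table()]).
#' @export
read_expression <- function(path, unit,
                            orientation = c("genes-in-rows", "samples-in-rows")) {
  orientation <- match.arg(orientation)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tbl) < 2) abort("malformed expression file: fewer than 2 columns")
  if (orientation == "samples-in-rows") {
    ids <- tbl[[1]]
    if (anyDuplicated(ids)) abort("duplicated sample ids in expression file")
    m <- t(as.matrix(tbl[-1]))
    colnames(m) <- ids
    tbl <- bind_cols(tibble(gene_id = rownames(m)),
                     as_tibble(m, .name_repair = "minimal"))
  } else {
    names(tbl)[1] <- "gene_id"
  }
  tbl$gene_id <- as.character(tbl$gene_id)
  expression_table(tbl, unit)
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression()]: genes in rows, first column `gene_id`,
#' full double precision so that a read/write round trip is lossless.
#'
#' @inheritParams expr_unit
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(as_tibble(unclass(x)), path)
  invisible(path)
}
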