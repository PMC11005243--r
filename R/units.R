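# Unit harmonization. All modelling downstream assumes TPM, in which
# length-adjusted abundances sum to 1e6 per sample; both conversions are
# per-sample positive rescalings and therefore preserve the within-sample
# ordering of genes (exactly for FPKM, among equal-length genes for counts).

#' Convert FPKM to TPM
#'
#' `TPM_g = FPKM_g / sum_g'(FPKM_g') * 1e6` per sample. A per-sample
#' positive rescaling, so the within-sample rank order of genes is
#' preserved exactly.
#'
#' @param x An expression table with unit `"FPKM"`.
#' @return An expression table with unit `"TPM"`; every sample column sums
#'   to 1e6.
#' @export
#' @examples
#' e <- expression_table(tibble::tibble(gene_id = c("A", "B"),
#'                                      s1 = c(2, 3)), unit = "FPKM")
#' expr_values(fpkm_to_tpm(e))  # 400000, 600000
fpkm_to_tpm <- function(x) {
  if (!identical(expr_unit(x), "FPKM")) {
    abort("fpkm_to_tpm() requires an expression table with unit FPKM")
  }
  m <- expr_values(x)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    abort(paste0("cannot normalize all-zero sample column(s): ",
                 paste(colnames(m)[cs <= 0], collapse = ", ")))
  }
  expression_from_matrix(sweep(m, 2, cs, "/") * 1e6, "TPM")
}

#' Convert read counts to TPM
#'
#' Counts are first length-normalized to per-kilobase rates
#' (`rate_g = counts_g / length_g`), then rescaled per sample so the rates
#' sum to 1e6. Genes of equal length keep their count order.
#'
#' @param x An expression table with unit `"counts"`.
#' @param lengths A data frame with columns `gene_id` and `length_kb`
#'   (positive, in kilobases) covering every gene in `x`.
#' @return An expression table with unit `"TPM"`.
#' @export
counts_to_tpm <- function(x, lengths) {
  if (!identical(expr_unit(x), "counts")) {
    abort("counts_to_tpm() requires an expression table with unit counts")
  }
  lengths <- as_tibble(lengths)
  if (!all(c("gene_id", "length_kb") %in% names(lengths))) {
    abort("`lengths` must have columns gene_id and length_kb")
  }
  if (anyDuplicated(lengths$gene_id)) abort("duplicated gene ids in length table")
  missing <- setdiff(expr_genes(x), lengths$gene_id)
  if (length(missing) > 0) {
    abort(paste0("no length for gene(s): ", paste(missing, collapse = ", ")))
  }
  len <- lengths$length_kb[match(expr_genes(x), lengths$gene_id)]
  if (any(!is.finite(len)) || any(len <= 0)) abort("gene lengths must be positive")
  rates <- expr_values(x) / len
  cs <- colSums(rates)
  if (any(cs <= 0)) {
    abort(paste0("cannot normalize all-zero sample column(s): ",
                 paste(colnames(rates)[cs <= 0], collapse = ", ")))
  }
  expression_from_matrix(sweep(rates, 2, cs, "/") * 1e6, "TPM")
}

#' Harmonize an expression table to TPM
#'
#' Dispatches on the declared unit: TPM passes through, FPKM goes through
#' [fpkm_to_tpm()], counts through [counts_to_tpm()] (which requires
#' `lengths`).
#'
#' @inheritParams counts_to_tpm
#' @param lengths Gene length table, required only for counts input.
#' @return An expression table with unit `"TPM"`.
#' @export
to_tpm <- function(x, lengths = NULL) {
  switch(expr_unit(x),
    TPM = x,
    FPKM = fpkm_to_tpm(x),
    counts = {
      if (is.null(lengths)) abort("counts input needs a gene length table")
      counts_to_tpm(x, lengths)
    },
    abort(paste0("cannot convert unit '", expr_unit(x), "' to TPM"))
  )
}
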