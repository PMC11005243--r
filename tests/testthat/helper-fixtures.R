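# Small in-code fixtures shared across the suite.

# expression table from a genes x samples matrix given as a vector
make_expr <- function(values, genes, samples, unit = "counts") {
  m <- matrix(values, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  tbl <- dplyr::bind_cols(tibble::tibble(gene_id = genes),
                          tibble::as_tibble(as.data.frame(m)))
  expression_table(tbl, unit = unit)
}

# tiny panel: p genes named g1..gp, first a of them anchors
make_panel <- function(p, a) {
  tibble::tibble(gene_id = paste0("g", seq_len(p)),
                 is_anchor = seq_len(p) <= a)
}

# random TPM expression table over the default panel plus a few extras
random_panel_expr <- function(n_samples, extra_genes = 5) {
  panel <- checkpoint_panel()
  genes <- c(panel$gene_id, paste0("X", seq_len(extra_genes)))
  m <- matrix(2^rnorm(length(genes) * n_samples, 5, 2),
              nrow = length(genes),
              dimnames = list(genes, paste0("s", seq_len(n_samples))))
  m <- sweep(m, 2, colSums(m), "/") * 1e6
  make_expr(m, genes, colnames(m), unit = "TPM")
}

# small simulation used by several modelling tests
small_sim <- function(effect_delta = 3, seed = 99, sizes = c(20, 16),
                      n_bg = 40, ...) {
  simulate_studies(simulation_config(
    samples_per_study = sizes, n_background_genes = n_bg,
    effect_delta = effect_delta, seed = seed, ...))
}

# brute-force AUC: concordance over all (responder, non-responder) pairs
auc_bruteforce <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  g <- expand.grid(p = pos, n = neg)
  mean(ifelse(g$p > g$n, 1, ifelse(g$p == g$n, 0.5, 0)))
}

# brute-force anchor-constrained pair enumeration
pairs_bruteforce <- function(panel) {
  out <- 0L
  p <- nrow(panel)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (panel$is_anchor[i] || panel$is_anchor[j]) out <- out + 1L
    }
  }
  out
}
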