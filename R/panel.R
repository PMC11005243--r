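# The checkpoint gene panel and anchor-constrained pair enumeration.
# Candidate features are all unordered gene pairs from the panel that
# contain at least one anchor gene; with a anchors among p panel genes
# that is choose(a, 2) + a * (p - a) pairs (135 for the default 26/6
# panel). Only one orientation per pair is kept because the reverse
# indicator is its complement off ties.

#' Load a checkpoint gene panel
#'
#' A panel is an ordered list of gene ids with a flagged anchor subset;
#' anchors are the checkpoint genes directly engaged by anti-PD-1 /
#' anti-CTLA-4 therapy (PD-1, PDL-1, CTLA4, CD28, CD80, CD86 in the
#' packaged default), and every candidate pair must contain one.
#'
#' @param path Optional path to a TSV with columns `gene_id` and
#'   `is_anchor` (0/1); defaults to the packaged 26-gene panel.
#' @return A tibble with columns `gene_id` (character) and `is_anchor`
#'   (logical), in panel order.
#' @export
checkpoint_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "checkpoint_panel.tsv",
                                package = "icbpairs", mustWork = TRUE)
  panel <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c("gene_id", "is_anchor") %in% names(panel))) {
    abort("panel file must have columns gene_id and is_anchor")
  }
  panel <- as_tibble(panel) |>
    mutate(gene_id = as.character(.data$gene_id),
           is_anchor = as.logical(as.integer(.data$is_anchor)))
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  if (anyDuplicated(panel$gene_id)) abort("duplicated gene ids in panel")
  if (anyNA(panel$is_anchor)) abort("is_anchor must be 0/1")
  if (!any(panel$is_anchor)) abort("panel has an empty anchor set")
  invisible(panel)
}

#' Enumerate anchor-constrained gene pairs
#'
#' Returns every unordered pair of distinct panel genes containing at
#' least one anchor, once each, in canonical orientation: the anchor gene
#' first; when both genes are anchors, the one earlier in panel order is
#' first. The output order is deterministic given the panel (lexicographic
#' in panel positions), so feature columns are reproducible across runs.
#'
#' @param panel A panel tibble as returned by [checkpoint_panel()].
#' @return A tibble with columns `first`, `second` and `pair` (the
#'   `"first>second"` feature name). For `a` anchors among `p` panel genes
#'   the row count is `choose(a, 2) + a * (p - a)`.
#' @export
#' @examples
#' nrow(enumerate_pairs(checkpoint_panel()))  # 135
enumerate_pairs <- function(panel) {
  validate_panel(panel)
  p <- nrow(panel)
  if (p < 2) abort("panel needs at least 2 genes to form pairs")
  idx <- utils::combn(p, 2)
  keep <- panel$is_anchor[idx[1, ]] | panel$is_anchor[idx[2, ]]
  idx <- idx[, keep, drop = FALSE]
  # canonical orientation: anchor first; both anchors -> earlier panel
  # position first (combn already emits i < j, so only the case where the
  # second gene is the sole anchor needs swapping)
  swap <- !panel$is_anchor[idx[1, ]] & panel$is_anchor[idx[2, ]]
  first <- ifelse(swap, idx[2, ], idx[1, ])
  second <- ifelse(swap, idx[1, ], idx[2, ])
  g1 <- panel$gene_id[first]
  g2 <- panel$gene_id[second]
  tibble(first = g1, second = g2, pair = paste0(g1, ">", g2))
}
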