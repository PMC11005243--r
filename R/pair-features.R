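# Relative-expression pair features: f_{x,y}(i) = 1 iff gene x's
# expression strictly exceeds gene y's within sample i, else 0 (ties give
# 0). The encoding depends only on the within-sample ordering of the
# panel genes, which is what makes it robust to per-sample monotone
# distortions and, empirically, to cross-study batch effects.

#' Encode samples as binary relative-expression pair features
#'
#' For each sample `i` and pair `(x, y)` the feature is
#' `1` if `exp_x(i) > exp_y(i)` and `0` otherwise; ties map to 0
#' (strict inequality, no random tie-breaking). The encoding of a sample
#' depends only on that sample's values, so encoding a subset of samples
#' equals subsetting the encoding.
#'
#' @param x An expression table containing every gene named in `pairs`.
#' @param pairs A pair tibble from [enumerate_pairs()] (columns `first`,
#'   `second`, `pair`).
#' @return A tibble with a `sample_id` column and one integer 0/1 column
#'   per pair, named by the pair's `"first>second"` label, in `pairs`
#'   order.
#' @export
encode_pair_features <- function(x, pairs) {
  genes <- union(pairs$first, pairs$second)
  missing <- setdiff(genes, expr_genes(x))
  if (length(missing) > 0) {
    abort(paste0("pair gene(s) absent from expression table: ",
                 paste(missing, collapse = ", ")))
  }
  m <- expr_values(x)
  f <- t((m[pairs$first, , drop = FALSE] >
            m[pairs$second, , drop = FALSE]) * 1L)
  colnames(f) <- pairs$pair
  bind_cols(tibble(sample_id = rownames(f)),
            as_tibble(f, .name_repair = "minimal"))
}

#' Verify the complement identity of a pair-feature encoding
#'
#' Checks, for every sample and pair, that the stored indicator equals a
#' fresh evaluation and that the two orientations are complementary:
#' `f_{x,y} + f_{y,x} = 1` when the two expressions differ and both are 0
#' on an exact tie.
#'
#' @param features A pair-feature tibble produced by
#'   [encode_pair_features()] from `x`.
#' @param x The expression table the features were encoded from.
#' @return `TRUE` if every cell satisfies the identity, else `FALSE`.
#' @export
complement_check <- function(features, x) {
  pair_names <- setdiff(names(features), "sample_id")
  split_at <- regexpr(">", pair_names, fixed = TRUE)
  pairs <- tibble(
    first = substr(pair_names, 1, split_at - 1),
    second = substr(pair_names, split_at + 1, nchar(pair_names)),
    pair = pair_names
  )
  m <- expr_values(x)[, features$sample_id, drop = FALSE]
  fwd <- t((m[pairs$first, , drop = FALSE] >
              m[pairs$second, , drop = FALSE]) * 1L)
  rev <- t((m[pairs$second, , drop = FALSE] >
              m[pairs$first, , drop = FALSE]) * 1L)
  stored <- as.matrix(features[pair_names])
  ties <- t(m[pairs$first, , drop = FALSE] == m[pairs$second, , drop = FALSE])
  all(stored == fwd) &&
    all((fwd + rev)[!ties] == 1) &&
    all(fwd[ties] == 0) && all(rev[ties] == 0)
}

#' Write a pair-feature matrix to TSV
#'
#' Samples in rows, pair names in the header.
#'
#' @param features A pair-feature tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pair_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}
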