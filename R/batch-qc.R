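# Batch-structure QC for merged datasets. Two complementary views:
# agglomerative clustering of samples (do batches form their own
# clusters?) and a k-nearest-neighbour batch-mixing score normalized so
# that random mixing scores ~1 and perfect batch separation scores 0.

#' Hierarchically cluster samples
#'
#' Agglomerative clustering of samples on a real-valued (Euclidean) or
#' binary (Hamming, i.e. mean mismatch) feature matrix. Deterministic
#' given the input: `stats::hclust` with the stated linkage, distance ties
#' broken by stable sample order.
#'
#' @param features A tibble with a `sample_id` column and numeric feature
#'   columns (e.g. log2(TPM+1) genes or pair features), or a numeric
#'   matrix with sample rownames.
#' @param distance `"euclidean"` for real-valued features or `"hamming"`
#'   for binary features (values must be 0/1).
#' @param linkage Agglomeration rule passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return A list of class `sample_clustering` holding the `hclust` tree
#'   and the sample ids in input order.
#' @export
cluster_samples <- function(features, distance = c("euclidean", "hamming"),
                            linkage = "complete") {
  distance <- match.arg(distance)
  m <- as_feature_matrix(features)
  if (nrow(m) < 2) abort("need at least 2 samples to cluster")
  if (distance == "hamming") {
    if (!all(m %in% c(0, 1))) {
      abort("hamming distance requires binary 0/1 features")
    }
    d <- dist(m, method = "manhattan") / ncol(m)
  } else {
    d <- dist(m, method = "euclidean")
  }
  structure(
    list(hclust = hclust(d, method = linkage), distance = distance,
         linkage = linkage, sample_ids = rownames(m)),
    class = "sample_clustering"
  )
}

#' Per-batch purity at a dendrogram cut
#'
#' Cuts the tree into `k` clusters and reports, for each batch, the
#' average over that batch's samples of the fraction of their cluster
#' belonging to the batch: `purity_b = sum_c (n_bc / n_b) * (n_bc / n_c)`.
#' Purity 1 means the batch occupies cluster(s) of its own (batch
#' separation); under good mixing each batch's purity falls towards its
#' overall frequency.
#'
#' @param clustering A [cluster_samples()] result.
#' @param batch Batch/study label per sample, aligned with the clustering
#'   input order.
#' @param k Number of clusters to cut into (typically the number of
#'   batches).
#' @return A tibble with columns `batch` and `purity`.
#' @export
batch_purity <- function(clustering, batch, k) {
  stopifnot(inherits(clustering, "sample_clustering"))
  batch <- as.character(batch)
  if (length(batch) != length(clustering$sample_ids)) {
    abort("batch labels must align with clustered samples")
  }
  cl <- cutree(clustering$hclust, k = k)
  tab <- table(batch, cl)
  n_c <- colSums(tab)
  purrr::map_dfr(rownames(tab), function(b) {
    n_bc <- tab[b, ]
    tibble(batch = b,
           purity = sum((n_bc / sum(n_bc)) * (n_bc / n_c)))
  })
}

#' Nearest-neighbour batch-mixing score
#'
#' For each sample, the fraction of its `k` nearest neighbours (Euclidean)
#' sharing its batch is computed; the mean fraction is rescaled against
#' its expectation under random mixing so that the score is ~1 when
#' batches are intermixed and 0 when they are perfectly separated:
#' `score = (1 - observed) / (1 - expected)`, clamped to `[0, 1]`, where
#' `expected = sum_b (n_b / n) * (n_b - 1) / (n - 1)`.
#'
#' @inheritParams cluster_samples
#' @param batch Batch label per sample (>= 2 distinct values).
#' @param k Number of nearest neighbours (default 15; must be < number of
#'   samples).
#' @return A single number in `[0, 1]`.
#' @export
batch_mixing_score <- function(features, batch, k = 15) {
  m <- as_feature_matrix(features)
  n <- nrow(m)
  batch <- as.character(batch)
  if (length(batch) != n) abort("batch labels must align with samples")
  if (length(unique(batch)) < 2) abort("need at least 2 batches")
  if (k >= n) abort("k must be smaller than the number of samples")
  d <- as.matrix(dist(m))
  same <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, -i])            # ties broken by stable index order
    nn <- seq_len(n)[-i][ord[seq_len(k)]]
    mean(batch[nn] == batch[i])
  }, numeric(1))
  observed <- mean(same)
  nb <- table(batch)
  expected <- sum((nb / n) * (nb - 1) / (n - 1))
  min(max((1 - observed) / (1 - expected), 0), 1)
}

#' Per-batch location-scale standardization of expression
#'
#' A deliberately simple batch-adjustment baseline: per gene, values are
#' log2(TPM+1)-transformed, centred and scaled within each batch, then
#' mapped back onto the gene's global mean and standard deviation before
#' back-transforming to the linear scale. This is a location-scale
#' stand-in for ComBat-style adjustment without empirical-Bayes shrinkage;
#' unlike pair features, it does **not** preserve the within-sample
#' ordering of genes, which is exactly why rank-based features are the
#' preferred route for cross-study modelling.
#'
#' @param x An expression table (TPM scale).
#' @param batch Batch label per sample; every batch needs >= 2 samples.
#' @return An expression table with unit `"normalized"` (columns no longer
#'   sum to 1e6).
#' @export
batch_standardize <- function(x, batch) {
  m <- expr_values(x)
  batch <- as.character(batch)
  if (length(batch) != ncol(m)) abort("batch labels must align with samples")
  nb <- table(batch)
  if (any(nb < 2)) {
    abort(paste0("batch(es) with < 2 samples: ",
                 paste(names(nb)[nb < 2], collapse = ", ")))
  }
  lg <- log2(m + 1)
  # population moments so that identical batches map exactly onto the
  # global profile (n-1 denominators would not cancel across group sizes)
  row_psd <- function(x) sqrt(rowMeans((x - rowMeans(x))^2))
  gmean <- rowMeans(lg)
  gsd <- row_psd(lg)
  out <- lg
  for (b in unique(batch)) {
    cols <- which(batch == b)
    bm <- rowMeans(lg[, cols, drop = FALSE])
    bs <- pmax(row_psd(lg[, cols, drop = FALSE]), 1e-8)  # variance floor
    z <- (lg[, cols, drop = FALSE] - bm) / bs
    out[, cols] <- z * gsd + gmean
  }
  expression_from_matrix(pmax(2^out - 1, 0), "normalized")
}

#' Assess residual batch structure of a feature matrix
#'
#' Convenience wrapper combining [cluster_samples()], [batch_purity()] at
#' `k = ` number of batches, and [batch_mixing_score()].
#'
#' @inheritParams batch_mixing_score
#' @inheritParams cluster_samples
#' @param k_neighbors Neighbourhood size for the mixing score.
#' @return A list of class `batch_assessment` with `mixing_score`,
#'   `purity` (tibble) and `clustering`.
#' @export
assess_batch <- function(features, batch,
                         distance = c("euclidean", "hamming"),
                         linkage = "complete", k_neighbors = 15) {
  clustering <- cluster_samples(features, distance = distance,
                                linkage = linkage)
  purity <- batch_purity(clustering, batch, k = length(unique(batch)))
  structure(
    list(mixing_score = batch_mixing_score(features, batch, k = k_neighbors),
         purity = purity, clustering = clustering),
    class = "batch_assessment"
  )
}

#' @export
print.batch_assessment <- function(x, ...) {
  cat(sprintf("<batch_assessment: mixing score %.3f>\n", x$mixing_score))
  print(x$purity)
  invisible(x)
}

#' @rdname assess_batch
#' @param x A `batch_assessment`.
#' @param ... Unused.
#' @method tidy batch_assessment
#' @export
tidy.batch_assessment <- function(x, ...) x$purity

#' @rdname assess_batch
#' @method glance batch_assessment
#' @export
glance.batch_assessment <- function(x, ...) {
  tibble(mixing_score = x$mixing_score,
         mean_purity = mean(x$purity$purity),
         n_batches = nrow(x$purity))
}

#' @rdname assess_batch
#' @param object A `batch_assessment`.
#' @method autoplot batch_assessment
#' @export
autoplot.batch_assessment <- function(object, ...) {
  ggplot2::ggplot(object$purity,
                  ggplot2::aes(x = .data$batch, y = .data$purity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mixing_score, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "per-batch cluster purity", x = NULL,
                  title = sprintf("batch mixing score %.2f (dashed)",
                                  object$mixing_score)) +
    ggplot2::theme_minimal()
}

# features: tibble with sample_id column, or matrix with rownames
as_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    if (is.null(rownames(features))) {
      rownames(features) <- paste0("s", seq_len(nrow(features)))
    }
    return(features)
  }
  features <- as_tibble(features)
  if (!"sample_id" %in% names(features)) {
    abort("features must be a matrix or a tibble with a sample_id column")
  }
  m <- as.matrix(features[setdiff(names(features), "sample_id")])
  rownames(m) <- features$sample_id
  m
}
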