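# Repeated stratified k-fold cross-validation. Each replicate draws a
# fresh stratified partition; within a replicate each fold's model is
# trained on the remaining folds and scores the held-out fold. AUC is
# computed per replicate from the pooled out-of-fold scores and then
# averaged across replicates; all fold fits are retained so that
# per-feature selection probabilities can be profiled afterwards.

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that within each class the
#' fold sizes differ by at most one sample, which keeps per-fold class
#' proportions within one sample of the global proportions.
#'
#' @param y Binary labels (any encoding accepted by the package).
#' @param k Number of folds (each class must have >= k members).
#' @return An integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k) {
  y <- as_binary_labels(y)
  if (k < 2) abort("need at least 2 folds")
  if (min(table(y)) < k) abort("each class needs at least k samples")
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified cross-validated evaluation
#'
#' Runs `replicates` independent rounds of stratified `folds`-fold
#' cross-validation of one classifier family. When a class has fewer
#' members than `folds`, the fold count automatically falls back to the
#' minority-class count (minimum 2) with a warning -- small cohorts are
#' evaluated at the largest feasible resolution rather than rejected.
#' The entire procedure is a deterministic function of
#' `(data, method, folds, replicates, seed)`.
#'
#' @inheritParams fit_and_select
#' @param folds Requested number of folds (default 10).
#' @param replicates Number of independent cross-validation rounds
#'   (default 10).
#' @param seed Integer seed governing every partition and every model fit.
#' @param fpr_grid Fixed false-positive-rate grid for the vertically
#'   averaged mean ROC curve (default 101 points on `[0, 1]`).
#' @return A list of class `icb_cv` with `mean_auc`, `per_replicate`
#'   (tibble of replicate AUCs), `mean_roc` (tibble `fpr`, `tpr`),
#'   `fold_results` (tibble with one row per fold fit: replicate, fold,
#'   held-out ids/scores, selected features, fold AUC) and bookkeeping
#'   fields. Use [tidy()], [glance()], [autoplot()] and
#'   [selection_profile()] on it.
#' @export
cross_validate <- function(features, labels, method = icb_methods,
                           folds = 10, replicates = 10, seed = 1,
                           hyperparameters = list(),
                           fpr_grid = seq(0, 1, length.out = 101)) {
  method <- match.arg(method)
  X <- as_feature_matrix(features)
  y <- as_binary_labels(labels)
  if (length(y) != nrow(X)) abort("labels must align with samples")
  if (length(unique(y)) < 2) abort("both classes must be present")
  if (folds < 2) abort("need at least 2 folds")
  k <- min(folds, min(table(y)))
  if (k < 2) abort("minority class too small for cross-validation")
  if (k < folds) {
    warn(sprintf(
      "minority class (%d) smaller than %d folds; using %d-fold CV",
      min(table(y)), folds, k))
  }

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)

  fold_rows <- list()
  rep_auc <- numeric(replicates)
  roc_grid <- matrix(NA_real_, nrow = replicates, ncol = length(fpr_grid))
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    fold <- stratified_folds(y, k)
    pooled_scores <- numeric(length(y))
    for (f in seq_len(k)) {
      test <- which(fold == f)
      fit <- fit_and_select(X[-test, , drop = FALSE], y[-test],
                            method = method,
                            hyperparameters = hyperparameters)
      sc <- predict_scores(fit, X[test, , drop = FALSE])
      pooled_scores[test] <- sc
      fold_rows[[length(fold_rows) + 1]] <- tibble(
        replicate = r, fold = f,
        test_sample_ids = list(rownames(X)[test]),
        scores = list(unname(sc)),
        selected = list(fit$selected),
        auc = if (length(unique(y[test])) == 2) auc(sc, y[test]) else NA_real_
      )
    }
    rep_auc[r] <- auc(pooled_scores, y)
    roc_grid[r, ] <- interp_roc(roc_points(pooled_scores, y), fpr_grid)
  }

  structure(list(
    method = method,
    folds = k, folds_requested = folds, replicates = replicates,
    seed = seed,
    per_replicate = tibble(replicate = seq_len(replicates), auc = rep_auc),
    mean_auc = mean(rep_auc),
    mean_roc = tibble(fpr = fpr_grid, tpr = colMeans(roc_grid)),
    fold_results = bind_rows(fold_rows),
    feature_names = colnames(X),
    n_samples = length(y)
  ), class = "icb_cv")
}

#' @export
print.icb_cv <- function(x, ...) {
  cat(sprintf(
    "<icb_cv %s: %d-fold x %d replicates on %d samples, mean AUC %.3f>\n",
    x$method, x$folds, x$replicates, x$n_samples, x$mean_auc))
  invisible(x)
}

#' @rdname cross_validate
#' @param x,object An `icb_cv` object.
#' @param ... Unused.
#' @method tidy icb_cv
#' @export
tidy.icb_cv <- function(x, ...) x$per_replicate

#' @rdname cross_validate
#' @method glance icb_cv
#' @export
glance.icb_cv <- function(x, ...) {
  tibble(method = x$method, mean_auc = x$mean_auc,
         sd_auc = sd(x$per_replicate$auc), folds = x$folds,
         replicates = x$replicates, n_samples = x$n_samples)
}

#' @rdname cross_validate
#' @method autoplot icb_cv
#' @export
autoplot.icb_cv <- function(object, ...) {
  ggplot2::ggplot(object$mean_roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s: mean AUC %.3f (%d x %d-fold CV)",
                                  object$method, object$mean_auc,
                                  object$replicates, object$folds)) +
    ggplot2::theme_minimal()
}

#' Per-feature selection probabilities from cross-validation fits
#'
#' The selection probability of a feature under a method is the fraction
#' of all cross-validation model fits (`folds x replicates`) in which the
#' method's own selection rule included the feature. Features that were
#' offered but never selected have probability exactly 0.
#'
#' @param cv An `icb_cv` object or a (optionally named) list of them,
#'   e.g. one per method.
#' @return A tibble with columns `method`, `feature`, `probability`,
#'   covering every offered feature.
#' @export
selection_profile <- function(cv) {
  if (inherits(cv, "icb_cv")) cv <- list(cv)
  purrr::map_dfr(cv, function(x) {
    stopifnot(inherits(x, "icb_cv"))
    n_fits <- nrow(x$fold_results)
    counts <- table(factor(unlist(x$fold_results$selected),
                           levels = x$feature_names))
    tibble(method = x$method, feature = x$feature_names,
           probability = as.numeric(counts) / n_fits)
  })
}

#' Filter a selection profile for reporting
#'
#' Keeps features whose selection probability reaches `min_probability`
#' in at least one method (the convention used for selection heatmaps; a
#' feature at exactly the threshold is kept).
#'
#' @param profile A tibble from [selection_profile()].
#' @param min_probability Reporting threshold (default 0.2).
#' @return The filtered profile tibble.
#' @export
filter_selection <- function(profile, min_probability = 0.2) {
  keep <- profile |>
    summarise(max_p = max(.data$probability), .by = "feature") |>
    filter(.data$max_p >= min_probability)
  filter(profile, .data$feature %in% keep$feature)
}

#' Cross-method consistency of feature selection
#'
#' Spearman rank correlation (tie-corrected midranks) of per-feature
#' selection probabilities between every pair of methods. A method whose
#' profile is constant has no rank ordering; its correlations are
#' reported as `NA` with a warning.
#'
#' @param profile A tibble from [selection_profile()] covering >= 2
#'   methods over a common feature list.
#' @return A symmetric correlation matrix (methods x methods, unit
#'   diagonal).
#' @export
selection_consistency <- function(profile) {
  wide <- profile |>
    pivot_wider(id_cols = "feature", names_from = "method",
                values_from = "probability")
  m <- as.matrix(wide[-1])
  if (anyNA(m)) abort("profiles must cover the same feature list")
  if (ncol(m) < 2) abort("need profiles from at least 2 methods")
  flat <- apply(m, 2, function(v) length(unique(v)) == 1)
  if (any(flat)) {
    warn(paste0("constant selection profile(s), correlation undefined: ",
                paste(colnames(m)[flat], collapse = ", ")))
  }
  out <- suppressWarnings(cor(m, method = "spearman"))
  diag(out) <- 1
  out
}

#' Heatmap of selection probabilities across methods
#'
#' @param profile A tibble from [selection_profile()], typically after
#'   [filter_selection()].
#' @return A ggplot object (features x methods tile plot).
#' @export
plot_selection_profile <- function(profile) {
  ord <- profile |>
    summarise(p = mean(.data$probability), .by = "feature") |>
    arrange(.data$p)
  profile |>
    mutate(feature = factor(.data$feature, levels = ord$feature)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$method, y = .data$feature,
                                 fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "selection\nprobability") +
    ggplot2::theme_minimal()
}
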