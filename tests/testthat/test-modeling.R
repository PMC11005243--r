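# Classifier fits, selection semantics and the cross-validation engine.

test_that("a perfectly separating feature is selected by every method", {
  set.seed(601)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(winner = y,                       # deterministic given class
             matrix(rbinom(n * 10, 1, 0.5), n,
                    dimnames = list(NULL, paste0("noise", 1:10))))
  rownames(X) <- paste0("s", 1:n)
  for (m in c("random_forest", "lasso_logistic", "xgboost")) {
    fit <- fit_and_select(X, y, method = m, seed = 1)
    expect_true("winner" %in% fit$selected, label = m)
    sc <- predict_scores(fit, X)
    expect_gt(auc(sc, y), 0.99)
  }
  # tree methods rank the planted feature first
  rf <- fit_and_select(X, y, method = "random_forest", seed = 1)
  expect_identical(names(which.max(rf$importance)), "winner")
  xg <- fit_and_select(X, y, method = "xgboost", seed = 1)
  expect_identical(xg$importance$Feature[1], "winner")
})

test_that("lasso under pure noise may shrink to an intercept-only model", {
  set.seed(602)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  fit <- fit_and_select(X, y, method = "lasso_logistic",
                        hyperparameters = list(lambda_rule = "1se"),
                        seed = 4)
  # heavy penalty: few-to-no features; scoring still works
  expect_lte(length(fit$selected), 2)
  expect_length(predict_scores(fit, X), n)
})

test_that("fit_and_select validates degenerate inputs", {
  X <- matrix(rnorm(20), 10, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_and_select(X, rep(1, 10), method = "random_forest"),
               "both classes")
  expect_error(fit_and_select(X[, 0], rep(c(0, 1), 5), "random_forest"),
               "empty feature")
})

test_that("stratified folds keep class balance within one sample", {
  set.seed(603)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    y <- rbinom(n, 1, runif(1, 0.25, 0.6))
    k <- sample(2:8, 1)
    if (min(table(y)) < k) next
    fold <- stratified_folds(y, k)
    expect_setequal(unique(fold), 1:k)
    global <- mean(y)
    for (f in 1:k) {
      idx <- fold == f
      expect_lte(abs(sum(y[idx]) - global * sum(idx)), 1)
    }
  }
  expect_error(stratified_folds(c(0, 1, 1, 1), 3), "at least k")
})

test_that("cross-validation is deterministic and falls back on small classes", {
  set.seed(604)
  sim <- small_sim()
  merged <- merge_studies(sim$studies)
  f <- encode_pair_features(merged$expression,
                            enumerate_pairs(checkpoint_panel()))
  y <- merged$metadata$label
  cv1 <- suppressWarnings(
    cross_validate(f, y, "lasso_logistic", folds = 3, replicates = 2,
                   seed = 11))
  cv2 <- suppressWarnings(
    cross_validate(f, y, "lasso_logistic", folds = 3, replicates = 2,
                   seed = 11))
  expect_identical(cv1$per_replicate, cv2$per_replicate)
  expect_identical(cv1$fold_results$selected, cv2$fold_results$selected)
  expect_equal(cv1$mean_auc, mean(cv1$per_replicate$auc))
  expect_true(all(cv1$per_replicate$auc >= 0 & cv1$per_replicate$auc <= 1))

  # minority class smaller than requested folds -> documented fallback
  expect_warning(
    cvf <- cross_validate(f, y, "xgboost", folds = 50, replicates = 1,
                          seed = 1),
    "folds")
  expect_equal(cvf$folds, unname(min(table(y))))

  # deterministic data: every fold model perfect regardless of seed
  n <- 40
  yy <- rep(c(0, 1), each = n / 2)
  X <- cbind(w = yy, matrix(rbinom(n * 3, 1, 0.5), n,
                            dimnames = list(NULL, paste0("z", 1:3))))
  rownames(X) <- paste0("s", 1:n)
  for (s in c(5, 6)) {
    cvp <- cross_validate(X, yy, "lasso_logistic", folds = 4,
                          replicates = 2, seed = s)
    expect_equal(cvp$mean_auc, 1)
  }
})

test_that("selection probabilities count fits and respect the report filter", {
  fr <- tibble::tibble(
    replicate = rep(1:2, each = 2), fold = rep(1:2, 2),
    test_sample_ids = list("a", "b", "c", "d"),
    scores = list(1, 1, 1, 1),
    selected = list(c("f1", "f2"), "f1", "f1", character(0)),
    auc = 1)
  cv <- structure(list(method = "random_forest", fold_results = fr,
                       feature_names = c("f1", "f2", "f3")),
                  class = "icb_cv")
  prof <- selection_profile(cv)
  expect_equal(prof$probability[prof$feature == "f1"], 0.75)
  expect_equal(prof$probability[prof$feature == "f2"], 0.25)
  expect_equal(prof$probability[prof$feature == "f3"], 0)   # never offered up

  # filter keeps a feature at exactly the threshold
  kept <- filter_selection(prof, min_probability = 0.25)
  expect_setequal(unique(kept$feature), c("f1", "f2"))
  kept2 <- filter_selection(prof, min_probability = 0.2)
  expect_setequal(unique(kept2$feature), c("f1", "f2"))
})

test_that("selection consistency reproduces hand-computed rank correlations", {
  prof <- tibble::tibble(
    method = rep(c("a", "b"), each = 3),
    feature = rep(c("x", "y", "z"), 2),
    probability = c(0.1, 0.4, 0.9, 0.2, 0.3, 0.8))
  m <- selection_consistency(prof)
  expect_equal(m["a", "b"], 1)                 # identical rank vectors
  expect_equal(diag(m), c(a = 1, b = 1))

  rev <- prof
  rev$probability[4:6] <- c(0.9, 0.4, 0.1)
  expect_equal(selection_consistency(rev)["a", "b"], -1)

  flat <- prof
  flat$probability[4:6] <- 0.5
  expect_warning(mf <- selection_consistency(flat), "constant")
  expect_true(is.na(mf["a", "b"]))
})

test_that("selection probabilities are invariant to feature column order", {
  set.seed(605)
  sim <- small_sim()
  merged <- merge_studies(sim$studies)
  f <- encode_pair_features(merged$expression,
                            enumerate_pairs(checkpoint_panel()))
  y <- merged$metadata$label
  cv_a <- suppressWarnings(
    cross_validate(f, y, "lasso_logistic", folds = 3, replicates = 1,
                   seed = 9))
  perm <- c("sample_id", sample(setdiff(names(f), "sample_id")))
  cv_b <- suppressWarnings(
    cross_validate(f[perm], y, "lasso_logistic", folds = 3,
                   replicates = 1, seed = 9))
  pa <- selection_profile(cv_a) |> dplyr::arrange(feature)
  pb <- selection_profile(cv_b) |> dplyr::arrange(feature)
  expect_equal(pa, pb)
})
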