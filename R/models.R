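# The three classifier families and their selected-feature semantics:
#   lasso_logistic -- glmnet binomial lasso; regularization strength from
#     inner cross-validation; selected = non-zero coefficients.
#   random_forest  -- randomForest; selected = features whose Gini
#     importance exceeds the mean importance over offered features.
#   xgboost        -- gradient-boosted trees; selected = features used in
#     at least one split (non-zero gain).
# Every fit exposes a real-valued response-probability score per sample.

icb_methods <- c("random_forest", "lasso_logistic", "xgboost")

default_hyperparameters <- function(method) {
  switch(method,
    random_forest = list(ntree = 500, mtry = NULL),   # NULL -> floor(sqrt(p))
    lasso_logistic = list(lambda_rule = "min", inner_folds = 5),
    xgboost = list(nrounds = 100, max_depth = 3, eta = 0.1)
  )
}

#' Fit one classifier and extract its selected features
#'
#' Trains a single model of the requested family on a samples-by-features
#' matrix with a binary outcome and returns the fit together with the
#' features the method itself selected (see the per-method semantics in
#' the Details).
#'
#' @details
#' * `lasso_logistic`: binomial lasso via [glmnet::cv.glmnet()]; the
#'   regularization strength is chosen by inner cross-validation
#'   (`inner_folds`, default 5) at the deviance minimum
#'   (`lambda_rule = "min"`) or the one-standard-error rule (`"1se"`).
#'   Selected features are those with non-zero coefficients; full
#'   shrinkage to an intercept-only model is permitted.
#' * `random_forest`: features are ranked by Gini importance
#'   (mean decrease in node impurity); selected features are those whose
#'   importance exceeds the mean importance over all offered features.
#' * `xgboost`: features appearing in at least one split (non-zero gain).
#'
#' @param features A tibble with a `sample_id` column and numeric feature
#'   columns, or a numeric matrix with column names.
#' @param labels Binary outcome per sample
#'   (`"response"`/`"non-response"`, logical or 0/1).
#' @param method One of `"random_forest"`, `"lasso_logistic"`,
#'   `"xgboost"`.
#' @param hyperparameters Named list overriding the method defaults
#'   (RF: `ntree` 500, `mtry` sqrt(p); lasso: `lambda_rule` "min",
#'   `inner_folds` 5; xgboost: `nrounds` 100, `max_depth` 3, `eta` 0.1).
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   before fitting so the fit is reproducible in isolation.
#' @return A list of class `icb_fit` with elements `method`, `model`,
#'   `selected` (character vector of feature names) and `feature_names`.
#' @export
fit_and_select <- function(features, labels, method = icb_methods,
                           hyperparameters = list(), seed = NULL) {
  method <- match.arg(method)
  X <- as_feature_matrix(features)
  if (ncol(X) == 0) abort("empty feature matrix")
  if (is.null(colnames(X))) abort("feature matrix must have column names")
  y <- as_binary_labels(labels)
  if (length(y) != nrow(X)) abort("labels must align with samples")
  if (length(unique(y)) < 2) abort("both classes must be present in labels")
  if (!is.null(seed)) set.seed(seed)
  hp <- modifyList(default_hyperparameters(method), hyperparameters)

  fit <- switch(method,
    lasso_logistic = fit_lasso(X, y, hp),
    random_forest = fit_rf(X, y, hp),
    xgboost = fit_xgb(X, y, hp)
  )
  structure(c(fit, list(method = method, feature_names = colnames(X))),
            class = "icb_fit")
}

fit_lasso <- function(X, y, hp) {
  Xg <- X
  padded <- FALSE
  if (ncol(Xg) < 2) {                    # glmnet needs >= 2 columns
    Xg <- cbind(Xg, `..pad..` = 0)
    padded <- TRUE
  }
  nf <- min(hp$inner_folds, min(table(y)))
  if (nf < 2) abort("lasso inner cross-validation needs >= 2 of each class")
  # stratified inner folds: unstratified ones can lose a class entirely
  foldid <- stratified_folds(y, nf)
  cv <- glmnet::cv.glmnet(Xg, y, family = "binomial", foldid = foldid,
                          type.measure = "deviance")
  lam <- if (identical(hp$lambda_rule, "1se")) cv$lambda.1se else cv$lambda.min
  cf <- coef(cv, s = lam)[-1, 1]
  selected <- names(cf)[cf != 0]
  if (padded) selected <- setdiff(selected, "..pad..")
  list(model = cv, lambda = lam, selected = selected, padded = padded)
}

fit_rf <- function(X, y, hp) {
  mtry <- hp$mtry %||% max(1, floor(sqrt(ncol(X))))
  model <- randomForest::randomForest(
    x = X, y = factor(y, levels = c(0, 1)),
    ntree = hp$ntree, mtry = mtry)
  imp <- model$importance[, "MeanDecreaseGini"]
  list(model = model, importance = imp,
       selected = names(imp)[imp > mean(imp)])
}

fit_xgb <- function(X, y, hp) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  model <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                  eta = hp$eta, nthread = 1),
    data = dtrain, nrounds = hp$nrounds, verbose = 0)
  imp <- tryCatch(
    xgboost::xgb.importance(feature_names = colnames(X), model = model),
    error = function(e) NULL)
  list(model = model, importance = imp,
       selected = if (is.null(imp)) character(0) else imp$Feature)
}

#' Predicted response probabilities from a fitted model
#'
#' @param fit An `icb_fit` from [fit_and_select()].
#' @param features New samples in the same feature space (tibble with
#'   `sample_id` or matrix).
#' @return A named numeric vector of response probabilities.
#' @export
predict_scores <- function(fit, features) {
  stopifnot(inherits(fit, "icb_fit"))
  X <- as_feature_matrix(features)
  X <- X[, fit$feature_names, drop = FALSE]
  scores <- switch(fit$method,
    lasso_logistic = {
      Xg <- if (isTRUE(fit$padded)) cbind(X, `..pad..` = 0) else X
      as.numeric(predict(fit$model, newx = Xg, s = fit$lambda,
                         type = "response"))
    },
    random_forest =
      as.numeric(predict(fit$model, X, type = "prob")[, "1"]),
    xgboost = as.numeric(predict(fit$model, xgboost::xgb.DMatrix(X)))
  )
  setNames(scores, rownames(X))
}

#' @export
print.icb_fit <- function(x, ...) {
  cat(sprintf("<icb_fit %s: %d/%d features selected>\n", x$method,
              length(x$selected), length(x$feature_names)))
  invisible(x)
}
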