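# ROC/AUC, authored with a built-in cross-check: the trapezoidal area
# under the tie-grouped ROC staircase must equal the tie-corrected
# Mann-Whitney concordance probability to 1e-12, or auc() refuses to
# return a value. Labels are "response"/"non-response", logical, factor
# or 0/1; the positive class is response/1.

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("response", "non-response"))
    if (length(bad) > 0) {
      abort(paste0("labels must be response/non-response, got: ",
                   paste(bad, collapse = ", ")))
    }
    return(as.integer(labels == "response"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (!all(labels %in% c(0, 1))) abort("labels must be binary")
  as.integer(labels)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the distinct score values (tied
#' scores grouped) and returns the (FPR, TPR) staircase from (0, 0) to
#' (1, 1).
#'
#' @param scores Real-valued classifier scores, larger = more
#'   response-like.
#' @param labels Binary outcome per score (`"response"`/`"non-response"`,
#'   logical or 0/1).
#' @return A tibble with columns `fpr` and `tpr`, monotone non-decreasing.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) abort("scores and labels must align")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  last <- cumsum(rle(s)$lengths)        # last index of each tied group
  tibble(
    fpr = c(0, cumsum(y == 0)[last] / n0),
    tpr = c(0, cumsum(y == 1)[last] / n1)
  )
}

#' Area under the ROC curve
#'
#' Computed two independent ways -- trapezoidal integration of
#' [roc_points()] and the tie-corrected Mann-Whitney concordance
#' (probability that a random responder outscores a random non-responder,
#' ties counting one half) -- which must agree to `1e-12`.
#'
#' @inheritParams roc_points
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  roc <- roc_points(scores, y)
  n <- nrow(roc)
  trap <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)                     # midranks handle ties
  mw <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (abs(trap - mw) > 1e-12) {
    abort(sprintf("internal AUC cross-check failed (%.15f vs %.15f)",
                  trap, mw))
  }
  trap
}

# vertical interpolation of a staircase ROC onto a fixed FPR grid
interp_roc <- function(roc, grid) {
  approx(roc$fpr, roc$tpr, xout = grid, method = "linear",
         ties = max, rule = 2)$y
}
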