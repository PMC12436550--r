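#' Gaze-regression error metrics (1/(2n) convention)
#'
#' Computes RMSE and MAE over `n` predicted gaze points using the convention
#' that both coordinates of every point contribute as separate scalar
#' residuals, i.e. the normalizer is `2n`:
#' \deqn{MSE = \frac{1}{2n}\sum_i (x_i-\hat x_i)^2 + (y_i-\hat y_i)^2,\quad
#'       RMSE = \sqrt{MSE},}
#' \deqn{MAE = \frac{1}{2n}\sum_i |x_i-\hat x_i| + |y_i-\hat y_i|.}
#'
#' @param truth `n x 2` matrix of ground-truth gaze points.
#' @param pred `n x 2` matrix of predicted gaze points.
#' @return List with elements `rmse`, `mae`, `mse`, `n`.
#' @export
evaluate_regression <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (nrow(truth) == 0L) stop("need at least one gaze point")
  if (!all(dim(truth) == dim(pred)) || ncol(truth) != 2L)
    stop("truth and pred must both be n x 2 matrices")
  r <- truth - pred
  n <- nrow(truth)
  mse <- sum(r^2) / (2 * n)
  list(rmse = sqrt(mse), mae = sum(abs(r)) / (2 * n), mse = mse, n = n)
}

#' Fixation-classification metrics
#'
#' Accuracy at a probability threshold and AUC by the rank (Mann-Whitney)
#' statistic. A probability exactly at the threshold is counted as class 0
#' (the tie-break is `prob > threshold`). AUC requires both classes to be
#' present; a single-class truth vector is an explicit error.
#'
#' @param truth Length-`n` vector of flags in `{0, 1}`.
#' @param prob Length-`n` vector of predicted probabilities in `[0, 1]`.
#' @param threshold Decision threshold for accuracy (default 0.5).
#' @return List with elements `accuracy`, `auc`, `n`.
#' @export
evaluate_classification <- function(truth, prob, threshold = 0.5) {
  if (length(truth) == 0L) stop("need at least one instance")
  if (length(truth) != length(prob)) stop("truth and prob lengths differ")
  if (!all(truth %in% c(0, 1))) stop("truth must be flags in {0, 1}")
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  acc <- mean((prob > threshold) == (truth == 1))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: truth contains a single class")
  r <- rank(prob)  # midranks: ties contribute 1/2, the Mann-Whitney value
  auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(accuracy = acc, auc = auc, n = length(truth))
}
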