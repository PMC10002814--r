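# Shared internal helpers: seed fan-out, empirical ROC machinery, classification
# metrics used by the selection, stratification and JMI stages.

# Deterministic fan-out of one master seed into per-stage / per-repeat seeds.
# Linear-congruential step on the Lehmer modulus; stays inside 32-bit range.
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(master) * 48271 + offset * 16807) %% 2147483629 + 1)
}

stop_if_not_binary <- function(labels) {
  if (length(unique(labels)) != 2L)
    stop("labels must contain exactly two classes", call. = FALSE)
  invisible(TRUE)
}

# Empirical ROC curve over the distinct observed scores. `positive` scores are
# assumed larger under direction ">" (greater-is-positive).
roc_points <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  y <- as_binary(labels, positive)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  # collapse ties on score so tied positives/negatives move together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  P <- sum(y); N <- length(y) - P
  data.frame(
    threshold = s[last],
    tpr = tp[last] / P,
    fpr = fp[last] / N
  )
}

# Trapezoidal AUC over the empirical ROC; with tied scores this equals the
# Mann-Whitney U statistic with half credit for ties.
auc_trapezoid <- function(scores, labels, positive = NULL) {
  rc <- roc_points(scores, labels, positive)
  fpr <- c(0, rc$fpr); tpr <- c(0, rc$tpr)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Map labels to 0/1. If `positive` is NULL the second sorted level is positive.
# `require_present` guards inputs that must contain the positive class (class
# labels); predictions may legitimately miss it.
as_binary <- function(labels, positive = NULL, require_present = TRUE) {
  lv <- sort(unique(as.character(labels)))
  if (is.null(positive)) positive <- lv[length(lv)]
  if (require_present && !positive %in% lv)
    stop("positive class not present in labels", call. = FALSE)
  as.integer(as.character(labels) == positive)
}

# Accuracy / precision / recall / AUC + confusion matrix for binary problems.
# Precision and recall are reported for the positive class.
classification_metrics <- function(truth, predicted, scores, positive = NULL) {
  yt <- as_binary(truth, positive)
  lv <- sort(unique(as.character(truth)))
  if (is.null(positive)) positive <- lv[length(lv)]
  yp <- as_binary(predicted, positive, require_present = FALSE)
  tp <- sum(yt == 1 & yp == 1); fp <- sum(yt == 0 & yp == 1)
  fn <- sum(yt == 1 & yp == 0); tn <- sum(yt == 0 & yp == 0)
  cm <- matrix(c(tn, fn, fp, tp), 2, 2,
               dimnames = list(truth = c("neg", "pos"),
                               predicted = c("neg", "pos")))
  list(
    accuracy  = (tp + tn) / length(yt),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall    = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    auc       = auc_trapezoid(scores, yt, positive = "1"),
    confusion = cm
  )
}

# Stratified index split: per class, the held-out side receives
# ceiling((1 - fraction) * n_class) subjects; deterministic given seed.
stratified_split <- function(labels, fraction = 0.8, seed = 1L) {
  stop_if_not_binary(labels)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  test <- integer(0)
  for (lv in sort(unique(as.character(labels)))) {
    idx <- which(as.character(labels) == lv)
    n_test <- ceiling((1 - fraction) * length(idx))
    if (n_test < 1L || n_test >= length(idx))
      stop("class '", lv, "' too small to stratify", call. = FALSE)
    test <- c(test, sort(sample(idx, n_test)))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

# Stratified k-fold assignment; returns integer fold id per observation.
stratified_folds <- function(labels, k, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in sort(unique(as.character(labels)))) {
    idx <- which(as.character(labels) == lv)
    if (length(idx) < k)
      stop("class '", lv, "' has fewer members than folds", call. = FALSE)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
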