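#' Stratified train/test split
#'
#' Splits subjects into train and test sets stratified by class label. Per
#' class, the held-out side receives `ceiling((1 - fraction) * n)` subjects
#' (so with 134 per class at `fraction = 0.8` the held-out set has 27 + 27
#' subjects). Deterministic given `seed`.
#'
#' @param labels class labels (two classes).
#' @param fraction training fraction, default 0.8.
#' @param seed RNG seed.
#' @return List with sorted integer vectors `train` and `test` partitioning
#'   `seq_along(labels)`.
#' @export
split_train_test <- function(labels, fraction = 0.8, seed = 1L) {
  stratified_split(labels, fraction, seed)
}

# Linear classifiers used inside RFE. Features are assumed standardized;
# importance is the absolute coefficient. Fixed regularization (SVM C = 1,
# ridge-logistic lambda = 0.01) — no tuning, so nothing can leak from test.
fit_linear_weights <- function(x, y, classifier = c("svm", "logistic")) {
  classifier <- match.arg(classifier)
  yf <- factor(y)
  if (classifier == "svm") {
    fit <- e1071::svm(x, yf, kernel = "linear", cost = 1, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    w <- w[colnames(x)]  # svm may reorder SV columns; align by name
  } else {
    fit <- glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                          lambda = 0.01, standardize = FALSE)
    w <- as.numeric(coef(fit))[-1]
    names(w) <- colnames(x)
  }
  w
}

#' Recursive feature elimination with a linear classifier
#'
#' Iteratively fits a linear classifier (max-margin SVM with linear kernel and
#' C = 1, or L2-regularized logistic regression with fixed penalty), removes
#' the `step` features with the smallest absolute coefficients, and refits,
#' stopping when `stop_size` features remain. Features must already be
#' standardized on the training data. Ties on importance are broken by
#' removing the earlier column.
#'
#' @param x standardized training feature matrix with column names.
#' @param y binary labels.
#' @param classifier `"svm"` or `"logistic"`.
#' @param stop_size number of features to retain (default 14).
#' @param step features removed per iteration (default 1).
#' @return List with `selected` (column names, input order), `elimination`
#'   (names in removal order, weakest first) and `classifier`.
#' @export
rfe <- function(x, y, classifier = c("svm", "logistic"), stop_size = 14L,
                step = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (stop_size >= ncol(x)) {
    if (stop_size > ncol(x)) stop("stop_size exceeds number of features", call. = FALSE)
    return(list(selected = colnames(x), elimination = character(0),
                classifier = classifier))
  }
  remaining <- colnames(x)
  eliminated <- character(0)
  while (length(remaining) > stop_size) {
    w <- fit_linear_weights(x[, remaining, drop = FALSE], y, classifier)
    k <- min(step, length(remaining) - stop_size)
    drop_idx <- order(abs(w), seq_along(w))[seq_len(k)]
    eliminated <- c(eliminated, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  list(selected = remaining, elimination = eliminated, classifier = classifier)
}

#' Intersect two selected peptide sets
#'
#' Deterministic intersection in the order of `feature_order` (the peptide
#' matrix column order). An empty intersection is allowed but raises a
#' warning.
#'
#' @param set_a,set_b character vectors of feature names (nonempty).
#' @param feature_order reference ordering; defaults to `set_a`'s order.
#' @return Character vector.
#' @export
intersect_panels <- function(set_a, set_b, feature_order = NULL) {
  if (!length(set_a) || !length(set_b))
    stop("both sets must be nonempty", call. = FALSE)
  if (is.null(feature_order)) feature_order <- set_a
  panel <- feature_order[feature_order %in% set_a & feature_order %in% set_b]
  if (!length(panel)) warning("empty panel: the two selections do not intersect",
                              call. = FALSE)
  panel
}

# Fast logistic fit + scores used by evaluation and the permutation null.
logistic_scores <- function(x_train, y_train, x_test) {
  suppressWarnings({
    fit <- glm.fit(cbind(1, x_train), y_train, family = binomial())
  })
  drop(plogis(cbind(1, x_test) %*% fit$coefficients))
}

#' Evaluate a peptide panel on held-out data
#'
#' Trains a logistic-regression classifier on the training subjects restricted
#' to the panel (standardization parameters estimated on train only) and
#' reports accuracy, precision, recall, ROC-AUC and the confusion matrix on
#' the untouched test subjects.
#'
#' @param peptides subjects x peptides abundance matrix.
#' @param labels binary group labels.
#' @param panel character vector of panel peptide names.
#' @param train,test integer index vectors from [split_train_test()].
#' @param positive positive class; defaults to the sorted-last label.
#' @return List: `accuracy`, `precision`, `recall`, `auc`, `confusion`.
#' @export
evaluate_panel <- function(peptides, labels, panel, train, test,
                           positive = NULL) {
  if (!length(panel)) stop("panel is empty", call. = FALSE)
  if (length(intersect(train, test)))
    stop("train and test overlap", call. = FALSE)
  if (length(unique(labels[test])) < 2L)
    stop("test set contains a single class", call. = FALSE)
  xtr <- standardize_matrix(log(peptides[train, panel, drop = FALSE]))
  xte <- standardize_matrix(log(peptides[test, panel, drop = FALSE]),
                            center = attr(xtr, "center"),
                            scale = attr(xtr, "scale"))
  y <- as_binary(labels, positive)
  scores <- logistic_scores(xtr, y[train], xte)
  pred <- as.integer(scores > 0.5)
  classification_metrics(y[test], pred, scores, positive = "1")
}

#' Random-panel permutation null for panel performance
#'
#' Evaluates `B` random peptide panels of the same size as the observed panel
#' (drawn without replacement within a panel, uniformly over all peptides)
#' with exactly the same train/test evaluation as [evaluate_panel()], and
#' returns the empirical p-value per metric with the add-one correction
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, which can never be zero.
#'
#' @inheritParams evaluate_panel
#' @param B number of random panels (default 100000).
#' @param seed RNG seed.
#' @param observed optional precomputed result of [evaluate_panel()] for the
#'   observed panel.
#' @return Object of class `permutation_null`: `observed` metrics, `B`,
#'   matrix `null` (B x 4) and named vector `p`.
#' @export
permutation_null <- function(peptides, labels, panel, train, test,
                             B = 100000L, seed = 1L, positive = NULL,
                             observed = NULL) {
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  if (length(panel) >= ncol(peptides))
    stop("panel size equals the number of peptides: null undefined", call. = FALSE)
  if (is.null(observed))
    observed <- evaluate_panel(peptides, labels, panel, train, test, positive)
  y <- as_binary(labels, positive)
  logx <- log(peptides)
  set.seed(seed)
  metrics <- c("accuracy", "precision", "recall", "auc")
  null <- matrix(NA_real_, B, 4L, dimnames = list(NULL, metrics))
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(peptides), length(panel))
    xtr <- standardize_matrix(logx[train, cols, drop = FALSE])
    xte <- standardize_matrix(logx[test, cols, drop = FALSE],
                              center = attr(xtr, "center"),
                              scale = attr(xtr, "scale"))
    scores <- logistic_scores(xtr, y[train], xte)
    m <- classification_metrics(y[test], as.integer(scores > 0.5), scores,
                                positive = "1")
    null[b, ] <- c(m$accuracy, m$precision, m$recall, m$auc)
  }
  obs <- c(accuracy = observed$accuracy, precision = observed$precision,
           recall = observed$recall, auc = observed$auc)
  p <- vapply(metrics, function(mt) {
    nl <- null[, mt]
    nl <- nl[is.finite(nl)]
    (1 + sum(nl >= obs[[mt]])) / (length(nl) + 1)
  }, numeric(1))
  structure(list(observed = obs, B = B, null = null, p = p),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Random-panel permutation null (B =", x$B, ")\n")
  for (mt in names(x$p))
    cat(sprintf("  %-9s observed %.3f  p = %.4g\n", mt, x$observed[[mt]],
                x$p[[mt]]))
  invisible(x)
}

#' Dual-classifier RFE panel selection
#'
#' The full discriminative-selection stage: stratified 80/20 split, training
#' features mean-centred and scaled to unit variance (on the log abundances),
#' recursive feature elimination run independently with a linear SVM and with
#' logistic regression down to `stop_size` peptides each, and the final panel
#' taken as the intersection of the two selections. The panel is then
#' evaluated with a logistic classifier on the held-out 20%, which played no
#' role in selection or training.
#'
#' @param peptides subjects x peptides abundance matrix (positive values; the
#'   log scale is used internally).
#' @param labels binary group labels (e.g. `"CN/BM-"` vs `"AD"`).
#' @param stop_size RFE stopping size per classifier (default 14).
#' @param fraction training fraction (default 0.8).
#' @param seed RNG seed (split only; the rest is deterministic).
#' @param positive positive class for the evaluation metrics.
#' @return Object of class `panel_selection`: `split`, per-classifier
#'   `rfe_svm` / `rfe_logistic`, `panel`, and held-out `metrics`.
#' @export
select_panel <- function(peptides, labels, stop_size = 14L, fraction = 0.8,
                         seed = 1L, positive = NULL) {
  stopifnot(is.matrix(peptides), nrow(peptides) == length(labels))
  split <- split_train_test(labels, fraction, seed)
  xtr <- standardize_matrix(log(peptides[split$train, , drop = FALSE]))
  ytr <- as_binary(labels, positive)[split$train]
  r_svm <- rfe(xtr, ytr, "svm", stop_size)
  r_log <- rfe(xtr, ytr, "logistic", stop_size)
  panel <- intersect_panels(r_svm$selected, r_log$selected,
                            feature_order = colnames(peptides))
  metrics <- if (length(panel))
    evaluate_panel(peptides, labels, panel, split$train, split$test, positive)
  else NULL
  structure(list(split = split, rfe_svm = r_svm, rfe_logistic = r_log,
                 panel = panel, metrics = metrics, stop_size = stop_size,
                 labels = labels),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("Dual-RFE panel selection (stop size", x$stop_size, "per classifier)\n")
  cat("  train/test:", length(x$split$train), "/", length(x$split$test),
      "subjects\n")
  cat("  intersection panel (", length(x$panel), " peptides): ",
      paste(x$panel, collapse = ", "), "\n", sep = "")
  if (!is.null(x$metrics))
    cat(sprintf("  held-out: accuracy %.3f, precision %.3f, recall %.3f, AUC %.3f\n",
                x$metrics$accuracy, x$metrics$precision, x$metrics$recall,
                x$metrics$auc))
  invisible(x)
}

#' @export
summary.panel_selection <- function(object, ...) {
  cat("Per-classifier selections:\n")
  cat("  SVM:      ", paste(object$rfe_svm$selected, collapse = ", "), "\n")
  cat("  logistic: ", paste(object$rfe_logistic$selected, collapse = ", "), "\n")
  print(object)
  if (!is.null(object$metrics)) {
    cat("Held-out confusion matrix:\n")
    print(object$metrics$confusion)
  }
  invisible(object)
}
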