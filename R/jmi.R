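#' Plug-in mutual information of two discrete vectors
#'
#' `I(X; Y) = sum p(x, y) log( p(x, y) / (p(x) p(y)) )` in nats, estimated
#' from the joint counts, with the `0 log 0 = 0` convention. Symmetric and
#' non-negative.
#'
#' @param x,y discrete vectors (factors, integers or characters) of equal
#'   length.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  if (!length(x) || length(x) != length(y))
    stop("x and y must be nonempty and of equal length", call. = FALSE)
  mi_from_table(table(x, y))
}

mi_from_table <- function(tab) {
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj); py <- colSums(pj)
  terms <- pj * log(pj / outer(px, py))
  sum(terms[pj > 0])
}

#' Equal-frequency discretization
#'
#' Bins a continuous vector into (at most) `bins` equal-frequency bins whose
#' edges are the sample quantiles; pass stored `breaks` to apply training-set
#' edges to new data. Duplicate quantiles under heavy ties collapse, so fewer
#' bins may result.
#'
#' @param x numeric vector.
#' @param bins number of bins (default 5).
#' @param breaks optional precomputed bin edges (first/last are infinite).
#' @return Integer bin ids with the edges attached as `attr(, "breaks")`.
#' @export
discretize_bins <- function(x, bins = 5L, breaks = NULL) {
  if (is.null(breaks)) {
    qs <- quantile(x, probs = seq(0, 1, length.out = bins + 1L), type = 7)
    breaks <- unique(qs)
    breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  }
  out <- cut(x, breaks = breaks, labels = FALSE, include.lowest = TRUE)
  attr(out, "breaks") <- breaks
  out
}

#' Greedy joint-mutual-information feature selection
#'
#' Forward selection under the JMI criterion: the first feature maximizes
#' `I(X; Y)`; each later step adds the candidate maximizing
#' `sum over selected s of I(X_cand, X_s; Y)`, the summed joint information
#' with the class over the already-selected set. Continuous features are
#' discretized into equal-frequency bins whose edges are computed on the
#' supplied (training) data only. Ties are broken by input feature order;
#' constant features are excluded up front.
#'
#' @param features numeric matrix (training subjects x features) with column
#'   names.
#' @param labels class labels (at least two classes).
#' @param target_size number of features to select (default 5).
#' @param bins equal-frequency bins per feature (default 5).
#' @return Object of class `jmi_selection`: `selected` (names in selection
#'   order), `scores` (per-step winning JMI score), `bins`, `breaks` (per
#'   selected feature), `excluded` (constant features).
#' @export
jmi_select <- function(features, labels, target_size = 5L, bins = 5L) {
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  if (length(unique(labels)) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (target_size >= ncol(features))
    stop("target_size must be smaller than the number of features", call. = FALSE)
  y <- factor(labels)
  constant <- apply(features, 2, function(v) sd(v) == 0)
  if (any(constant))
    message("excluded constant feature(s): ",
            paste(colnames(features)[constant], collapse = ", "))
  pool <- colnames(features)[!constant]
  disc <- lapply(pool, function(nm) discretize_bins(features[, nm], bins))
  names(disc) <- pool

  selected <- character(0)
  scores <- numeric(0)
  while (length(selected) < target_size && length(pool)) {
    cand_scores <- vapply(pool, function(nm) {
      if (!length(selected)) {
        mutual_information(disc[[nm]], y)
      } else {
        sum(vapply(selected, function(s) {
          mi_from_table(table(interaction(disc[[nm]], disc[[s]], drop = TRUE), y))
        }, numeric(1)))
      }
    }, numeric(1))
    best <- which.max(cand_scores)  # first max: input-order tie-break
    selected <- c(selected, pool[best])
    scores <- c(scores, cand_scores[best])
    pool <- pool[-best]
  }
  structure(list(selected = selected, scores = unname(scores), bins = bins,
                 breaks = lapply(disc[selected], attr, "breaks"),
                 excluded = colnames(features)[constant]),
            class = "jmi_selection")
}

#' @export
print.jmi_selection <- function(x, ...) {
  cat("JMI forward selection (", x$bins, " equal-frequency bins)\n", sep = "")
  for (i in seq_along(x$selected))
    cat(sprintf("  %d. %-12s score %.4f nats\n", i, x$selected[i], x$scores[i]))
  invisible(x)
}

#' Held-out evaluation of a sub-grouping panel
#'
#' Trains a logistic classifier on a stratified 80% of the subjects using the
#' panel features (standardization parameters from the training side only)
#' and reports accuracy and the confusion matrix on the untouched 20%.
#'
#' @param peptides subjects x peptides abundance matrix (positive).
#' @param labels two-class subgroup labels.
#' @param panel panel peptide names.
#' @param holdout_fraction held-out fraction (default 0.2).
#' @param seed RNG seed for the split.
#' @param positive positive class for the metrics.
#' @return List: `accuracy`, `confusion`, `auc`, `split`.
#' @export
evaluate_subgroup_panel <- function(peptides, labels, panel,
                                    holdout_fraction = 0.2, seed = 1L,
                                    positive = NULL) {
  split <- stratified_split(labels, 1 - holdout_fraction, seed)
  m <- evaluate_panel(peptides, labels, panel, split$train, split$test,
                      positive)
  list(accuracy = m$accuracy, confusion = m$confusion, auc = m$auc,
       split = split)
}

#' Cross-validated ROC evaluation of a panel
#'
#' Stratified k-fold cross-validation (default 6 folds) of a linear logistic
#' classifier on the panel features: per-fold ROC curve and trapezoidal AUC,
#' with the mean AUC and its standard error across folds.
#'
#' @inheritParams evaluate_subgroup_panel
#' @param k number of folds (default 6); every class must have at least `k`
#'   members.
#' @return Object of class `cv_roc`: `fold` assignment, `auc` per fold,
#'   `mean_auc`, `se`, and per-fold ROC curves in `roc`.
#' @export
cross_validated_roc <- function(peptides, labels, panel, k = 6L, seed = 1L,
                                positive = NULL) {
  fold <- stratified_folds(labels, k, seed)
  y <- as_binary(labels, positive)
  logx <- log(peptides[, panel, drop = FALSE])
  aucs <- numeric(k)
  rocs <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    xtr <- standardize_matrix(logx[tr, , drop = FALSE])
    xte <- standardize_matrix(logx[te, , drop = FALSE],
                              center = attr(xtr, "center"),
                              scale = attr(xtr, "scale"))
    scores <- logistic_scores(xtr, y[tr], xte)
    rocs[[f]] <- roc_points(scores, y[te], positive = "1")
    aucs[f] <- auc_trapezoid(scores, y[te], positive = "1")
  }
  structure(list(fold = fold, auc = aucs, mean_auc = mean(aucs),
                 se = sd(aucs) / sqrt(k), roc = rocs, k = k),
            class = "cv_roc")
}

#' @export
print.cv_roc <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated ROC: mean AUC %.3f (SE %.3f)\n",
              x$k, x$mean_auc, x$se))
  cat("  per-fold AUC:", paste(sprintf("%.3f", x$auc), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cv_roc <- function(x, ...) {
  plot(c(0, 1), c(0, 1), type = "n", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("%d-fold CV ROC (mean AUC %.2f)", x$k, x$mean_auc), ...)
  abline(0, 1, lty = 3, col = "grey")
  for (rc in x$roc)
    lines(c(0, rc$fpr, 1), c(0, rc$tpr, 1), col = "#00000055")
  invisible(x)
}
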