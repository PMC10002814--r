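#' Two-component Gaussian-mixture cutoff for a biomarker ratio
#'
#' Fits a univariate two-component Gaussian mixture to a positive analyte
#' ratio (for instance tTau:Abeta42) by EM with multiple restarts, and derives
#' the decision cutoff as the equal-posterior crossing between the two
#' component means — the Bayes decision boundary of the fitted mixture.
#'
#' Bimodality of the fit is checked with Ashman's D,
#' `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`; fits with D < 2 are flagged
#' unimodal and carry no cutoff (`NA`) rather than a silently meaningless one.
#'
#' @param ratios positive numeric vector, length >= 20.
#' @param on_log_scale fit the mixture to `log(ratios)`; the returned cutoff
#'   is always on the original ratio scale.
#' @param n_starts number of EM restarts (best log-likelihood kept).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per start.
#' @param seed RNG seed for the random restarts.
#' @return Object of class `cutoff_model`: component `weights`, `means`,
#'   `sds` (on the fitting scale), `cutoff` (ratio scale, `NA` when flagged),
#'   `loglik`, `converged`, `bimodal`, `ashman_d`, `on_log_scale`.
#' @export
fit_ratio_mixture <- function(ratios, on_log_scale = FALSE, n_starts = 10L,
                              tol = 1e-8, max_iter = 500L, seed = 1L) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 20L) stop("need at least 20 observations", call. = FALSE)
  if (any(ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  x <- if (on_log_scale) log(ratios) else ratios
  var_floor <- 1e-6 * var(x)
  set.seed(seed)

  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- em_two_gauss(x, start = s, var_floor = var_floor,
                        tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  o <- order(best$means)
  m <- best$means[o]; sdev <- sqrt(best$vars[o]); w <- best$weights[o]

  d_ashman <- abs(diff(m)) / sqrt(mean(sdev^2))
  bimodal <- d_ashman >= 2
  cutoff <- NA_real_
  if (bimodal) {
    cutoff <- equal_posterior_point(w, m, sdev)
    if (on_log_scale) cutoff <- exp(cutoff)
  }
  structure(list(weights = w, means = m, sds = sdev, cutoff = cutoff,
                 loglik = best$loglik, converged = best$converged,
                 bimodal = bimodal, ashman_d = d_ashman,
                 on_log_scale = on_log_scale, n = length(x)),
            class = "cutoff_model")
}

# EM for a 1-D two-component Gaussian mixture. start = 1 uses a median split;
# later starts draw random responsibilities.
em_two_gauss <- function(x, start, var_floor, tol, max_iter) {
  n <- length(x)
  if (start == 1L) {
    r1 <- as.numeric(x <= median(x))
  } else {
    r1 <- runif(n)
  }
  resp <- cbind(r1, 1 - r1)
  w <- colMeans(resp)
  m <- colSums(resp * x) / colSums(resp)
  v <- pmax(colSums(resp * outer(x, m, `-`)^2) / colSums(resp), var_floor)

  loglik <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- cbind(w[1] * dnorm(x, m[1], sqrt(v[1])),
                  w[2] * dnorm(x, m[2], sqrt(v[2])))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8)) break  # emptied component; keep last params
    w <- nk / n
    m <- colSums(resp * x) / nk
    v <- colSums(resp * (outer(x, m, `-`))^2) / nk
    if (any(v < var_floor))
      stop("degenerate mixture component (variance below floor)", call. = FALSE)
    if (is.finite(loglik) && abs(ll - loglik) < tol) { converged <- TRUE; loglik <- ll; break }
    loglik <- ll
  }
  list(weights = w, means = m, vars = v, loglik = loglik, converged = converged)
}

# Equal-posterior crossing between the two component means: coarse grid for a
# sign change of log(w1 f1) - log(w2 f2), refined by bisection.
equal_posterior_point <- function(w, m, sdev) {
  f <- function(t) {
    (log(w[1]) + dnorm(t, m[1], sdev[1], log = TRUE)) -
      (log(w[2]) + dnorm(t, m[2], sdev[2], log = TRUE))
  }
  grid <- seq(m[1], m[2], length.out = 512)
  vals <- vapply(grid, f, numeric(1))
  sgn <- which(diff(sign(vals)) != 0)
  if (!length(sgn)) return(mean(m))  # no crossing inside (m1, m2)
  i <- sgn[1]
  uniroot(f, lower = grid[i], upper = grid[i + 1], tol = 1e-12)$root
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat("Two-component Gaussian mixture cutoff model",
      if (x$on_log_scale) "(fitted on log scale)", "\n")
  cat(sprintf("  components: w = %.3f/%.3f, mean = %.4g/%.4g, sd = %.4g/%.4g\n",
              x$weights[1], x$weights[2], x$means[1], x$means[2],
              x$sds[1], x$sds[2]))
  cat(sprintf("  log-likelihood %.3f (converged: %s), Ashman D = %.2f\n",
              x$loglik, x$converged, x$ashman_d))
  if (x$bimodal) cat(sprintf("  cutoff (ratio scale): %.4g\n", x$cutoff))
  else cat("  flagged unimodal: no cutoff derived\n")
  invisible(x)
}

#' Gate subjects into biomarker groups by an analyte-ratio cutoff
#'
#' A subject is biomarker-positive iff `ttau / abeta42 > cutoff` (strictly).
#' Cognitively normal positives are labelled `"AsymAD"`, cognitively normal
#' negatives `"CN/BM-"`, impaired positives `"AD"` (biomarker-confirmed), and
#' impaired negatives `"impaired/BM-"`. Subjects with missing analytes are
#' labelled `NA` and listed in `attr(, "excluded")` with a reason.
#'
#' @param subjects data frame with columns `abeta42`, `ttau` and
#'   `cognitive_status` (`"normal"` / `"impaired"`).
#' @param cutoff positive ratio cutoff; the default 0.24 is the convention for
#'   the tTau:Abeta42 ratio used throughout the package.
#' @return Character vector of group labels (one per row), with attributes
#'   `positive` (logical biomarker status) and `excluded`.
#' @export
gate_subjects <- function(subjects, cutoff = 0.24) {
  stopifnot(cutoff > 0)
  need <- c("abeta42", "ttau", "cognitive_status")
  if (!all(need %in% names(subjects)))
    stop("subjects must have columns ", paste(need, collapse = ", "), call. = FALSE)
  ratio <- subjects$ttau / subjects$abeta42
  missing_idx <- which(is.na(ratio))
  positive <- ratio > cutoff
  normal <- subjects$cognitive_status == "normal"
  label <- ifelse(normal & positive, "AsymAD",
           ifelse(normal & !positive, "CN/BM-",
           ifelse(!normal & positive, "AD", "impaired/BM-")))
  label[missing_idx] <- NA_character_
  if (length(missing_idx))
    message(length(missing_idx), " subject(s) excluded from gating: missing analytes")
  attr(label, "positive") <- positive
  attr(label, "excluded") <- data.frame(row = missing_idx,
                                        reason = rep("missing analytes",
                                                     length(missing_idx)))
  label
}

#' Youden-index ROC cutoff
#'
#' Scans the midpoints between consecutive distinct score values and returns
#' the threshold maximizing Youden's J = sensitivity + specificity - 1. Ties
#' on J are broken toward higher specificity, then toward the more extreme
#' threshold.
#'
#' @param scores numeric scores.
#' @param labels binary labels (the sorted-last level is the positive class
#'   unless `positive` is given).
#' @param direction `">"` if larger scores indicate the positive class,
#'   `"<"` otherwise.
#' @param positive optional positive-class label.
#' @return Object of class `roc_cutoff`: `threshold`, `direction`,
#'   `sensitivity`, `specificity`, `youden_j`, and `uninformative` (TRUE when
#'   all scores are identical).
#' @export
youden_cutoff <- function(scores, labels, direction = c(">", "<"),
                          positive = NULL) {
  direction <- match.arg(direction)
  stop_if_not_binary(labels)
  y <- as_binary(labels, positive)
  su <- sort(unique(scores))
  uninformative <- length(su) == 1L
  cand <- if (uninformative) su else (head(su, -1) + su[-1]) / 2
  best <- NULL
  for (thr in cand) {
    pred <- if (direction == ">") scores > thr else scores < thr
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    j <- sens + spec - 1
    extremity <- if (direction == ">") thr else -thr
    key <- c(j, spec, extremity)
    if (is.null(best) || lex_gt(key, best$key))
      best <- list(key = key, threshold = thr, sens = sens, spec = spec, j = j)
  }
  structure(list(threshold = best$threshold, direction = direction,
                 sensitivity = best$sens, specificity = best$spec,
                 youden_j = best$j, uninformative = uninformative),
            class = "roc_cutoff")
}

lex_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + 1e-12) return(TRUE)
    if (a[i] < b[i] - 1e-12) return(FALSE)
  }
  FALSE
}

#' @export
print.roc_cutoff <- function(x, ...) {
  cat(sprintf("Youden cutoff: positive if score %s %.6g\n", x$direction,
              x$threshold))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, J = %.3f%s\n",
              x$sensitivity, x$specificity, x$youden_j,
              if (x$uninformative) " [uninformative]" else ""))
  invisible(x)
}

#' Standardize a vector to z-scores
#'
#' `(x - mean) / sd`, using reference statistics when supplied (for example
#' train-set statistics applied to test data) and the input's own otherwise.
#' The statistics used are attached as attributes `center` and `scale`.
#'
#' @param x numeric vector.
#' @param center,scale optional reference mean and SD.
#' @return z-scores with `center`/`scale` attributes.
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- mean(x, na.rm = TRUE)
  if (is.null(scale)) scale <- sd(x, na.rm = TRUE)
  if (!is.finite(scale) || scale <= 0)
    stop("zero or undefined variance on the reference set", call. = FALSE)
  structure((x - center) / scale, center = center, scale = scale)
}

# column-wise train-referenced standardization for feature matrices
standardize_matrix <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  out <- sweep(sweep(x, 2, center), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Analyte panel with derived ratios and z-scores
#'
#' Convenience constructor: from raw Abeta42 / tTau / pTau columns, derives
#' tTau:Abeta42 and pTau:Abeta42 ratios and cohort-standardized versions of
#' all five quantities (columns prefixed `z_`).
#'
#' @param subjects data frame with positive `abeta42`, `ttau`, `ptau` columns.
#' @return Data frame of analytes, ratios and z-scores.
#' @export
analyte_panel <- function(subjects) {
  need <- c("abeta42", "ttau", "ptau")
  stopifnot(all(need %in% names(subjects)))
  if (any(subjects[need] <= 0, na.rm = TRUE))
    stop("analytes must be positive", call. = FALSE)
  out <- subjects[need]
  out$ttau_abeta42 <- out$ttau / out$abeta42
  out$ptau_abeta42 <- out$ptau / out$abeta42
  for (v in names(out)) out[[paste0("z_", v)]] <- as.numeric(standardize(out[[v]]))
  out
}
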