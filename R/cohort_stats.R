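#' Median regression of an outcome on a standardized analyte
#'
#' Quantile regression at the 0.5 quantile (minimizing summed absolute
#' residuals): robust to the right-skewed residuals typical of
#' neuropsychological scores. The coefficient of interest is the analyte's;
#' when the analyte is standardized it reads as outcome change per 1 SD of
#' analyte, and a more positive beta means a stronger positive association.
#'
#' Inference is by seeded nonparametric (xy-pair) bootstrap by default:
#' percentile CI and a normal-approximation p-value from the bootstrap SE.
#' `method = "rank"` instead takes the rank-inversion CI from
#' \code{quantreg} and a Wald p-value under its `nid` standard errors.
#'
#' Rows with missing values in the outcome, analyte or covariates are dropped
#' listwise and the count reported via `message()`.
#'
#' @param outcome numeric response vector.
#' @param analyte numeric predictor of interest (typically a z-score).
#' @param covariates optional data frame of adjustment covariates
#'   (e.g. age, sex, race, education).
#' @param method `"bootstrap"` (default) or `"rank"`.
#' @param B bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed for the bootstrap.
#' @param outcome_name,analyte_name labels carried into the result.
#' @return Object of class `csf_regression` with `beta`, `ci`, `p`, `n`,
#'   `model = "median"`, and the fitted \code{quantreg::rq} object in `fit`.
#' @export
median_regression <- function(outcome, analyte, covariates = NULL,
                              method = c("bootstrap", "rank"), B = 1000L,
                              level = 0.95, seed = 1L,
                              outcome_name = "outcome",
                              analyte_name = "analyte") {
  method <- match.arg(method)
  dat <- data.frame(.y = outcome, .x = analyte)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  keep <- complete.cases(dat)
  if (any(!keep))
    message(sum(!keep), " row(s) dropped (listwise deletion of missing values)")
  dat <- dat[keep, , drop = FALSE]
  n_coef <- 2L + if (is.null(covariates)) 0L else ncol(covariates)
  if (nrow(dat) <= n_coef + 5L)
    stop("too few complete observations for the number of coefficients",
         call. = FALSE)
  form <- stats::as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"),
                                                collapse = " + ")))
  mm <- stats::model.matrix(form, dat)
  if (qr(mm)$rank < ncol(mm))
    stop("design matrix is rank deficient", call. = FALSE)

  # rq warns about nonunique solutions on degenerate (e.g. noiseless) data;
  # the minimizer returned is still a valid L1 fit
  fit <- suppressWarnings(quantreg::rq(form, tau = 0.5, data = dat))
  beta <- unname(coef(fit)[".x"])
  alpha <- 1 - level

  if (method == "bootstrap") {
    set.seed(seed)
    boots <- vapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(dat), replace = TRUE)
      fb <- tryCatch(
        suppressWarnings(quantreg::rq(form, tau = 0.5,
                                      data = dat[idx, , drop = FALSE])),
        error = function(e) NULL)
      if (is.null(fb)) NA_real_ else unname(coef(fb)[".x"])
    }, numeric(1))
    boots <- boots[is.finite(boots)]
    se <- sd(boots)
    ci <- unname(quantile(boots, c(alpha / 2, 1 - alpha / 2)))
    p <- 2 * pnorm(-abs(beta) / se)
  } else {
    sm <- summary(fit, se = "rank", alpha = alpha)
    cf <- sm$coefficients
    ci <- unname(cf[".x", c("lower bd", "upper bd")])
    se <- NA_real_
    p <- tryCatch({
      sn <- summary(fit, se = "nid")
      unname(sn$coefficients[".x", "Pr(>|t|)"])
    }, error = function(e) NA_real_)
  }
  new_csf_regression(outcome_name, analyte_name, beta, ci, p, se,
                     n = nrow(dat), model = "median", fit = fit)
}

#' Logistic regression on a median-dichotomized outcome
#'
#' For sparse or heavily tied scores: the outcome is split at its median
#' (ties assigned to the lower class) and modelled by maximum-likelihood
#' logistic regression. The analyte coefficient is a log-odds ratio per unit
#' (per SD when standardized). Perfect separation is flagged and the fit
#' falls back to a lightly ridge-penalized logistic model.
#'
#' @inheritParams median_regression
#' @return Object of class `csf_regression` (`model = "logistic"`, plus
#'   `separation` flag).
#' @export
dichotomized_logistic <- function(outcome, analyte, covariates = NULL,
                                  level = 0.95,
                                  outcome_name = "outcome",
                                  analyte_name = "analyte") {
  if (length(unique(outcome[!is.na(outcome)])) < 2L)
    stop("outcome has fewer than 2 distinct values; cannot dichotomize",
         call. = FALSE)
  med <- median(outcome, na.rm = TRUE)
  hi <- as.integer(outcome > med)  # ties at the median go to the lower class
  message("dichotomized at median ", signif(med, 4), ": ",
          sum(hi == 0, na.rm = TRUE), " low / ", sum(hi == 1, na.rm = TRUE), " high")
  dat <- data.frame(.y = hi, .x = analyte)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  keep <- complete.cases(dat)
  if (any(!keep))
    message(sum(!keep), " row(s) dropped (listwise deletion of missing values)")
  dat <- dat[keep, , drop = FALSE]
  form <- stats::as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"),
                                                collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated) {
    mm <- stats::model.matrix(form, dat)[, -1, drop = FALSE]
    pen <- glmnet::glmnet(cbind(mm, 0), dat$.y, family = "binomial",
                          alpha = 0, lambda = 1e-2, standardize = FALSE)
    beta <- as.numeric(coef(pen))[match(".x", colnames(mm)) + 1L]
    se <- NA_real_; ci <- c(NA_real_, NA_real_); p <- NA_real_
  } else {
    sm <- summary(fit)$coefficients
    beta <- unname(sm[".x", "Estimate"])
    se <- unname(sm[".x", "Std. Error"])
    z <- qnorm(1 - (1 - level) / 2)
    ci <- beta + c(-1, 1) * z * se
    p <- unname(sm[".x", "Pr(>|z|)"])
  }
  out <- new_csf_regression(outcome_name, analyte_name, beta, ci, p, se,
                            n = nrow(dat), model = "logistic", fit = fit)
  out$separation <- separated
  out
}

new_csf_regression <- function(outcome, analyte, beta, ci, p, se, n, model, fit) {
  structure(list(outcome = outcome, analyte = analyte, beta = beta,
                 ci_lower = ci[1], ci_upper = ci[2], p = p, se = se, n = n,
                 model = model, fit = fit),
            class = "csf_regression")
}

#' @export
print.csf_regression <- function(x, ...) {
  cat(sprintf("%s regression: %s ~ %s (n = %d)\n",
              if (x$model == "median") "Median (quantile 0.5)" else "Dichotomized logistic",
              x$outcome, x$analyte, x$n))
  cat(sprintf("  beta = %.4g  [%.4g, %.4g]  p = %.4g\n",
              x$beta, x$ci_lower, x$ci_upper, x$p))
  if (isTRUE(x$separation)) cat("  note: perfect separation; ridge fallback used\n")
  invisible(x)
}

#' @export
coef.csf_regression <- function(object, ...) {
  setNames(object$beta, object$analyte)
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure at level `q` (default 0.20, i.e. FDR < 20%). Rejections
#' are monotone in p: any p-value not larger than a rejected one is also
#' rejected.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q target FDR in `(0, 1)`.
#' @return Logical rejection flags, same length and order as `pvalues`.
#' @export
bh_fdr <- function(pvalues, q = 0.20) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  p.adjust(pvalues, method = "BH") <= q
}

#' Kendall-tau ranking of peptides against a cognitive score
#'
#' Tie-corrected Kendall tau-b between each peptide's abundance and a score,
#' sorted in descending order of tau (stable sort). Constant peptides, for
#' which tau is undefined, are excluded and reported.
#'
#' @param peptides subjects x peptides numeric matrix.
#' @param score numeric score vector (one per subject).
#' @param highlight optional character vector of peptide names to flag in the
#'   output (e.g. a selected panel).
#' @return Object of class `tau_ranking`: data frame with columns `peptide`,
#'   `tau`, `in_panel`, sorted by descending tau; excluded peptides in
#'   `attr(, "excluded")`.
#' @export
kendall_ranking <- function(peptides, score, highlight = character(0)) {
  stopifnot(is.matrix(peptides), nrow(peptides) == length(score))
  nm <- colnames(peptides)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(peptides)))
  taus <- rep(NA_real_, ncol(peptides))
  for (j in seq_len(ncol(peptides))) {
    ok <- complete.cases(peptides[, j], score)
    if (sum(ok) < 10L)
      stop("peptide ", nm[j], " has fewer than 10 complete pairs", call. = FALSE)
    if (sd(peptides[ok, j]) == 0) next  # tau undefined for constant peptide
    taus[j] <- cor(peptides[ok, j], score[ok], method = "kendall")
  }
  excluded <- nm[is.na(taus)]
  if (length(excluded))
    message("excluded constant peptide(s): ", paste(excluded, collapse = ", "))
  keep <- !is.na(taus)
  ord <- order(-taus[keep])
  out <- data.frame(peptide = nm[keep][ord], tau = taus[keep][ord],
                    in_panel = nm[keep][ord] %in% highlight,
                    stringsAsFactors = FALSE)
  class(out) <- c("tau_ranking", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

#' Matched-group hypothesis tests
#'
#' Dispatches to the appropriate paired or exact test: paired t-test or
#' Wilcoxon signed-rank test for paired continuous values, McNemar-Bowker
#' symmetry test for paired categorical values (k x k table), and Fisher's
#' exact test for an r x c contingency table. All p-values are two-sided.
#'
#' For the Wilcoxon test, identical paired vectors leave no nonzero
#' differences; the test is then undefined and the result is flagged with
#' `p = 1`.
#'
#' @param case,control paired numeric vectors (for `paired_t` / `wilcoxon`)
#'   or paired categorical vectors (for `mcnemar_bowker`).
#' @param type which test to run.
#' @param table contingency table or matrix (for `fisher`, or
#'   `mcnemar_bowker` given directly as a square table).
#' @return List with `statistic`, `p.value`, `method`, and `undefined` flag.
#' @export
matched_tests <- function(case = NULL, control = NULL,
                          type = c("paired_t", "wilcoxon", "mcnemar_bowker",
                                   "fisher"),
                          table = NULL) {
  type <- match.arg(type)
  undefined <- FALSE
  ht <- switch(type,
    paired_t = t.test(case, control, paired = TRUE),
    wilcoxon = {
      d <- case - control
      if (all(d == 0, na.rm = TRUE)) {
        undefined <- TRUE
        list(statistic = NA_real_, p.value = 1,
             method = "Wilcoxon signed rank test (no nonzero differences)")
      } else {
        suppressWarnings(wilcox.test(case, control, paired = TRUE))
      }
    },
    mcnemar_bowker = {
      tb <- if (!is.null(table)) as.table(as.matrix(table))
            else table(factor(case), factor(control))
      if (nrow(tb) != ncol(tb)) stop("square table required", call. = FALSE)
      mcnemar.test(tb, correct = FALSE)
    },
    fisher = {
      if (is.null(table)) stop("fisher requires a contingency table", call. = FALSE)
      fisher.test(as.matrix(table))
    })
  list(statistic = unname(if (!is.null(ht$statistic)) ht$statistic else NA_real_),
       p.value = ht$p.value, method = ht$method, undefined = undefined)
}

#' Run the cohort regression stage over analytes and outcomes
#'
#' Convenience driver mirroring a results table: every combination of outcome
#' and standardized analyte is fitted (median regression by default,
#' dichotomized logistic for outcomes named in `dichotomize`), and BH FDR
#' flags are added at level `q`.
#'
#' @param subjects subject data frame containing the outcome columns.
#' @param outcomes character vector of outcome column names.
#' @param analytes data frame of standardized analyte columns.
#' @param covariates optional covariate data frame.
#' @param dichotomize outcomes to model via [dichotomized_logistic()].
#' @param q FDR level for [bh_fdr()].
#' @param B,seed bootstrap settings passed to [median_regression()].
#' @return Data frame with one row per (outcome, analyte): estimate, CI,
#'   p-value and FDR flag.
#' @export
regression_table <- function(subjects, outcomes, analytes, covariates = NULL,
                             dichotomize = character(0), q = 0.20,
                             B = 1000L, seed = 1L) {
  rows <- list()
  for (oc in outcomes) {
    for (an in names(analytes)) {
      res <- if (oc %in% dichotomize)
        suppressMessages(dichotomized_logistic(subjects[[oc]], analytes[[an]],
                                               covariates, outcome_name = oc,
                                               analyte_name = an))
      else
        suppressMessages(median_regression(subjects[[oc]], analytes[[an]],
                                           covariates, B = B,
                                           seed = derive_seed(seed, length(rows)),
                                           outcome_name = oc, analyte_name = an))
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, analyte = an, estimate = res$beta,
        ci_lower = res$ci_lower, ci_upper = res$ci_upper, p = res$p,
        model = res$model, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_pass <- bh_fdr(out$p, q)
  out
}
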