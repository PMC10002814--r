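# Independent brute-force oracles used to check package operations.
# Each reimplements the operation's definition directly, without calling
# package internals.

# Kendall tau-b by O(n^2) concordant/discordant pair counting.
oracle_kendall <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) next
    else if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx_total(x)) * (n0 - tx_total(y)))
}
tx_total <- function(v) {
  tb <- table(v)
  sum(tb * (tb - 1) / 2)
}

# Exhaustive Youden scan over midpoints of consecutive distinct scores.
oracle_youden_j <- function(scores, labels, direction = ">", positive) {
  y <- as.integer(as.character(labels) == positive)
  su <- sort(unique(scores))
  cand <- if (length(su) == 1) su else (su[-length(su)] + su[-1]) / 2
  best <- -Inf
  for (thr in cand) {
    pred <- if (direction == ">") scores > thr else scores < thr
    j <- sum(pred & y == 1) / sum(y == 1) + sum(!pred & y == 0) / sum(y == 0) - 1
    if (j > best) best <- j
  }
  best
}

# Benjamini-Hochberg step-up from its definition.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Mutual information by explicit term-by-term summation over a count table.
oracle_mi <- function(tab) {
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0)
      out <- out + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
  }
  out
}

# AUC as the Mann-Whitney U statistic by brute-force pair counting
# (half credit for tied scores).
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# KNN majority vote by full distance sort (ties by reference order).
oracle_knn_label <- function(coords, ref_idx, ref_labels, q, k) {
  d <- apply(coords[ref_idx, , drop = FALSE], 1,
             function(r) sqrt(sum((r - coords[q, ])^2)))
  ord <- order(d, seq_along(ref_idx))
  nb <- as.character(ref_labels)[ord[seq_len(k)]]
  names(sort(table(nb), decreasing = TRUE))[1]
}

# Step-by-step RFE oracle: refit the named classifier at every step and drop
# the feature with the smallest absolute coefficient (ties: earlier column).
oracle_rfe_order <- function(x, y, classifier, stop_size) {
  remaining <- colnames(x)
  elim <- character(0)
  while (length(remaining) > stop_size) {
    xs <- x[, remaining, drop = FALSE]
    if (classifier == "svm") {
      fit <- e1071::svm(xs, factor(y), kernel = "linear", cost = 1, scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV)[colnames(xs)]
    } else {
      fit <- glmnet::glmnet(xs, factor(y), family = "binomial", alpha = 0,
                            lambda = 0.01, standardize = FALSE)
      w <- as.numeric(coef(fit))[-1]
    }
    worst <- which(abs(w) == min(abs(w)))[1]
    elim <- c(elim, remaining[worst])
    remaining <- remaining[-worst]
  }
  list(elimination = elim, selected = remaining)
}

# JMI candidate scores at one greedy step, by direct table construction.
oracle_jmi_scores <- function(disc, y, selected, pool) {
  vapply(pool, function(nm) {
    if (!length(selected)) {
      oracle_mi(table(disc[[nm]], y))
    } else {
      sum(vapply(selected, function(s) {
        joint <- paste(disc[[nm]], disc[[s]])
        oracle_mi(table(joint, y))
      }, numeric(1)))
    }
  }, numeric(1))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  dens <- dhyper(support, m, n, kk)
  obs <- dhyper(tab[1, 1], m, n, kk)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Greedy matching oracle following the documented convention: cases in
# descending order of nearest-eligible-control distance, each taking its
# nearest unused control.
oracle_greedy_match <- function(case_vals, ctrl_vals) {
  sdv <- sd(c(case_vals, ctrl_vals))
  D <- abs(outer(case_vals, ctrl_vals, `-`)) / sdv
  difficulty <- apply(D, 1, min)
  ord <- order(-difficulty, seq_along(case_vals))
  used <- logical(length(ctrl_vals))
  pairs <- matrix(NA_integer_, length(case_vals), 2)
  for (i in ord) {
    d <- D[i, ]; d[used] <- Inf
    j <- which.min(d)
    used[j] <- TRUE
    pairs[i, ] <- c(i, j)
  }
  pairs
}
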