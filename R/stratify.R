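#' 2-D t-SNE embedding of a standardized panel
#'
#' Embeds all subjects (reference and query jointly) into two dimensions with
#' t-SNE. The embedding is deterministic given `seed`. Perplexity is capped at
#' `(n - 1) / 3` as the algorithm requires.
#'
#' @param x standardized numeric feature matrix (subjects x features).
#' @param perplexity t-SNE perplexity (default 30, capped).
#' @param max_iter gradient-descent iterations (default 1000).
#' @param seed RNG seed.
#' @return Object of class `embedding_run`: `coords` (n x 2 matrix, rownames
#'   preserved), `perplexity`, `max_iter`, `seed`.
#' @export
embed_2d <- function(x, perplexity = 30, max_iter = 1000L, seed = 1L) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (n < 4L) stop("too few subjects to embed", call. = FALSE)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 1) stop("too few subjects for any valid perplexity", call. = FALSE)
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                      max_iter = max_iter, pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE,
                      num_threads = 1)
  coords <- fit$Y
  rownames(coords) <- rownames(x)
  structure(list(coords = coords, perplexity = perplexity,
                 max_iter = max_iter, seed = seed),
            class = "embedding_run")
}

#' K-nearest-neighbour pseudo-labelling in an embedding
#'
#' Assigns each query subject the majority label of its `k` nearest reference
#' subjects (Euclidean distance in the embedding). Only reference subjects
#' vote; queries never do. `k` must be odd, so there are no vote ties;
#' distance ties are broken by reference subject order, making the assignment
#' deterministic.
#'
#' @param coords n x 2 coordinate matrix (all subjects).
#' @param ref_idx integer indices of reference subjects in `coords`.
#' @param ref_labels labels of the reference subjects (two classes).
#' @param query_idx integer indices of query subjects.
#' @param k number of neighbours (odd, default 5).
#' @return Data frame: `query` (index), one vote-count column per reference
#'   class, and `label` (the winning class).
#' @export
knn_assign <- function(coords, ref_idx, ref_labels, query_idx, k = 5L) {
  if (k %% 2L == 0L) stop("k must be odd", call. = FALSE)
  if (k >= length(ref_idx)) stop("k must be smaller than the number of references",
                                 call. = FALSE)
  stop_if_not_binary(ref_labels)
  classes <- sort(unique(as.character(ref_labels)))
  votes <- matrix(0L, length(query_idx), 2L,
                  dimnames = list(NULL, classes))
  lab <- character(length(query_idx))
  for (i in seq_along(query_idx)) {
    d <- sqrt(rowSums((coords[ref_idx, , drop = FALSE] -
                         matrix(coords[query_idx[i], ], length(ref_idx),
                                ncol(coords), byrow = TRUE))^2))
    nb <- order(d, seq_along(ref_idx))[seq_len(k)]  # ties -> reference order
    v <- table(factor(as.character(ref_labels)[nb], levels = classes))
    votes[i, ] <- as.integer(v)
    lab[i] <- classes[which.max(v)]
  }
  out <- data.frame(query = query_idx, votes, label = lab,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

#' Stability stratification of intermediate cases
#'
#' Repeats the joint t-SNE embedding + KNN pseudo-labelling with
#' repeat-specific seeds derived from a master seed, and summarizes each
#' query's assignments as the probability of the `ad_label` class across
#' repeats. Final labels: `"AD-like"` if that probability exceeds the upper
#' band edge, `"Control-like"` below the lower edge, `"uncertain"` inside the
#' band.
#'
#' The embedding is fitted jointly on reference and query subjects, on the
#' panel's log abundances standardized across all subjects involved.
#'
#' @param peptides subjects x peptides abundance matrix (positive).
#' @param panel character vector of panel peptide names.
#' @param ref_idx,ref_labels reference subjects and their two-class labels.
#' @param query_idx query (e.g. AsymAD) subject indices.
#' @param repeats number of embedding repeats (default 100).
#' @param k KNN neighbours (odd, default 5).
#' @param perplexity,max_iter t-SNE settings (see [embed_2d()]).
#' @param band uncertainty band on the assignment probability, default
#'   `c(0.4, 0.6)`.
#' @param ad_label which reference class counts as AD; defaults to the
#'   sorted-last reference class.
#' @param seed master seed; repeat seeds are derived from it.
#' @return Object of class `stratification`: data frame `assignments`
#'   (subject, `p_ad_like`, `final_label`), the per-repeat label matrix
#'   `repeat_labels`, and the settings used.
#' @export
stability_stratify <- function(peptides, panel, ref_idx, ref_labels, query_idx,
                               repeats = 100L, k = 5L, perplexity = 30,
                               max_iter = 1000L, band = c(0.4, 0.6),
                               ad_label = NULL, seed = 1L) {
  if (repeats < 1L) stop("repeats must be at least 1", call. = FALSE)
  classes <- sort(unique(as.character(ref_labels)))
  if (is.null(ad_label)) ad_label <- classes[length(classes)]
  if (!ad_label %in% classes) stop("ad_label not among reference labels", call. = FALSE)
  # canonical (sorted) subject order inside the embedding, so results do not
  # depend on the order queries are listed in
  ord <- order(c(ref_idx, query_idx))
  all_idx <- c(ref_idx, query_idx)[ord]
  is_ref <- c(rep(TRUE, length(ref_idx)), rep(FALSE, length(query_idx)))[ord]
  ref_lab_sorted <- as.character(ref_labels)[order(ref_idx)]
  x <- standardize_matrix(log(peptides[all_idx, panel, drop = FALSE]))
  ref_pos <- which(is_ref)
  query_pos <- which(!is_ref)

  lab_mat <- matrix(NA_character_, length(query_idx), repeats)
  for (r in seq_len(repeats)) {
    emb <- embed_2d(x, perplexity = perplexity, max_iter = max_iter,
                    seed = derive_seed(seed, r))
    asg <- knn_assign(emb$coords, ref_pos, ref_lab_sorted, query_pos, k = k)
    # map back from canonical order to the caller's query order
    lab_mat[, r] <- asg$label[match(query_idx, all_idx[query_pos])]
  }
  p_ad <- rowMeans(lab_mat == ad_label)
  final <- ifelse(p_ad > band[2], "AD-like",
           ifelse(p_ad < band[1], "Control-like", "uncertain"))
  ids <- rownames(peptides)[query_idx]
  if (is.null(ids)) ids <- as.character(query_idx)
  assignments <- data.frame(subject = ids, query = query_idx,
                            p_ad_like = p_ad, final_label = final,
                            stringsAsFactors = FALSE)
  structure(list(assignments = assignments, repeat_labels = lab_mat,
                 repeats = repeats, k = k, band = band, ad_label = ad_label,
                 panel = panel, seed = seed),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  tab <- table(factor(x$assignments$final_label,
                      levels = c("Control-like", "uncertain", "AD-like")))
  cat("Stability stratification:", nrow(x$assignments), "query subjects,",
      x$repeats, "repeats, k =", x$k, "\n")
  cat(sprintf("  Control-like %d | uncertain %d | AD-like %d (band %.2f-%.2f)\n",
              tab[["Control-like"]], tab[["uncertain"]], tab[["AD-like"]],
              x$band[1], x$band[2]))
  invisible(x)
}

#' APOE genotype enrichment between subgroups
#'
#' Builds the genotype x subgroup contingency table, tests it with Fisher's
#' exact test (two-sided, exact enumeration), and reports the epsilon-4
#' allele frequency per subgroup.
#'
#' @param genotypes character vector of genotypes, e.g. `"e3/e4"`.
#' @param subgroup two-level grouping vector, same length.
#' @return List: `table` (genotype x subgroup), `p` (Fisher exact),
#'   `allele_freq` (named epsilon-4 allele frequency per subgroup).
#' @export
apoe_enrichment <- function(genotypes, subgroup) {
  stopifnot(length(genotypes) == length(subgroup))
  sub <- factor(subgroup)
  if (nlevels(sub) != 2L) stop("exactly two subgroups required", call. = FALSE)
  if (any(table(sub) == 0L)) stop("empty subgroup", call. = FALSE)
  tab <- table(genotype = factor(genotypes), subgroup = sub)
  p <- fisher.test(tab, workspace = 2e7)$p.value
  e4_count <- function(g) {
    alleles <- unlist(strsplit(g, "/", fixed = TRUE))
    sum(alleles == "e4") / length(alleles)
  }
  freq <- vapply(levels(sub), function(lv) e4_count(genotypes[sub == lv]),
                 numeric(1))
  list(table = tab, p = p, allele_freq = freq)
}
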