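#' Pipeline configuration
#'
#' Collects every stage parameter with the package's standard defaults:
#' tTau:Abeta42 gating at a strict `> 0.24` cutoff (or `"auto"` to derive it
#' from the cohort by Gaussian mixture), RFE stop size 14 per classifier,
#' permutation null of 100,000 random panels, stratification with 100
#' embedding repeats and k = 5 neighbours, a 5-peptide JMI target, 6-fold
#' cross-validation and Benjamini-Hochberg FDR at 20%.
#'
#' @param subjects_csv,peptides_csv optional input CSV paths; when `NULL` a
#'   synthetic cohort is generated from `spec`.
#' @param spec a [cohort_spec()] used when no input files are given.
#' @param cutoff `"auto"` or a positive number.
#' @param ratio_on_log_scale fit the mixture on the log ratio scale.
#' @param stop_size RFE stopping size.
#' @param B permutation-null panel count.
#' @param repeats stratification embedding repeats.
#' @param k KNN neighbours.
#' @param perplexity t-SNE perplexity.
#' @param target_size JMI panel size.
#' @param bins JMI discretization bins.
#' @param folds cross-validation folds.
#' @param q FDR level.
#' @param fraction training fraction for the 80/20 splits.
#' @param band stratification uncertainty band.
#' @param regression_B bootstrap replicates for median-regression inference.
#' @param seed master seed; all stage seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(subjects_csv = NULL, peptides_csv = NULL,
                            spec = cohort_spec(), cutoff = 0.24,
                            ratio_on_log_scale = FALSE,
                            stop_size = 14L, B = 100000L, repeats = 100L,
                            k = 5L, perplexity = 30, target_size = 5L,
                            bins = 5L, folds = 6L, q = 0.20, fraction = 0.8,
                            band = c(0.4, 0.6), regression_B = 1000L,
                            seed = 1L) {
  if (!identical(cutoff, "auto") && (!is.numeric(cutoff) || cutoff <= 0))
    stop("cutoff must be 'auto' or a positive number", call. = FALSE)
  for (pth in c(subjects_csv, peptides_csv))
    if (!is.null(pth) && !file.exists(pth))
      stop("input file not found: ", pth, call. = FALSE)
  if (stop_size >= spec$n_peptides)
    stop("stop_size must be smaller than the number of peptides", call. = FALSE)
  if (target_size >= spec$n_peptides)
    stop("target_size must be smaller than the number of peptides", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  structure(list(subjects_csv = subjects_csv, peptides_csv = peptides_csv,
                 spec = spec, cutoff = cutoff,
                 ratio_on_log_scale = ratio_on_log_scale,
                 stop_size = as.integer(stop_size), B = as.integer(B),
                 repeats = as.integer(repeats), k = as.integer(k),
                 perplexity = perplexity, target_size = as.integer(target_size),
                 bins = as.integer(bins), folds = as.integer(folds), q = q,
                 fraction = fraction, band = band,
                 regression_B = as.integer(regression_B),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate pipeline input tables
#'
#' Schema checks for the subject and peptide CSVs: required columns, numeric
#' types, analyte positivity (with row numbers) and subject-id alignment
#' between the two tables. All violations are collected, not just the first.
#'
#' @param subjects_csv,peptides_csv file paths.
#' @return Data frame with columns `component` and `message`; zero rows means
#'   the inputs are valid.
#' @export
validate_inputs <- function(subjects_csv, peptides_csv) {
  for (pth in c(subjects_csv, peptides_csv))
    if (!file.exists(pth)) stop("unreadable file: ", pth, call. = FALSE)
  subj <- read.csv(subjects_csv, stringsAsFactors = FALSE)
  pept <- read.csv(peptides_csv, check.names = FALSE, stringsAsFactors = FALSE)
  v <- list()
  note <- function(component, msg)
    v[[length(v) + 1L]] <<- data.frame(component = component, message = msg,
                                       stringsAsFactors = FALSE)
  need <- c("subject_id", "cognitive_status", "abeta42", "ttau", "ptau")
  for (cl in setdiff(need, names(subj)))
    note("subjects", paste("missing column:", cl))
  for (cl in intersect(c("abeta42", "ttau", "ptau"), names(subj))) {
    if (!is.numeric(subj[[cl]])) {
      note("subjects", paste("column not numeric:", cl))
    } else {
      bad <- which(!is.na(subj[[cl]]) & subj[[cl]] <= 0)
      for (r in bad) note("subjects", paste0("non-positive ", cl, " at row ", r))
    }
  }
  if (names(pept)[1] != "subject_id")
    note("peptides", "first column must be subject_id")
  pcols <- setdiff(names(pept), "subject_id")
  nonnum <- pcols[!vapply(pept[pcols], is.numeric, logical(1))]
  for (cl in nonnum) note("peptides", paste("column not numeric:", cl))
  if ("subject_id" %in% names(subj) && "subject_id" %in% names(pept)) {
    for (id in setdiff(subj$subject_id, pept$subject_id))
      note("alignment", paste("subject missing from peptide matrix:", id))
    for (id in setdiff(pept$subject_id, subj$subject_id))
      note("alignment", paste("subject missing from subject table:", id))
  }
  if (!length(v))
    return(data.frame(component = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Run the full stratification pipeline
#'
#' Orchestrates the six stages — synthesize (or load), gate, select,
#' stratify, JMI, cohort statistics — writing each stage's outputs and a JSON
#' manifest of parameters, seeds and output files into `out_dir`. Rerunning
#' with the same configuration reproduces every output.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return Object of class `pipeline_run`: the per-stage results plus the
#'   `manifest` list.
#' @export
run_pipeline <- function(config, out_dir = tempfile("csfstrat_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "csfstrat", seed = config$seed, stages = list())
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      err <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(err, file.path(out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  # 1. cohort -----------------------------------------------------------
  cohort <- stage("synthesize", function() {
    if (!is.null(config$subjects_csv)) {
      subjects <- read.csv(config$subjects_csv, stringsAsFactors = FALSE)
      pept <- read.csv(config$peptides_csv, check.names = FALSE,
                       stringsAsFactors = FALSE)
      m <- as.matrix(pept[, -1, drop = FALSE])
      rownames(m) <- pept[[1]]
      m <- m[subjects$subject_id, , drop = FALSE]
      list(subjects = subjects, peptides = m, ground_truth = NULL)
    } else {
      spec <- config$spec
      spec$seed <- derive_seed(config$seed, 1L)
      co <- generate_cohort(spec)
      write_cohort(co, out_dir)
      co
    }
  })
  manifest$stages$synthesize <- list(
    seed = derive_seed(config$seed, 1L),
    n_subjects = nrow(cohort$subjects), n_peptides = ncol(cohort$peptides),
    outputs = c("subjects.csv", "peptides.csv"))

  # 2. gate --------------------------------------------------------------
  gated <- stage("gate", function() {
    ratio <- cohort$subjects$ttau / cohort$subjects$abeta42
    model <- NULL
    cutoff <- config$cutoff
    if (identical(cutoff, "auto")) {
      # derive the cutoff from the cognitively normal subjects, whose ratio
      # distribution is the bimodal negative/positive mixture
      normal <- cohort$subjects$cognitive_status == "normal"
      model <- fit_ratio_mixture(ratio[normal],
                                 on_log_scale = config$ratio_on_log_scale,
                                 seed = derive_seed(config$seed, 2L))
      if (!model$bimodal)
        stop("ratio distribution not bimodal; no cutoff derivable")
      cutoff <- model$cutoff
    }
    labels <- gate_subjects(cohort$subjects, cutoff)
    write.csv(data.frame(subject_id = cohort$subjects$subject_id,
                         ratio = ratio, group = as.character(labels)),
              file.path(out_dir, "gated.csv"), row.names = FALSE)
    if (!is.null(model))
      jsonlite::write_json(model[c("weights", "means", "sds", "cutoff",
                                   "loglik", "converged", "bimodal")],
                           file.path(out_dir, "cutoff_model.json"),
                           auto_unbox = TRUE, digits = NA)
    list(labels = labels, cutoff = cutoff, model = model)
  })
  manifest$stages$gate <- list(cutoff = gated$cutoff,
                               outputs = "gated.csv")

  # 3. select ------------------------------------------------------------
  selection <- stage("select", function() {
    ref <- which(gated$labels %in% c("CN/BM-", "AD"))
    sel <- select_panel(cohort$peptides[ref, , drop = FALSE],
                        gated$labels[ref], stop_size = config$stop_size,
                        fraction = config$fraction,
                        seed = derive_seed(config$seed, 3L), positive = "AD")
    pn <- permutation_null(cohort$peptides[ref, , drop = FALSE],
                           gated$labels[ref], sel$panel, sel$split$train,
                           sel$split$test, B = config$B,
                           seed = derive_seed(config$seed, 4L),
                           positive = "AD", observed = sel$metrics)
    jsonlite::write_json(list(panel = sel$panel,
                              svm = sel$rfe_svm$selected,
                              logistic = sel$rfe_logistic$selected,
                              metrics = sel$metrics[c("accuracy", "precision",
                                                      "recall", "auc")],
                              permutation_p = as.list(pn$p)),
                         file.path(out_dir, "panel.json"),
                         auto_unbox = TRUE, digits = NA)
    list(selection = sel, null = pn, ref = ref)
  })
  manifest$stages$select <- list(
    seed = derive_seed(config$seed, 3L), stop_size = config$stop_size,
    B = config$B, panel = selection$selection$panel, outputs = "panel.json")

  # 4. stratify ----------------------------------------------------------
  strat <- stage("stratify", function() {
    ref <- which(gated$labels %in% c("CN/BM-", "AD"))
    qry <- which(gated$labels == "AsymAD")
    st <- stability_stratify(cohort$peptides, selection$selection$panel,
                             ref, gated$labels[ref], qry,
                             repeats = config$repeats, k = config$k,
                             perplexity = config$perplexity,
                             band = config$band, ad_label = "AD",
                             seed = derive_seed(config$seed, 5L))
    write.csv(st$assignments[c("subject", "p_ad_like", "final_label")],
              file.path(out_dir, "stratification.csv"), row.names = FALSE)
    st
  })
  manifest$stages$stratify <- list(
    seed = derive_seed(config$seed, 5L), repeats = config$repeats,
    k = config$k, outputs = "stratification.csv")

  # 5. jmi ---------------------------------------------------------------
  jmi <- stage("jmi", function() {
    keep <- strat$assignments$final_label != "uncertain"
    idx <- strat$assignments$query[keep]
    lab <- strat$assignments$final_label[keep]
    split <- split_train_test(lab, config$fraction,
                              seed = derive_seed(config$seed, 6L))
    xtr <- log(cohort$peptides[idx[split$train], , drop = FALSE])
    sel <- jmi_select(xtr, lab[split$train], target_size = config$target_size,
                      bins = config$bins)
    m <- evaluate_panel(cohort$peptides[idx, , drop = FALSE], lab,
                        sel$selected, split$train, split$test,
                        positive = "AD-like")
    cv <- cross_validated_roc(cohort$peptides[idx, , drop = FALSE], lab,
                              sel$selected, k = config$folds,
                              seed = derive_seed(config$seed, 7L),
                              positive = "AD-like")
    jsonlite::write_json(list(panel = sel$selected, scores = sel$scores,
                              holdout_accuracy = m$accuracy,
                              cv_mean_auc = cv$mean_auc, cv_se = cv$se),
                         file.path(out_dir, "jmi.json"), auto_unbox = TRUE,
                         digits = NA)
    list(selection = sel, metrics = m, cv = cv, idx = idx, labels = lab)
  })
  manifest$stages$jmi <- list(
    seed = derive_seed(config$seed, 6L), target_size = config$target_size,
    bins = config$bins, folds = config$folds, outputs = "jmi.json")

  # 6. stats -------------------------------------------------------------
  stats_tab <- stage("stats", function() {
    pan <- analyte_panel(cohort$subjects)
    analytes <- pan[c("z_ttau", "z_ptau", "z_abeta42", "z_ttau_abeta42",
                      "z_ptau_abeta42")]
    outcomes <- intersect(names(default_cognition_params()),
                          names(cohort$subjects))
    tab <- regression_table(cohort$subjects, outcomes, analytes,
                            q = config$q, B = config$regression_B,
                            seed = derive_seed(config$seed, 8L))
    write.csv(tab, file.path(out_dir, "regressions.csv"), row.names = FALSE)
    tab
  })
  manifest$stages$stats <- list(
    seed = derive_seed(config$seed, 8L), q = config$q,
    outputs = "regressions.csv")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(cohort = cohort, gate = gated, selection = selection,
                 stratification = strat, jmi = jmi, regressions = stats_tab,
                 manifest = manifest, out_dir = out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("csfstrat pipeline run (", length(x$manifest$stages), " stages) -> ",
      x$out_dir, "\n", sep = "")
  cat("  cutoff:", signif(x$gate$cutoff, 4),
      "| panel:", paste(x$selection$selection$panel, collapse = ", "), "\n")
  cat(sprintf("  held-out AUC %.3f | JMI panel: %s | subgroup accuracy %.3f\n",
              x$selection$selection$metrics$auc,
              paste(x$jmi$selection$selected, collapse = ", "),
              x$jmi$metrics$accuracy))
  invisible(x)
}
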