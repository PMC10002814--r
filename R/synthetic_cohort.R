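#' Specify a synthetic CSF cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. Defaults
#' emulate a matched three-group CSF biomarker study: cognitively normal
#' biomarker-negative controls (`control`), cognitively normal biomarker-positive
#' cases (`asymad`, asymptomatic Alzheimer's disease), and biomarker-confirmed
#' symptomatic AD (`ad`), 134 subjects per group, with a 75-peptide targeted
#' proteomic panel of which 8 peptides carry a 2-SD group shift on the log
#' scale.
#'
#' Analyte parameters (medians and interquartile ranges for the tTau:Abeta42
#' ratio, Abeta42 and pTau, in pg/ml) and APOE epsilon-4 allele frequencies
#' default to values typical of a middle-aged biomarker-stratified cohort:
#' ratio medians 0.12 / 0.31 / 0.64 and epsilon-4 frequencies 0.08 / 0.40 /
#' 0.50 for control / asymad / ad. AsymAD subjects sit on a latent
#' Control-to-AD continuum `u in [0, 1]`: their peptide centroid interpolates
#' between the control and AD centroids, and their per-subject epsilon-4
#' allele frequency rises with `u`.
#'
#' @param n_control,n_asymad,n_ad group sizes (all positive).
#' @param n_peptides number of peptides in the panel.
#' @param informative_peptides integer indices of peptides carrying a group
#'   shift.
#' @param effect_sizes log-scale AD-vs-control mean shifts in SD units, one per
#'   informative peptide; signs alternate by default (up- and down-regulated
#'   peptides).
#' @param peptide_sd log-scale within-group SD of peptide abundances.
#' @param n_latent_factors,factor_sd optional low-rank shared covariance:
#'   number of latent factors and loading SD (0 = diagonal covariance).
#' @param asymad_latent_mix parameters of the latent-position mixture
#'   `weight * Beta(a1, b1) + (1 - weight) * Beta(a2, b2)`.
#' @param apoe_e4_freq named per-group epsilon-4 allele frequencies.
#' @param apoe_e2_freq epsilon-2 share of the non-epsilon-4 allele mass.
#' @param apoe_u_slope log-odds slope coupling AsymAD epsilon-4 frequency to
#'   the latent position `u`.
#' @param apoe_peptides optional list linking two pseudo-peptides to APOE
#'   genotype: `list(e4 = index, e2e3 = index, effect = SD-per-allele)`. The
#'   `e4` peptide rises with epsilon-4 allele dosage, the `e2e3` peptide with
#'   the number of non-epsilon-4 alleles.
#' @param analyte_params per-group `list(ratio =, abeta42 =, ptau = c(median,
#'   iqr_lo, iqr_hi))`; see defaults.
#' @param ratio_gate boundary separating the biomarker-negative and -positive
#'   ratio components; group ratio distributions are truncated on their side
#'   of it.
#' @param cognition named list per score: `list(intercept =, ttau =, ptau =,
#'   noise_sd =, noise_shape =)` giving loadings on standardized tTau/pTau and
#'   a right-skewed (shifted-gamma) noise spec.
#' @param comorbidity_logits named list per condition: `c(intercept, beta)`
#'   where `beta` multiplies standardized Abeta42.
#' @param seed RNG seed; identical spec objects generate identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_control = 134L, n_asymad = 134L, n_ad = 134L,
                        n_peptides = 75L,
                        informative_peptides = c(3L, 11L, 19L, 28L, 36L, 44L, 53L, 62L),
                        effect_sizes = 2 * (-1)^(seq_along(informative_peptides) + 1),
                        peptide_sd = 0.5,
                        n_latent_factors = 0L, factor_sd = 0.3,
                        asymad_latent_mix = list(weight = 0.5, a1 = 2, b1 = 5,
                                                 a2 = 5, b2 = 2),
                        apoe_e4_freq = c(control = 0.08, asymad = 0.40, ad = 0.50),
                        apoe_e2_freq = 0.08,
                        apoe_u_slope = 3,
                        apoe_peptides = NULL,
                        analyte_params = default_analyte_params(),
                        ratio_gate = 0.24,
                        cognition = default_cognition_params(),
                        comorbidity_logits = list(
                          dyslipidemia = c(0.2, -0.35),
                          diabetes     = c(-2.4, -0.40),
                          hypertension = c(-0.7, 0)),
                        seed = 1L) {
  counts <- c(n_control = n_control, n_asymad = n_asymad, n_ad = n_ad)
  if (any(counts <= 0)) stop("all group counts must be positive", call. = FALSE)
  informative_peptides <- as.integer(informative_peptides)
  if (length(informative_peptides) &&
      (min(informative_peptides) < 1L || max(informative_peptides) > n_peptides))
    stop("informative_peptides must lie in 1..n_peptides", call. = FALSE)
  if (length(effect_sizes) != length(informative_peptides))
    stop("effect_sizes must match informative_peptides in length", call. = FALSE)
  if (any(!is.finite(effect_sizes))) stop("effect sizes must be finite", call. = FALSE)
  if (any(apoe_e4_freq < 0 | apoe_e4_freq > 1))
    stop("allele frequencies must be in [0, 1]", call. = FALSE)
  structure(list(
    n_control = as.integer(n_control), n_asymad = as.integer(n_asymad),
    n_ad = as.integer(n_ad), n_peptides = as.integer(n_peptides),
    informative_peptides = informative_peptides, effect_sizes = effect_sizes,
    peptide_sd = peptide_sd, n_latent_factors = as.integer(n_latent_factors),
    factor_sd = factor_sd, asymad_latent_mix = asymad_latent_mix,
    apoe_e4_freq = apoe_e4_freq, apoe_e2_freq = apoe_e2_freq,
    apoe_u_slope = apoe_u_slope, apoe_peptides = apoe_peptides,
    analyte_params = analyte_params, ratio_gate = ratio_gate,
    cognition = cognition, comorbidity_logits = comorbidity_logits,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Group-wise analyte calibration targets: median and interquartile range, in
# pg/ml. tTau and Abeta42 are drawn independently within group; the implied
# ratio medians (ttau/abeta42: 0.119, 0.327, 0.635) match the usual
# negative / asymptomatic / symptomatic ordering.
default_analyte_params <- function() {
  list(
    control = list(abeta42 = c(1412, 1192, 1700),
                   ttau   = c(167.6, 139.9, 192.7),
                   ptau   = c(14.8, 12.2, 17.2)),
    asymad  = list(abeta42 = c(740.1, 609.8, 862.5),
                   ttau   = c(242.0, 194.9, 299.4),
                   ptau   = c(22.8, 18.6, 28.2)),
    ad      = list(abeta42 = c(540.7, 445.6, 660.2),
                   ttau   = c(343.2, 265.7, 458.5),
                   ptau   = c(33.9, 26.7, 47.3))
  )
}

# Cognitive scores as linear functions of standardized tTau/pTau with
# right-skewed noise. Visuospatial / visual-memory scores load on tau;
# verbal list learning (avlt) deliberately loads on nothing, and no score
# loads on Abeta42.
default_cognition_params <- function() {
  list(
    moca           = list(intercept = 27.0, ttau = -0.22, ptau = -0.23, noise_sd = 2.0, noise_shape = 2),
    rcft_immediate = list(intercept = 16.5, ttau = -0.91, ptau = -0.92, noise_sd = 5.0, noise_shape = 2),
    rcft_delayed   = list(intercept = 16.0, ttau = -0.52, ptau = -0.62, noise_sd = 5.0, noise_shape = 2),
    avlt_immediate = list(intercept = 9.0,  ttau = 0,     ptau = 0,     noise_sd = 3.0, noise_shape = 2),
    avlt_delayed   = list(intercept = 5.5,  ttau = 0,     ptau = 0,     noise_sd = 2.5, noise_shape = 2),
    jolo           = list(intercept = 25.5, ttau = -0.29, ptau = -0.37, noise_sd = 3.0, noise_shape = 2)
  )
}

# median/IQR -> log-normal location/scale
lnorm_pars <- function(triple) {
  meanlog <- log(triple[1])
  sdlog <- log(triple[3] / triple[2]) / (2 * qnorm(0.75))
  c(meanlog = meanlog, sdlog = max(sdlog, 1e-6))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a subject table, a peptide abundance matrix and the generating ground
#' truth from a [cohort_spec()]. Peptide abundances are multivariate normal on
#' the log scale (diagonal covariance plus an optional low-rank shared factor)
#' and exponentiated; AsymAD subjects interpolate between the control and AD
#' log-centroids at their latent position `u`. tTau and Abeta42 are
#' independent log-normals within group, rejection-resampled so that every
#' control falls below the ratio gate and every AsymAD/AD subject above it;
#' the cohort tTau:Abeta42 distribution is therefore bimodal with all AsymAD
#' and AD subjects in the biomarker-positive component. APOE genotypes follow
#' Hardy-Weinberg proportions at the group (or, for AsymAD, `u`-linked) allele
#' frequencies.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `csf_cohort`: a list with
#'   \describe{
#'     \item{subjects}{data frame of demographics, APOE genotype, analytes,
#'       cognitive scores and comorbidity flags; `cognitive_status` is
#'       `"normal"` except for the AD group.}
#'     \item{peptides}{numeric matrix (subjects x peptides) of positive
#'       abundances, rownames = subject ids.}
#'     \item{ground_truth}{list: `informative_set`, per-subject latent `u`,
#'       `true_subgroup` (AD-like iff u > 0.5, NA outside AsymAD), and the
#'       planted cognition/comorbidity coefficients.}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_control + spec$n_asymad + spec$n_ad
  p <- spec$n_peptides
  group <- rep(c("control", "asymad", "ad"),
               times = c(spec$n_control, spec$n_asymad, spec$n_ad))

  # latent Control->AD position
  u <- numeric(n)
  u[group == "ad"] <- 1
  mx <- spec$asymad_latent_mix
  na_ <- spec$n_asymad
  from_first <- runif(na_) < mx$weight
  u[group == "asymad"] <- ifelse(from_first,
                                 rbeta(na_, mx$a1, mx$b1),
                                 rbeta(na_, mx$a2, mx$b2))

  # peptide log-centroids
  baseline <- rnorm(p, mean = 7, sd = 1)
  shift <- numeric(p)
  shift[spec$informative_peptides] <- spec$effect_sizes * spec$peptide_sd
  mu_ad <- baseline + shift
  centroid <- outer(1 - u, baseline) + outer(u, mu_ad)
  log_x <- centroid + matrix(rnorm(n * p, sd = spec$peptide_sd), n, p)
  if (spec$n_latent_factors > 0L) {
    load <- matrix(rnorm(p * spec$n_latent_factors, sd = spec$factor_sd),
                   p, spec$n_latent_factors)
    fac <- matrix(rnorm(n * spec$n_latent_factors), n, spec$n_latent_factors)
    log_x <- log_x + fac %*% t(load)
  }

  # APOE genotypes (Hardy-Weinberg at per-subject allele frequencies)
  p4 <- spec$apoe_e4_freq[match(group, names(spec$apoe_e4_freq))]
  is_asym <- group == "asymad"
  p4[is_asym] <- plogis(qlogis(spec$apoe_e4_freq[["asymad"]]) +
                          spec$apoe_u_slope * (u[is_asym] - 0.5))
  draw_allele <- function(pr4) {
    r <- runif(length(pr4))
    ifelse(r < pr4, "e4",
           ifelse(r < pr4 + (1 - pr4) * spec$apoe_e2_freq, "e2", "e3"))
  }
  a1 <- draw_allele(p4); a2 <- draw_allele(p4)
  genotype <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  n_e4 <- (a1 == "e4") + (a2 == "e4")

  if (!is.null(spec$apoe_peptides)) {
    ap <- spec$apoe_peptides
    log_x[, ap$e4]   <- log_x[, ap$e4]   + ap$effect * spec$peptide_sd * n_e4
    log_x[, ap$e2e3] <- log_x[, ap$e2e3] + ap$effect * spec$peptide_sd * (2 - n_e4)
  }
  peptides <- exp(log_x)

  # CSF analytes: tTau and Abeta42 independent log-normals within group,
  # rejection-resampled until each subject's tTau:Abeta42 ratio lies on the
  # group's side of the gate (below for controls, above otherwise), keeping
  # the cohort ratio distribution bimodal and consistent with gating.
  abeta42 <- ttau <- ptau <- numeric(n)
  for (g in c("control", "asymad", "ad")) {
    idx <- which(group == g)
    prm <- spec$analyte_params[[g]]
    ap_ <- lnorm_pars(prm$abeta42)
    tp <- lnorm_pars(prm$ttau)
    a <- rlnorm(length(idx), ap_[1], ap_[2])
    t_ <- rlnorm(length(idx), tp[1], tp[2])
    positive_side <- g != "control"
    for (iter in seq_len(1000L)) {
      bad <- if (positive_side) t_ / a <= spec$ratio_gate
             else t_ / a > spec$ratio_gate
      if (!any(bad)) break
      a[bad] <- rlnorm(sum(bad), ap_[1], ap_[2])
      t_[bad] <- rlnorm(sum(bad), tp[1], tp[2])
    }
    abeta42[idx] <- a
    ttau[idx] <- t_
    pp <- lnorm_pars(prm$ptau)
    ptau[idx] <- rlnorm(length(idx), pp[1], pp[2])
  }

  # cognition: loadings on cohort-standardized tau measures + skewed noise
  z_t <- as.numeric(scale(ttau)); z_p <- as.numeric(scale(ptau))
  cogn <- lapply(spec$cognition, function(cs) {
    g <- rgamma(n, shape = cs$noise_shape, rate = 1)
    noise <- (g - qgamma(0.5, cs$noise_shape, rate = 1)) /
      sqrt(cs$noise_shape) * cs$noise_sd
    cs$intercept + cs$ttau * z_t + cs$ptau * z_p + noise
  })

  # comorbidities: logistic on standardized Abeta42
  z_a <- as.numeric(scale(abeta42))
  comorb <- lapply(spec$comorbidity_logits, function(cl) {
    rbinom(n, 1L, plogis(cl[1] + cl[2] * z_a))
  })

  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group,
    cognitive_status = ifelse(group == "ad", "impaired", "normal"),
    age = round(rnorm(n, 66, 5.8), 1),
    sex = ifelse(runif(n) < 0.75, "F", "M"),
    race = sample(c("Caucasian", "AfricanAmerican", "Asian"), n, TRUE,
                  prob = c(0.925, 0.067, 0.008)),
    education = pmax(8, round(rnorm(n, ifelse(group == "ad", 15.4, 16.7), 2.2))),
    apoe = genotype,
    abeta42 = abeta42, ttau = ttau, ptau = ptau,
    stringsAsFactors = FALSE
  )
  for (nm in names(cogn)) subjects[[nm]] <- cogn[[nm]]
  for (nm in names(comorb)) subjects[[nm]] <- comorb[[nm]]

  rownames(peptides) <- subjects$subject_id
  colnames(peptides) <- sprintf("PEP%03d", seq_len(p))

  gt <- list(
    informative_set = spec$informative_peptides,
    u = setNames(u, subjects$subject_id),
    true_subgroup = ifelse(group == "asymad",
                           ifelse(u > 0.5, "AD-like", "Control-like"), NA),
    cognition_coefficients = spec$cognition,
    comorbidity_coefficients = spec$comorbidity_logits
  )
  structure(list(subjects = subjects, peptides = peptides, ground_truth = gt,
                 spec = spec),
            class = "csf_cohort")
}

#' @export
print.csf_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("Synthetic CSF cohort:", nrow(x$subjects), "subjects,",
      ncol(x$peptides), "peptides\n")
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  informative peptides:",
      paste(colnames(x$peptides)[x$ground_truth$informative_set], collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `subjects.csv`, `peptides.csv` (subject id in the first column) and
#' `ground_truth.csv` into `dir`.
#'
#' @param cohort a `csf_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "csf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("subjects.csv", "peptides.csv", "ground_truth.csv"))
  write.csv(cohort$subjects, paths[1], row.names = FALSE)
  write.csv(data.frame(subject_id = rownames(cohort$peptides),
                       cohort$peptides, check.names = FALSE),
            paths[2], row.names = FALSE)
  gt <- data.frame(subject_id = names(cohort$ground_truth$u),
                   u = unname(cohort$ground_truth$u),
                   true_subgroup = unname(cohort$ground_truth$true_subgroup))
  write.csv(gt, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Greedy 1:1 matched-group pairing
#'
#' Pairs each case with the nearest unused control: exact agreement on
#' categorical variables, scaled (per-variable SD) distance on continuous
#' ones, with an optional per-variable caliper. Cases are processed in
#' descending order of difficulty (distance to their nearest eligible control
#' before any assignment), so hard-to-match cases choose first; the result is
#' deterministic.
#'
#' @param subjects subject data frame.
#' @param case_group,control_group values of `subjects$group` to pair.
#' @param match_on character vector of matching variables.
#' @param caliper named numeric vector of per-variable tolerances on the raw
#'   scale (continuous variables only); variables absent from it are
#'   unrestricted.
#' @return Data frame with columns `case`, `control` (row indices into
#'   `subjects`) and `distance`; unmatched case indices are attached as
#'   `attr(, "unmatched")` and reported in a warning.
#' @export
match_groups <- function(subjects, case_group, control_group, match_on,
                         caliper = NULL) {
  if (!all(match_on %in% names(subjects)))
    stop("matching variables missing from subject table", call. = FALSE)
  cases <- which(subjects$group == case_group)
  ctrls <- which(subjects$group == control_group)
  if (!length(cases) || !length(ctrls))
    stop("both groups must be non-empty", call. = FALSE)

  is_cat <- vapply(subjects[match_on], function(v) !is.numeric(v), logical(1))
  num_vars <- match_on[!is_cat]
  cat_vars <- match_on[is_cat]
  sds <- vapply(subjects[num_vars], function(v) {
    s <- sd(v[c(cases, ctrls)]); if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))

  # pairwise case x control distance; Inf where ineligible
  D <- matrix(0, length(cases), length(ctrls))
  for (v in num_vars) {
    d <- abs(outer(subjects[[v]][cases], subjects[[v]][ctrls], `-`))
    cal <- if (!is.null(caliper) && v %in% names(caliper)) caliper[[v]] else Inf
    d[d > cal] <- Inf
    D <- D + (d / sds[[v]])^2
  }
  for (v in cat_vars) {
    mism <- outer(as.character(subjects[[v]][cases]),
                  as.character(subjects[[v]][ctrls]), `!=`)
    D[mism] <- Inf
  }
  D <- sqrt(D)

  difficulty <- apply(D, 1, min)
  order_cases <- order(-difficulty, cases)  # hardest first; index tie-break
  used <- logical(length(ctrls))
  out <- data.frame(case = integer(0), control = integer(0), distance = numeric(0))
  unmatched <- integer(0)
  for (i in order_cases) {
    d <- D[i, ]
    d[used] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) {
      unmatched <- c(unmatched, cases[i])
      next
    }
    used[j] <- TRUE
    out <- rbind(out, data.frame(case = cases[i], control = ctrls[j],
                                 distance = d[j]))
  }
  out <- out[order(out$case), , drop = FALSE]
  rownames(out) <- NULL
  if (length(unmatched))
    warning(length(unmatched), " case(s) could not be matched within caliper",
            call. = FALSE)
  attr(out, "unmatched") <- sort(unmatched)
  out
}
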