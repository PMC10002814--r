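test_that("identical spec and seed reproduce the cohort byte-identically", {
  a <- generate_cohort(small_spec(seed = 42))
  b <- generate_cohort(small_spec(seed = 42))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$peptides, b$peptides)
  expect_identical(a$ground_truth, b$ground_truth)
  d <- generate_cohort(small_spec(seed = 43))
  expect_false(identical(a$peptides, d$peptides))
})

test_that("spec validation rejects impossible cohorts", {
  expect_error(cohort_spec(n_control = 0), "positive")
  expect_error(cohort_spec(informative_peptides = c(1, 99)), "1..n_peptides")
  expect_error(cohort_spec(informative_peptides = 1:3,
                           effect_sizes = c(1, 2)), "length")
  expect_error(cohort_spec(apoe_e4_freq = c(control = -0.1, asymad = 0.4,
                                            ad = 0.5)), "frequencies")
})

test_that("realized APOE e4 allele frequencies hit the per-group targets", {
  spec <- cohort_spec(n_control = 500L, n_asymad = 500L, n_ad = 500L,
                      n_peptides = 10L, informative_peptides = integer(0),
                      effect_sizes = numeric(0), seed = 5)
  co <- generate_cohort(spec)
  e4 <- function(g) {
    al <- unlist(strsplit(co$subjects$apoe[co$subjects$group == g], "/"))
    mean(al == "e4")
  }
  targets <- c(control = 0.08, asymad = 0.40, ad = 0.50)
  for (g in names(targets)) {
    se <- sqrt(targets[[g]] * (1 - targets[[g]]) / 1000)  # 2n alleles
    expect_lt(abs(e4(g) - targets[[g]]), 4 * se)
  }
})

test_that("zero effect sizes give a null peptide generator", {
  spec <- cohort_spec(n_control = 200L, n_asymad = 2L, n_ad = 200L,
                      n_peptides = 20L, informative_peptides = integer(0),
                      effect_sizes = numeric(0), seed = 9)
  co <- generate_cohort(spec)
  g <- co$subjects$group
  lx <- log(co$peptides)
  tstats <- vapply(seq_len(20), function(j)
    unname(t.test(lx[g == "ad", j], lx[g == "control", j])$statistic),
    numeric(1))
  expect_true(all(abs(tstats) < 4.5))
})

test_that("informative peptides dominate group-mean t statistics", {
  spec <- cohort_spec(n_control = 200L, n_asymad = 2L, n_ad = 200L,
                      n_peptides = 30L,
                      informative_peptides = c(3L, 9L, 15L, 21L, 24L, 27L,
                                               29L, 30L),
                      effect_sizes = rep(2, 8), seed = 10)
  co <- generate_cohort(spec)
  g <- co$subjects$group
  lx <- log(co$peptides)
  # direct group-mean computation, not the generator's internals
  tstats <- vapply(seq_len(30), function(j) {
    a <- lx[g == "ad", j]; b <- lx[g == "control", j]
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }, numeric(1))
  inf <- spec$informative_peptides
  expect_gt(min(abs(tstats[inf])), max(abs(tstats[-inf])))
})

test_that("analyte medians are calibrated to the group targets", {
  spec <- cohort_spec(n_control = 500L, n_asymad = 500L, n_ad = 500L,
                      n_peptides = 10L, informative_peptides = integer(0),
                      effect_sizes = numeric(0), seed = 11)
  co <- generate_cohort(spec)
  prm <- co$spec$analyte_params
  for (g in c("control", "asymad", "ad")) {
    sub <- co$subjects[co$subjects$group == g, ]
    for (an in c("abeta42", "ttau", "ptau")) {
      target <- prm[[g]][[an]][1]
      expect_lt(abs(median(sub[[an]]) - target) / target, 0.10,
                label = paste(g, an, "median relative error"))
    }
  }
})

test_that("cohort ratio is bimodal and gate-consistent by construction", {
  co <- generate_cohort(small_spec(seed = 12))
  ratio <- co$subjects$ttau / co$subjects$abeta42
  pos <- co$subjects$group %in% c("asymad", "ad")
  expect_true(all(ratio[pos] > 0.24))
  expect_true(all(ratio[!pos] <= 0.24))
})

test_that("AsymAD vectors approach the AD centroid monotonically in u", {
  spec <- cohort_spec(n_control = 150L, n_asymad = 400L, n_ad = 150L,
                      seed = 13)
  co <- generate_cohort(spec)
  g <- co$subjects$group
  lx <- log(co$peptides)
  ad_centroid <- colMeans(lx[g == "ad", ])
  asym <- which(g == "asymad")
  d <- sqrt(rowSums((lx[asym, ] - matrix(ad_centroid, length(asym),
                                         ncol(lx), byrow = TRUE))^2))
  u <- co$ground_truth$u[asym]
  bins <- cut(u, breaks = seq(0, 1, by = 0.25), include.lowest = TRUE)
  mean_d <- tapply(d, bins, mean)
  expect_true(all(diff(mean_d) < 0))
})

test_that("write_cohort emits aligned CSV files", {
  co <- generate_cohort(small_spec(seed = 14))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  subj <- read.csv(paths[1])
  pept <- read.csv(paths[2], check.names = FALSE)
  expect_identical(subj$subject_id, pept$subject_id)
  expect_equal(nrow(pept), nrow(co$peptides))
})

test_that("matching pairs identical groups perfectly at zero distance", {
  df <- data.frame(group = rep(c("case", "ctrl"), each = 5),
                   age = rep(c(60, 62, 64, 66, 68), 2),
                   sex = rep(c("F", "F", "M", "M", "F"), 2))
  m <- match_groups(df, "case", "ctrl", c("age", "sex"))
  expect_equal(nrow(m), 5)
  expect_true(all(m$distance == 0))
  expect_length(attr(m, "unmatched"), 0)
})

test_that("caliper selects the nearest control within tolerance", {
  df <- data.frame(group = c("case", "ctrl", "ctrl"),
                   age = c(66, 65, 70))
  m <- match_groups(df, "case", "ctrl", "age", caliper = c(age = 2))
  expect_equal(m$control, 2L)  # the 65-year-old
  # caliper too tight: unmatched, with a warning
  expect_warning(m2 <- match_groups(df, "case", "ctrl", "age",
                                    caliper = c(age = 0.5)),
                 "could not be matched")
  expect_equal(attr(m2, "unmatched"), 1L)
})

test_that("greedy matching equals the brute-force greedy oracle", {
  set.seed(31)
  for (rep in 1:5) {
    ages_case <- runif(12, 55, 75)
    ages_ctrl <- runif(20, 55, 75)
    df <- data.frame(group = rep(c("case", "ctrl"), c(12, 20)),
                     age = c(ages_case, ages_ctrl))
    m <- match_groups(df, "case", "ctrl", "age")
    oracle <- oracle_greedy_match(ages_case, ages_ctrl)
    expect_equal(m$control - 12L, oracle[order(oracle[, 1]), 2])
  }
})
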