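test_that("median regression fits a noiseless line exactly", {
  x <- seq(-2, 2, length.out = 50)
  y <- 2 + 3 * x
  suppressMessages(r <- median_regression(y, x, B = 50, seed = 1))
  expect_equal(r$beta, 3, tolerance = 1e-8)
})

test_that("median regression recovers a planted coefficient under skewed noise", {
  set.seed(7)
  n <- 2000
  x <- rnorm(n)
  noise <- rgamma(n, shape = 2, rate = 1) - qgamma(0.5, 2, 1)  # median 0
  y <- 1 - 0.9 * x + noise
  suppressMessages(r <- median_regression(y, x, B = 100, seed = 2))
  expect_lt(abs(r$beta - (-0.9)), 0.1)
})

test_that("median regression matches a small-n L1 optimization oracle", {
  set.seed(8)
  x <- rnorm(25); y <- 1 + 0.5 * x + rnorm(25)
  suppressMessages(r <- median_regression(y, x, B = 50, seed = 3))
  # brute-force L1 loss surface over a fine grid around the fit
  l1 <- function(b0, b1) sum(abs(y - b0 - b1 * x))
  fit_loss <- l1(coef(r$fit)[1], r$beta)
  for (db in seq(-0.2, 0.2, by = 0.01)) {
    expect_gte(l1(coef(r$fit)[1] + db, r$beta), fit_loss - 1e-8)
    expect_gte(l1(coef(r$fit)[1], r$beta + db), fit_loss - 1e-8)
  }
})

test_that("bootstrap CI covers zero for an unrelated analyte", {
  set.seed(9)
  x <- rnorm(300); y <- rnorm(300)
  suppressMessages(r <- median_regression(y, x, B = 300, seed = 4))
  expect_lt(r$ci_lower, 0)
  expect_gt(r$ci_upper, 0)
})

test_that("median regression is equivariant to outcome scaling", {
  set.seed(10)
  x <- rnorm(100); y <- 2 * x + rnorm(100)
  suppressMessages(r1 <- median_regression(y, x, B = 50, seed = 5))
  suppressMessages(r2 <- median_regression(10 * y, x, B = 50, seed = 5))
  expect_equal(r2$beta, 10 * r1$beta, tolerance = 1e-6)
})

test_that("median regression validates its design matrix", {
  x <- rnorm(30)
  expect_error(suppressMessages(
    median_regression(rnorm(30), x, covariates = data.frame(dup = x))),
    "rank deficient")
  expect_error(suppressMessages(median_regression(rnorm(6), rnorm(6))),
               "too few")
})

test_that("dichotomized logistic regression behaves at the null and under signal", {
  set.seed(11)
  # analyte identical across classes -> beta ~ 0
  y <- rnorm(400)
  x <- rnorm(400)
  suppressMessages(r0 <- dichotomized_logistic(y, x))
  expect_lt(abs(r0$beta), 0.25)
  # planted log-odds slope 1.0 on the dichotomized outcome
  x <- rnorm(2000)
  hi <- rbinom(2000, 1, plogis(1.0 * x))
  # construct a continuous outcome whose median split reproduces hi
  y <- hi + runif(2000, -0.4, 0.4)
  suppressMessages(r1 <- dichotomized_logistic(y, x))
  expect_lt(abs(r1$beta - 1.0), 0.15)
  expect_error(suppressMessages(dichotomized_logistic(rep(1, 50), rnorm(50))),
               "distinct")
})

test_that("perfect separation is flagged and falls back to a penalized fit", {
  x <- c(rnorm(30, -3), rnorm(30, 3))
  y <- rep(c(0, 10), each = 30) + seq(0.01, 0.6, length.out = 60)
  suppressMessages(r <- dichotomized_logistic(y, x))
  expect_true(r$separation)
  expect_true(is.finite(r$beta))
  expect_gt(r$beta, 0)
})

test_that("BH FDR matches the step-up definition and its limit cases", {
  expect_true(all(bh_fdr(rep(0, 5))))
  expect_false(any(bh_fdr(rep(1, 5))))
  p <- c(0.01, 0.02, 0.30, 0.90)
  expect_equal(bh_fdr(p, 0.20), oracle_bh(p, 0.20))
  set.seed(12)
  for (rep in 1:20) {
    p <- runif(15)^2
    flags <- bh_fdr(p, 0.20)
    expect_equal(flags, oracle_bh(p, 0.20))
    # monotone in p
    expect_true(all(flags[p <= max(c(-Inf, p[flags]))] | !any(flags)))
    # superset of Bonferroni
    expect_true(all(flags[p <= 0.20 / length(p)]))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(0.5, q = 1.5), "0, 1")
})

test_that("kendall ranking matches brute-force pair counting and sorts stably", {
  set.seed(13)
  n <- 30
  score <- sample(1:8, n, replace = TRUE)  # ties on purpose
  pep <- cbind(A = score + 0, B = -score + 0,
               C = sample(1:5, n, replace = TRUE),
               D = rnorm(n))
  rk <- kendall_ranking(pep, score)
  expect_equal(rk$tau[rk$peptide == "A"], 1)
  expect_equal(rk$tau[rk$peptide == "B"], -1)
  for (nm in c("C", "D"))
    expect_equal(rk$tau[rk$peptide == nm],
                 oracle_kendall(pep[, nm], score), tolerance = 1e-12)
  expect_false(is.unsorted(rev(rk$tau)))
})

test_that("constant peptides are excluded from the ranking with a message", {
  set.seed(14)
  pep <- cbind(A = rnorm(20), K = rep(2, 20))
  expect_message(rk <- kendall_ranking(pep, rnorm(20)), "constant")
  expect_equal(attr(rk, "excluded"), "K")
  expect_equal(nrow(rk), 1)
})

test_that("matched tests dispatch correctly across the four test families", {
  # identical paired vectors: wilcoxon undefined, flagged with p = 1
  w <- matched_tests(c(1, 2, 3), c(1, 2, 3), type = "wilcoxon")
  expect_true(w$undefined)
  expect_equal(w$p.value, 1)
  # fisher 2x2 equals hypergeometric enumeration
  tab <- matrix(c(8, 1, 2, 9), 2)
  f <- matched_tests(type = "fisher", table = tab)
  expect_equal(f$p.value, oracle_fisher_2x2(tab), tolerance = 1e-9)
  # symmetric k x k table: McNemar-Bowker statistic 0
  sym <- matrix(c(5, 2, 3, 2, 6, 4, 3, 4, 7), 3)
  mb <- matched_tests(type = "mcnemar_bowker", table = sym)
  expect_equal(mb$statistic, 0)
  # paired t on shifted pairs
  pt <- matched_tests(c(1.0, 2.2, 2.9, 4.1), c(2.2, 3.1, 4.3, 5.0),
                      type = "paired_t")
  expect_lt(pt$p.value, 0.01)
})

test_that("regression stage reproduces the tau-significant / Abeta42-null pattern", {
  spec <- cohort_spec(n_control = 1000L, n_asymad = 1L, n_ad = 1L,
                      n_peptides = 5L, informative_peptides = integer(0),
                      effect_sizes = numeric(0), seed = 15)
  co <- generate_cohort(spec)
  s <- co$subjects[co$subjects$group == "control", ]
  pan <- analyte_panel(s)
  tab <- regression_table(s, outcomes = c("rcft_immediate", "avlt_immediate"),
                          analytes = pan[c("z_ttau", "z_abeta42")],
                          B = 200, seed = 16)
  get <- function(oc, an) tab[tab$outcome == oc & tab$analyte == an, ]
  tau_row <- get("rcft_immediate", "z_ttau")
  ab_row <- get("rcft_immediate", "z_abeta42")
  expect_lt(tau_row$p, 0.001)       # planted visuospatial tau decline
  expect_lt(tau_row$estimate, 0)
  expect_gt(ab_row$p, 0.01)         # Abeta42 carries no cognition signal
  expect_gt(get("avlt_immediate", "z_ttau")$p, 0.01)  # verbal memory null
})
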