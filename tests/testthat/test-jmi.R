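test_that("mutual information hits its closed forms", {
  # y a copy of a balanced binary x: I = log 2 nats
  x <- rep(c(0, 1), each = 20)
  expect_equal(mutual_information(x, x), log(2), tolerance = 1e-12)
  # independence built from a product table: I = 0
  x2 <- rep(c(0, 0, 1, 1), 10)
  y2 <- rep(c(0, 1, 0, 1), 10)
  expect_equal(mutual_information(x2, y2), 0, tolerance = 1e-12)
  expect_error(mutual_information(integer(0), integer(0)), "nonempty")
})

test_that("mutual information equals term-by-term summation on count tables", {
  tab <- matrix(c(10, 5, 3, 8, 2, 7), nrow = 3)
  x <- rep(rep(1:3, 2), times = as.vector(tab))
  y <- rep(rep(1:2, each = 3), times = as.vector(tab))
  expect_equal(mutual_information(x, y), oracle_mi(table(x, y)),
               tolerance = 1e-12)
  set.seed(1)
  for (rep in 1:10) {
    x <- sample(1:4, 60, replace = TRUE)
    y <- sample(1:3, 60, replace = TRUE)
    mi <- mutual_information(x, y)
    expect_equal(mi, oracle_mi(table(x, y)), tolerance = 1e-12)
    expect_gte(mi, 0)                               # non-negativity
    expect_equal(mi, mutual_information(y, x))      # symmetry
  }
})

test_that("JMI selects the label-copy feature first", {
  set.seed(2)
  y <- rep(c(0, 1), each = 30)
  x <- cbind(f1 = y + 0, f2 = rnorm(60), f3 = rnorm(60), f4 = rnorm(60))
  sel <- jmi_select(x, y, target_size = 2, bins = 2)
  expect_equal(sel$selected[1], "f1")
})

test_that("JMI greedy steps equal exhaustive candidate scoring", {
  set.seed(3)
  n <- 80
  y <- factor(sample(c("a", "b"), n, replace = TRUE))
  x <- cbind(f1 = rnorm(n) + (y == "a"), f2 = rnorm(n),
             f3 = rnorm(n) - 0.5 * (y == "a"), f4 = rnorm(n))
  sel <- jmi_select(x, y, target_size = 2, bins = 3)
  disc <- lapply(colnames(x), function(nm) discretize_bins(x[, nm], 3))
  names(disc) <- colnames(x)
  # step 1: univariate MI over all candidates
  s1 <- oracle_jmi_scores(disc, y, character(0), colnames(x))
  expect_equal(sel$selected[1], names(which.max(s1)))
  expect_equal(sel$scores[1], unname(max(s1)), tolerance = 1e-12)
  # step 2: joint-information scores over the remaining candidates
  pool <- setdiff(colnames(x), sel$selected[1])
  s2 <- oracle_jmi_scores(disc, y, sel$selected[1], pool)
  expect_equal(sel$selected[2], names(which.max(s2)))
  expect_equal(sel$scores[2], unname(max(s2)), tolerance = 1e-12)
})

test_that("JMI finds an XOR partner invisible to univariate ranking", {
  set.seed(4)
  n <- 600
  f1 <- rbinom(n, 1, 0.55)  # slight marginal bias
  f2 <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(f1, f2))
  x <- cbind(f1 = f1 + rnorm(n, sd = 0.05), f2 = f2 + rnorm(n, sd = 0.05),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  # marginally, only the partner of the biased feature is informative:
  # P(y=1 | f2) = P(f1 != f2) departs from 0.5 because f1 is biased, while
  # P(y=1 | f1) = 0.5 exactly. So f2 enters first and the XOR partner f1
  # must then beat every noise feature through the pairwise-joint term.
  sel <- jmi_select(x, y, target_size = 2, bins = 2)
  expect_equal(sel$selected[1], "f2")
  expect_equal(sel$selected[2], "f1")
})

test_that("JMI with target 1 is univariate MI ranking's top feature", {
  set.seed(5)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(a = rnorm(n, y), b = rnorm(n, 2 * y), c = rnorm(n))
  sel <- jmi_select(x, y, target_size = 1, bins = 4)
  mis <- vapply(colnames(x), function(nm)
    mutual_information(discretize_bins(x[, nm], 4), y), numeric(1))
  expect_equal(sel$selected, names(which.max(mis)))
})

test_that("constant features are excluded and inputs validated", {
  set.seed(6)
  x <- cbind(a = rnorm(40), k = rep(1, 40), b = rnorm(40))
  y <- rep(c(0, 1), 20)
  expect_message(sel <- jmi_select(x, y, target_size = 2, bins = 3),
                 "constant")
  expect_equal(sel$excluded, "k")
  expect_false("k" %in% sel$selected)
  expect_error(jmi_select(x, rep(1, 40), target_size = 2), "2 classes")
  expect_error(jmi_select(x, y, target_size = 3), "smaller")
})

test_that("bin edges computed on train transfer to new data", {
  set.seed(7)
  train <- rnorm(200)
  d1 <- discretize_bins(train, 5)
  d2 <- discretize_bins(c(-10, 0, 10), 5, breaks = attr(d1, "breaks"))
  expect_equal(as.integer(d2), c(1L, d1[which.min(abs(train))], 5L),
               tolerance = 0)
})

test_that("subgroup panel evaluation is perfect when separable, null when shuffled", {
  set.seed(8)
  n <- 60
  pep <- exp(rbind(matrix(rnorm(n * 4), n, 4),
                   matrix(rnorm(n * 4, 5), n, 4)))
  colnames(pep) <- paste0("P", 1:4)
  lab <- rep(c("Control-like", "AD-like"), each = n)
  ev <- evaluate_subgroup_panel(pep, lab, c("P1", "P2"), seed = 9)
  expect_equal(ev$accuracy, 1)
  labsh <- sample(lab)
  evsh <- evaluate_subgroup_panel(pep, labsh, c("P3", "P4"), seed = 10)
  expect_lt(evsh$accuracy, 0.85)  # near the 0.5 majority rate
})

test_that("per-fold CV AUC equals brute-force Mann-Whitney pair counting", {
  set.seed(9)
  n <- 72
  pep <- exp(matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("P", 1:3))))
  lab <- rep(c(0, 1), each = n / 2)
  pep[lab == 1, 1] <- pep[lab == 1, 1] * exp(1.2)
  cv <- cross_validated_roc(pep, lab, c("P1", "P2"), k = 6, seed = 11)
  logx <- log(pep[, c("P1", "P2")])
  for (f in 1:6) {
    tr <- which(cv$fold != f); te <- which(cv$fold == f)
    xtr <- scale(logx[tr, ])
    xte <- scale(logx[te, ], center = attr(xtr, "scaled:center"),
                 scale = attr(xtr, "scaled:scale"))
    fit <- suppressWarnings(glm.fit(cbind(1, xtr), lab[tr],
                                    family = binomial()))
    sc <- drop(plogis(cbind(1, xte) %*% fit$coefficients))
    expect_equal(cv$auc[f], oracle_auc(sc, lab[te]), tolerance = 1e-12)
  }
  expect_equal(cv$mean_auc, mean(cv$auc))
  expect_equal(cv$se, sd(cv$auc) / sqrt(6))
})

test_that("CV ROC is perfect for label-determined scores and null for noise", {
  set.seed(10)
  n <- 48
  lab <- rep(c(0, 1), each = n / 2)
  pep <- exp(matrix(rnorm(n * 2, sd = 0.1), n, 2,
                    dimnames = list(NULL, c("S", "N"))))
  pep[, "S"] <- exp(lab * 10 + rnorm(n, sd = 0.01))
  cv <- cross_validated_roc(pep, lab, "S", k = 6, seed = 12)
  expect_equal(cv$auc, rep(1, 6))
  expect_equal(cv$se, 0)
  cvn <- cross_validated_roc(pep, lab, "N", k = 6, seed = 13)
  expect_lt(abs(cvn$mean_auc - 0.5), 0.3)
  few <- c(1:5, (n / 2 + 1):(n / 2 + 5))
  expect_error(cross_validated_roc(pep[few, ], lab[few], "S", k = 6),
               "fewer members")
})
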