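test_that("comparisons are routed by Shapiro-Wilk normality", {
  set.seed(14)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  r <- route_and_compare(x, y)
  expect_equal(r$test, "t")
  # heavily skewed group -> Mann-Whitney (checked over seeds)
  routed <- sapply(1:5, function(s) {
    set.seed(100 + s)
    route_and_compare(rexp(30), rnorm(30))$test
  })
  expect_true(mean(routed == "mann-whitney") >= 0.8)
  expect_error(route_and_compare(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("the pooled t statistic matches the hand formula on a 4+4 set", {
  x <- c(1.2, 0.8, 1.1, 0.9); y <- c(0.2, 0.4, 0.1, 0.5)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  r <- route_and_compare(x, y)
  expect_equal(r$statistic, t_hand)
  # identical distributions: d = 0 and a tiny statistic
  same <- route_and_compare(c(x, y), c(y, x))
  expect_equal(same$d, 0)
  expect_gt(same$p, 0.95)
})

test_that("Cohen's d follows the pooled-SD formula and sign convention", {
  expect_equal(cohens_d(5, 1, 10, 5, 2, 10), 0)
  expect_equal(cohens_d(1, 1, 2, 0, 1, 2), 1)
  # group-summary arithmetic for a strong transition effect
  expect_equal(cohens_d(11.17, 2.87, 21, 8.89, 2.69, 45), 0.8298,
               tolerance = 1e-4)
  expect_error(cohens_d(1, 0, 5, 2, 0, 5), "undefined")
})

test_that("chi-square (no continuity correction) matches the oracle", {
  even <- matrix(c(10, 20, 10, 20), 2)
  expect_equal(chi_square_2x2(even)$statistic, 0)
  set.seed(15)
  for (i in 1:5) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    expect_equal(chi_square_2x2(tab)$statistic, oracle_chisq(tab))
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("BH adjustment matches the step-up oracle and its invariants", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(16)
  for (i in 1:10) {
    p <- runif(sample(3:15, 1))
    adj <- fdr_bh(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    perm <- sample(seq_along(p))
    expect_equal(fdr_bh(p[perm]), adj[perm])
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("correlations match hand values and rank oracles", {
  x <- 1:10
  r <- correlate_with_nrs(x, x)
  expect_equal(unname(r$pearson["r"]), 1)
  expect_equal(unname(r$spearman["rho"]), 1)
  # 3-point rank example, padded to meet n >= 4 with a tied midpoint
  r3 <- oracle_spearman(c(1, 2, 3), c(2, 1, 3))
  expect_equal(r3, 0.5)
  set.seed(17)
  a <- rnorm(25); b <- 0.4 * a + rnorm(25)
  rr <- correlate_with_nrs(a, b)
  expect_equal(unname(rr$pearson["r"]), oracle_pearson(a, b))
  expect_equal(unname(rr$spearman["rho"]), oracle_spearman(a, b))
  expect_error(correlate_with_nrs(rep(1, 5), 1:5), "zero-variance")
})

test_that("GLM adjustment reduces confounding and matches least squares", {
  set.seed(18)
  n <- 60
  subjects <- data.frame(
    subject = sprintf("S%02d", 1:n),
    group = rep(c("HP", "LP"), each = n / 2),
    age = round(rnorm(n, 50, 8)),
    surgery = sample(c("mastectomy", "breast-conserving"), n, TRUE),
    bdi = round(abs(rnorm(n, 4, 2))), alnd = sample(c(TRUE, FALSE), n, TRUE))
  # constant covariates fall out: adjusted effect = raw mean difference
  const <- subjects; const$age <- 50; const$bdi <- 3
  const$surgery <- "mastectomy"; const$alnd <- TRUE
  y <- rnorm(n) + (subjects$group == "HP")
  g <- glm_adjust(y, const)
  expect_equal(g$estimate,
               mean(y[subjects$group == "HP"]) - mean(y[subjects$group == "LP"]))
  # coefficients match the closed-form least-squares oracle
  X <- cbind(1, subjects$group == "HP", subjects$age,
             subjects$surgery == "mastectomy", subjects$bdi, subjects$alnd)
  y2 <- rnorm(n) + 0.8 * (subjects$group == "HP") + 0.05 * subjects$age
  beta <- oracle_ols(X, y2)
  g2 <- glm_adjust(y2, subjects)
  expect_equal(g2$estimate, beta[2], tolerance = 1e-8)
})

test_that("adjustment moves a confounded estimate toward the direct effect", {
  set.seed(19)
  hits <- replicate(60, {
    n <- 66
    group <- rep(c("HP", "LP"), c(21, 45))
    bdi <- rnorm(n) + 1.5 * (group == "HP")     # confounder tied to group
    y <- 0.5 * (group == "HP") + 1.0 * bdi + rnorm(n)
    subj <- data.frame(subject = as.character(1:n), group = group, bdi = bdi)
    raw <- mean(y[group == "HP"]) - mean(y[group == "LP"])
    adj <- glm_adjust(y, subj, covariates = "bdi")$estimate
    abs(adj - 0.5) < abs(raw - 0.5)
  })
  expect_gt(mean(hits), 0.8)
})

test_that("mixed ANOVA decomposes sums of squares like the hand oracle", {
  set.seed(20)
  n_s <- 8
  metrics <- data.frame(subject = sprintf("S%d", 1:n_s))
  for (cl in c("A", "B", "C", "D"))
    metrics[[paste0("cov_", cl)]] <- rnorm(n_s, 25, 4)
  subjects <- data.frame(subject = metrics$subject,
                         group = rep(c("HP", "LP"), each = 4))
  res <- mixed_anova(metrics, subjects, "coverage")
  long <- data.frame(
    value = unlist(metrics[paste0("cov_", c("A", "B", "C", "D"))]),
    subject = rep(metrics$subject, 4),
    group = rep(subjects$group, 4),
    class = rep(c("A", "B", "C", "D"), each = n_s))
  ss <- oracle_mixed_ss(long$value, long$subject, long$group, long$class)
  F_group <- (ss$group / 1) / (ss$subj / (n_s - 2))
  F_class <- (ss$class / 3) / (ss$error / (3 * (n_s - 2)))
  F_int <- (ss$interaction / 3) / (ss$error / (3 * (n_s - 2)))
  expect_equal(res$anova$F, c(F_group, F_class, F_int))
  expect_equal(res$anova$df1, c(1, 3, 3))
})

test_that("mixed ANOVA flags degenerate all-identical input", {
  metrics <- data.frame(subject = sprintf("S%d", 1:6),
                        cov_A = 25, cov_B = 25, cov_C = 25, cov_D = 25)
  subjects <- data.frame(subject = metrics$subject,
                         group = rep(c("HP", "LP"), each = 3))
  expect_warning(res <- mixed_anova(metrics, subjects, "coverage"),
                 "zero error variance")
  expect_true(all(is.nan(res$anova$F) | res$anova$F == 0))
  expect_null(res$posthoc)
  expect_error(mixed_anova(metrics["subject"], subjects, "coverage"),
               "per-class")
})
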