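test_that("per-feature ANOVA flags separated groups and not identical ones", {
  fn <- feature_names()
  tab <- as.data.frame(matrix(rep(c(1, 2, 3), 3), 9, 47, byrow = FALSE))
  colnames(tab) <- fn
  tab$class <- rep(c("a", "b", "c"), each = 3)
  res <- anova_per_feature(tab)
  expect_identical(nrow(res), 47L)
  expect_true(all(res$F == 0))
  expect_true(all(!res$significant))
  # widely separated groups with tiny jitter: p below any fixed threshold
  set.seed(1)
  tab2 <- tab
  tab2[fn] <- rep(c(0, 10, 20), each = 3) + matrix(rnorm(9 * 47, sd = 1e-3), 9, 47)
  res2 <- anova_per_feature(tab2)
  expect_true(all(res2$p < 1e-12))
  expect_true(all(res2$significant))
  expect_error(anova_per_feature(tab[1:3, ]), class = "sonotex_parameter_error")
})

test_that("per-feature t test matches the closed-form pooled statistic", {
  fn <- feature_names()
  tab <- as.data.frame(matrix(rnorm(4 * 47), 4, 47))
  colnames(tab) <- fn
  tab$label <- factor(c("g1", "g1", "g2", "g2"))
  tab[fn][1:2, ] <- matrix(rep(c(0, 1), 47), 2, 47)
  tab[fn][3:4, ] <- matrix(rep(c(10, 11), 47), 2, 47)
  res <- ttest_per_feature(tab)
  # oracle: pooled sp2 = 0.5, t = -10 / sqrt(0.5 * (1/2 + 1/2)) = -10 / sqrt(0.5)
  expect_equal(res$t, rep(-10 / sqrt(0.5), 47))
  expect_true(all(res$p < 0.01))
  # antisymmetry under group swap
  tab_sw <- tab
  tab_sw$label <- factor(as.character(tab$label), levels = c("g2", "g1"))
  expect_equal(ttest_per_feature(tab_sw)$t, -res$t)
  # identical groups: t = 0, p = 1
  tab_id <- tab
  tab_id[fn][3:4, ] <- tab_id[fn][1:2, ]
  res_id <- ttest_per_feature(tab_id)
  expect_true(all(res_id$t == 0) && all(res_id$p == 1))
})

test_that("AUC equals exhaustive pair counting, with the documented tie handling", {
  expect_equal(roc_with_ci(c(0.9, 0.4, 0.6, 0.1), c(1, 0, 1, 0))$auc, 1.0)
  expect_equal(roc_with_ci(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(roc_with_ci(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  for (s in 1:30) {
    set.seed(s)
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y <- c(0, 1, y[-(1:2)])
    sc <- round(rnorm(n), 1)  # rounding induces ties
    r <- roc_with_ci(sc, y)
    expect_equal(r$auc, oracle_auc(sc, y), tolerance = 1e-12)
    expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
    # trapezoidal integral of the ROC curve equals the Mann-Whitney AUC
    expect_equal(sum(diff(r$fpr) * (head(r$sensitivity, -1) + r$sensitivity[-1]) / 2),
                 r$auc, tolerance = 1e-12)
  }
  expect_error(roc_with_ci(1:4, c(1, 1, 1, 1)), class = "sonotex_parameter_error")
})

test_that("AUC and DeLong variance agree with the pROC reference", {
  set.seed(42)
  y <- rbinom(80, 1, 0.5)
  sa <- rnorm(80) + y
  sb <- rnorm(80) + 0.5 * y
  r <- roc_with_ci(sa, y)
  pr <- pROC::roc(y, sa, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  vr <- pROC::var(pr, method = "delong")
  expect_equal(r$se^2, as.numeric(vr), tolerance = 1e-10)
  dl <- delong_compare(sa, sb, y, paired = TRUE)
  pt <- pROC::roc.test(pr, pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dl$p_value, as.numeric(pt$p.value), tolerance = 1e-10)
})

test_that("DeLong handles identical scores and hand-enumerable cases", {
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.6, 0.4, 0.1)
  d <- delong_compare(s, s, y)
  expect_equal(d$delta, 0)
  expect_equal(d$p_value, 1)
  # placement values on the n = 4 case match exhaustive pair enumeration
  d2 <- delong_compare(s, c(0.9, 0.4, 0.6, 0.1), y)
  expect_equal(d2$auc_a, oracle_auc(s, y))
  expect_equal(d2$auc_b, 1.0)
  expect_lte(d2$p_value, 1)
})

test_that("single-AUC DeLong variance tracks the bootstrap on tie-free data", {
  set.seed(7)
  y <- rep(c(0, 1), each = 40)
  sc <- rnorm(80) + 0.8 * y
  r <- roc_with_ci(sc, y)
  boot <- vapply(1:1000, function(i) {
    idx <- c(sample(which(y == 0), replace = TRUE),
             sample(which(y == 1), replace = TRUE))
    roc_with_ci(sc[idx], y[idx])$auc
  }, numeric(1))
  expect_lt(abs(r$se^2 - var(boot)) / var(boot), 0.2)
})

test_that("ICC(2,1) is exact for identical readers and matches the mean-squares oracle", {
  r1 <- c(1, 2, 3, 4, 5)
  icc1 <- icc_two_reader(r1, r1)
  expect_equal(icc1$icc, 1.0)
  expect_identical(icc1$category, "almost perfect")
  # constant offset: hand-computed two-way ANOVA mean squares on 4 subjects
  x1 <- c(1, 2, 3, 4); x2 <- x1 + 2
  res <- icc_two_reader(x1, x2)
  n <- 4; k <- 2
  grand <- mean(c(x1, x2))
  msr <- k * sum((rowMeans(cbind(x1, x2)) - grand)^2) / (n - 1)
  msc <- n * sum((c(mean(x1), mean(x2)) - grand)^2) / (k - 1)
  mse <- 0  # rows and columns explain everything for a pure shift
  expected <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, expected)
  expect_lt(res$icc, 1)
  expect_error(icc_two_reader(rep(1, 5), rep(1, 5)), class = "sonotex_degenerate_roi")
})

test_that("Landis-Koch categories follow the printed bands", {
  band_of <- function(icc) {
    if (icc <= 0.40) "poor/fair" else if (icc <= 0.60) "moderate"
    else if (icc <= 0.80) "substantial" else "almost perfect"
  }
  set.seed(3)
  base <- rnorm(40)
  for (noise in c(0.1, 0.45, 0.8, 1.6, 3)) {
    res <- icc_two_reader(base, base + rnorm(40, sd = noise))
    expect_identical(res$category, band_of(res$icc))
  }
  # a mid-band value: noise tuned so icc lands in (0.61, 0.80] -> substantial
  res7 <- icc_two_reader(base, base + rnorm(40, sd = 0.65))
  expect_gt(res7$icc, 0.40)
  expect_identical(res7$category, band_of(res7$icc))
})

test_that("confusion metrics reproduce standard ratios", {
  pred <- factor(c("pos", "pos", "neg"), levels = c("neg", "pos"))
  act <- factor(c("pos", "pos", "neg"), levels = c("neg", "pos"))
  perfect <- confusion_metrics(pred, act)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  allpos <- confusion_metrics(factor(rep("pos", 3), levels = c("neg", "pos")), act)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_error(confusion_metrics(factor(character(0)), factor(character(0))),
               class = "sonotex_parameter_error")
})

test_that("feature correlation matrix is symmetric with unit diagonal", {
  fn <- feature_names()
  set.seed(11)
  tab <- as.data.frame(matrix(rnorm(1000 * 47), 1000, 47))
  colnames(tab) <- fn
  tab$hist_variance <- tab$hist_entropy          # duplicate
  tab$hist_skewness <- -tab$hist_entropy         # negation
  cm <- feature_correlation_matrix(tab)
  expect_equal(cm["hist_entropy", "hist_variance"], 1.0)
  expect_equal(cm["hist_entropy", "hist_skewness"], -1.0)
  expect_equal(cm, t(cm))
  expect_true(all(diag(cm) == 1))
  # independent columns: |r| < 0.15 for at least 95% of pairs at n = 1000
  off <- cm[upper.tri(cm)]
  expect_gt(mean(abs(off) < 0.15), 0.95)
  # constant column flagged and zeroed
  tab$szm_zsv <- 2
  expect_warning(cm2 <- feature_correlation_matrix(tab), "constant")
  expect_true(all(cm2["szm_zsv", setdiff(fn, "szm_zsv")] == 0))
  expect_equal(cm2["szm_zsv", "szm_zsv"], 1)
})
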