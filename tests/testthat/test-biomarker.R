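test_that("one-way ANOVA matches the textbook sums-of-squares formula", {
  set.seed(91)
  g <- rep(c("a", "b", "c"), c(10, 7, 10))
  y <- rnorm(27) + ifelse(g == "c", -0.8, 0)
  rel <- matrix(y, 1, dimnames = list("gene1", paste0("s", 1:27)))
  ann <- sample_annotation(colnames(rel), g)
  gt <- group_compare(rel, ann, control = "a")

  ni <- table(g); mi <- tapply(y, g, mean); gm <- mean(y)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((y - mi[g])^2)
  f_ref <- (ssb / 2) / (ssw / 24)
  p_ref <- pf(f_ref, 2, 24, lower.tail = FALSE)
  expect_equal(unique(gt$anova_F), f_ref, tolerance = 1e-8)
  expect_equal(unique(gt$anova_p), p_ref, tolerance = 1e-8)
  # and agrees with stats::oneway.test under equal variances
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  expect_equal(unique(gt$anova_F), unname(ow$statistic), tolerance = 1e-10)

  # pairwise Welch p against control, Holm-adjusted
  for (grp in c("b", "c")) {
    p_w <- t.test(y[g == grp], y[g == "a"])$p.value
    expect_equal(gt$p[gt$group == grp], p_w, tolerance = 1e-10)
  }
  expect_equal(gt$p_holm, p.adjust(gt$p, "holm"))
})

test_that("constant data give F = 0 and p = 1", {
  rel <- matrix(5, 1, 8, dimnames = list("g", paste0("s", 1:8)))
  ann <- two_group_ann(4, 4)
  gt <- group_compare(rel, ann, control = "control")
  expect_equal(gt$anova_F, 0)
  expect_equal(gt$anova_p, 1)
})

test_that("Holm step-down behaves as defined", {
  expect_equal(p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
})

test_that("AUC equals exhaustive pair counting with half ties", {
  r <- roc_analysis(c(3, 4, 5, 1, 2, 3), c(1, 1, 1, 0, 0, 0),
                    orientation = "high")
  expect_equal(r$auc, 8.5 / 9, tolerance = 1e-12)
  expect_equal(r$auc, brute_auc(c(3, 4, 5), c(1, 2, 3)), tolerance = 1e-12)

  # perfect separation and identical distributions
  expect_equal(roc_analysis(c(10, 11, 1, 2), c(1, 1, 0, 0),
                            orientation = "high")$auc, 1)
  expect_equal(roc_analysis(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0),
                            orientation = "high")$auc, 0.5)
})

test_that("trapezoid-curve AUC equals the Mann-Whitney estimator", {
  trapz_auc <- function(curve) {
    x <- curve$fpr; y <- curve$sensitivity
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  for (seed in 1:25) {
    set.seed(seed)
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    scores <- c(rnorm(n1, 0.5), rnorm(n0))
    if (seed %% 3 == 0) scores <- round(scores)  # force ties
    labels <- rep(c(1, 0), c(n1, n0))
    r <- roc_analysis(scores, labels, orientation = "high")
    expect_equal(trapz_auc(r$curve), r$auc, tolerance = 1e-12)
    expect_equal(r$auc, brute_auc(scores[labels == 1], scores[labels == 0]),
                 tolerance = 1e-12)
    # complement symmetry with the half-tie convention
    rneg <- roc_analysis(-scores, labels, orientation = "high")
    expect_equal(r$auc + rneg$auc, 1, tolerance = 1e-12)
  }
})

test_that("ROC curves are anchored and monotone, CI brackets the AUC", {
  set.seed(99)
  r <- roc_analysis(rnorm(30, rep(c(1, 0), 15)), rep(c(1, 0), 15),
                    orientation = "high")
  expect_equal(r$curve[1, ], data.frame(fpr = 0, sensitivity = 0))
  expect_equal(as.numeric(r$curve[nrow(r$curve), ]), c(1, 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$sensitivity) >= 0))
  expect_lte(r$ci_low, r$auc); expect_gte(r$ci_high, r$auc)
  expect_error(roc_analysis(rnorm(5), rep(1, 5)), "both classes")
})

test_that("AUC and DeLong CI agree with pROC on random instances", {
  skip_if_not_installed("pROC")
  for (seed in 1:10) {
    set.seed(100 + seed)
    labels <- rep(c(1, 0), c(12, 15))
    scores <- rnorm(27, labels)
    r <- roc_analysis(scores, labels, orientation = "high")
    pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(c(r$ci_low, r$ci_high), ci[c(1, 3)], tolerance = 1e-9)
  }
})

test_that("auto orientation flips markers that fall in disease", {
  set.seed(7)
  scores <- c(rnorm(10, 0), rnorm(10, 2))   # cases low
  labels <- rep(c(1, 0), each = 10)
  r <- roc_analysis(scores, labels, orientation = "auto")
  expect_true(r$flipped)
  expect_equal(r$direction, "<=")
  expect_gt(r$auc, 0.5)
})

test_that("the Youden cutoff matches brute force with the documented tie rule", {
  r <- roc_analysis(c(3, 4, 5, 1, 2, 3), c(1, 1, 1, 0, 0, 0),
                    orientation = "high")
  expect_equal(r$youden_J, 2 / 3, tolerance = 1e-12)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 200 / 3, tolerance = 1e-10)
  expect_equal(r$cutoff, 2.5)

  for (seed in 1:25) {
    set.seed(200 + seed)
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    scores <- round(c(rnorm(n1, 1), rnorm(n0)), 1)
    labels <- rep(c(1, 0), c(n1, n0))
    r <- roc_analysis(scores, labels, orientation = "high")
    bf <- brute_youden(scores[labels == 1], scores[labels == 0])
    expect_equal(r$youden_J, bf$J, tolerance = 1e-12)
    expect_equal(r$cutoff, bf$t)
    expect_equal(r$sensitivity, 100 * bf$sens)
  }

  # degenerate identical scores: J = 0 at the all-case operating point
  rd <- roc_analysis(rep(2, 6), rep(c(1, 0), 3), orientation = "high")
  expect_equal(rd$youden_J, 0)
  expect_equal(rd$sensitivity, 100)
  expect_equal(rd$specificity, 0)
})

test_that("partial correlation reduces to Pearson and matches matrix inversion", {
  set.seed(111)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20)
  pc0 <- adjusted_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc0$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc0$p, ct$p.value, tolerance = 1e-12)
  expect_equal(pc0$df, 18)

  # y = x with covariates -> r = 1
  cov2 <- data.frame(age = rnorm(20, 60, 5), weight = rnorm(20, 65, 7))
  expect_equal(adjusted_correlation(x, x, cov2)$r, 1)

  # 8-point seeded instance against the correlation-matrix-inversion formula
  set.seed(112)
  x8 <- rnorm(8); y8 <- rnorm(8)
  c8 <- data.frame(a = rnorm(8), b = rnorm(8))
  pc <- adjusted_correlation(x8, y8, c8)
  Rm <- cor(cbind(x8, y8, c8))
  P <- solve(Rm)
  r_ref <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(pc$r, r_ref, tolerance = 1e-10)
  expect_equal(pc$df, 8 - 2 - 2)
})

test_that("partial correlation is invariant to affine covariate rescaling", {
  set.seed(113)
  x <- rnorm(15); y <- rnorm(15)
  cv <- data.frame(a = rnorm(15, 100, 10), b = rnorm(15))
  cv2 <- data.frame(a = 3 * cv$a - 50, b = -0.1 * cv$b + 2)
  expect_equal(adjusted_correlation(x, y, cv)$r,
               adjusted_correlation(x, y, cv2)$r, tolerance = 1e-10)
  # collinear covariates are rejected by name
  cv3 <- data.frame(a = cv$a, b = 2 * cv$a)
  expect_error(adjusted_correlation(x, y, cv3), "collinear")
})
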