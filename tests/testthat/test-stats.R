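test_that("sensitivity/specificity reproduce the printed operating point", {
  # all 43 test-positives nested in 54 gold-positives among 64 cases
  ct <- confusion_table(tp = 43, fp = 0, fn = 11, tn = 10)
  ss <- sensitivity_specificity(ct)
  expect_equal(ss$sensitivity_rounded, 80L)
  expect_equal(ss$specificity_rounded, 100L)
  expect_equal(ss$sensitivity, 100 * 43 / 54, tolerance = 1e-12)

  perfect <- sensitivity_specificity(confusion_table(10, 0, 0, 10))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)

  small <- sensitivity_specificity(confusion_table(tp = 2, fp = 1,
                                                   fn = 2, tn = 5))
  expect_equal(small$sensitivity_rounded, 50L)
  expect_equal(small$specificity_rounded, 83L)

  expect_error(sensitivity_specificity(confusion_table(0, 3, 0, 7)),
               "undefined")
  expect_error(confusion_table(-1, 0, 0, 0), "non-negative")
})

test_that("ordinal ROC-AUC equals brute-force pair counting", {
  # perfectly separating binary score
  expect_equal(roc_auc_ordinal(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # constant score: all ties
  expect_equal(roc_auc_ordinal(rep(2, 6), c(TRUE, TRUE, FALSE, TRUE,
                                            FALSE, FALSE)), 0.5)
  # three-level score reconstructed from the printed detection counts:
  # gold+: 35 at level 2 (2.0 SD), 8 at level 1 (1.5 SD), 11 at level 0;
  # gold-: 10 at level 0
  scores <- c(rep(2, 35), rep(1, 8), rep(0, 11), rep(0, 10))
  gold <- c(rep(TRUE, 54), rep(FALSE, 10))
  brute <- function(s, g) {
    sp <- s[g]; sn <- s[!g]
    tot <- 0
    for (i in sp) for (j in sn) tot <- tot + (i > j) + 0.5 * (i == j)
    tot / (length(sp) * length(sn))
  }
  expect_equal(brute(scores, gold), 485 / 540)
  expect_equal(roc_auc_ordinal(scores, gold), 485 / 540, tolerance = 1e-12)
  # random ordinal data against the brute-force oracle and pROC
  set.seed(51)
  for (i in 1:10) {
    s <- sample(0:3, 40, replace = TRUE)
    g <- runif(40) < 0.5
    if (!any(g) || all(g)) next
    expect_equal(roc_auc_ordinal(s, g), brute(s, g), tolerance = 1e-12)
    expect_equal(roc_auc_ordinal(s, g),
                 as.numeric(pROC::auc(pROC::roc(g, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-9)
  }
  expect_error(roc_auc_ordinal(c(1, 2), c(TRUE, TRUE)), "single class")
})

test_that("binary AUC equals (sensitivity + specificity) / 2", {
  set.seed(52)
  for (i in 1:20) {
    test <- runif(30) < 0.5
    gold <- runif(30) < 0.6
    if (!any(gold) || all(gold)) next
    ct <- confusion_from_verdicts(test, gold)
    ss <- sensitivity_specificity(ct)
    expect_equal(roc_auc_ordinal(as.numeric(test), gold),
                 (ss$sensitivity + ss$specificity) / 200,
                 tolerance = 1e-12)
  }
})

test_that("Cohen's kappa matches hand evaluation and is transpose-invariant", {
  t1 <- matrix(c(20, 5, 5, 70), 2, 2, byrow = TRUE)
  k <- cohens_kappa(t1)
  expect_equal(k$kappa, 0.7333, tolerance = 1e-4)
  expect_equal(k$agreement_percent, 90)

  # perfect agreement with mixed marginals
  expect_equal(cohens_kappa(matrix(c(30, 0, 0, 70), 2, 2))$kappa, 1)
  # exactly chance-level agreement
  chance <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(cohens_kappa(chance)$kappa, 0, tolerance = 1e-12)

  # brute-force oracle and transpose invariance on random tables
  set.seed(53)
  for (i in 1:20) {
    t <- matrix(rpois(4, 20), 2, 2)
    if (sum(t) == 0) next
    n <- sum(t)
    po <- (t[1, 1] + t[2, 2]) / n
    pe <- (sum(t[1, ]) * sum(t[, 1]) + sum(t[2, ]) * sum(t[, 2])) / n^2
    if (abs(1 - pe) < 1e-12) next
    expect_equal(cohens_kappa(t)$kappa, (po - pe) / (1 - pe),
                 tolerance = 1e-12)
    expect_equal(cohens_kappa(t)$kappa, cohens_kappa(t(t))$kappa,
                 tolerance = 1e-12)
  }
  degenerate <- matrix(c(5, 0, 3, 0), 2, 2)  # both raters fixed on class 1?
  # marginals concentrated on one column for rater B -> pe < 1, still defined
  expect_true(is.finite(cohens_kappa(degenerate)$kappa))
  expect_error(cohens_kappa(matrix(c(9, 0, 0, 0), 2, 2)), "degenerate")
})

test_that("rank-sum test: exact small-sample p and identical-sample guard", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_warning(r2 <- wilcoxon_rank_sum(rep(5, 4), rep(5, 6)), "identical")
  expect_equal(r2$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "nonempty")
})

test_that("rank-sum test has power against a one-SD shift", {
  set.seed(54)
  rejections <- 0L
  for (i in 1:200) {
    x <- rnorm(50)
    y <- rnorm(50, mean = 1)
    if (wilcoxon_rank_sum(x, y)$p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / 200, 0.9)
})

test_that("signed-rank test: exact enumeration and antisymmetry", {
  x <- c(2, 3, 4); y <- c(1, 1, 1)  # differences {1, 2, 3}, all positive
  r <- wilcoxon_signed_rank(x, y)
  expect_equal(r$p, 0.25, tolerance = 1e-12)
  expect_equal(r$statistic, 6)
  # swapping the samples gives the mirrored statistic, identical p
  r2 <- wilcoxon_signed_rank(y, x)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("cohort evaluation reproduces the printed study-level metrics", {
  # reconstruct the printed per-case counts as a results table
  df <- data.frame(
    case_id = 1:64,
    asym_positive = c(rep(TRUE, 43), rep(FALSE, 21)),
    asym_level = c(rep(2, 35), rep(1.5, 8), rep(0, 21)),
    pi_positive = c(rep(TRUE, 54), rep(FALSE, 10)))
  rep <- evaluate_cohort(df)
  expect_equal(rep$detection_rate_asym_percent, 67)
  expect_equal(rep$detection_rate_pi_percent, 84)
  expect_equal(rep$sensitivity_percent, 80L)
  expect_equal(rep$specificity_percent, 100L)
  expect_equal(rep$roc_auc, 485 / 540, tolerance = 1e-12)
})
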