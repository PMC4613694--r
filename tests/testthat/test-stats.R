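test_that("two-sample KS statistic matches enumerated ECDF cases", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 3, 5), c(2, 4))$statistic, 1 / 3,
               tolerance = 1e-12)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
  # symmetry and brute-force oracle on random samples
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    D <- ks_two_sample(x, y)$statistic
    expect_equal(D, brute_ks_D(x, y), tolerance = 1e-12)
    expect_equal(D, ks_two_sample(y, x)$statistic, tolerance = 1e-12)
    expect_true(D >= 0 && D <= 1)
  }
})

test_that("one-sample KS normality screen calibrates and detects", {
  set.seed(31)
  pvals <- replicate(100, ks_one_sample_normal(rnorm(10000))$p_value)
  expect_gte(mean(pvals > 0.05), 0.90)
  expect_lt(ks_one_sample_normal(rexp(10000))$p_value, 0.001)
  x <- rnorm(500)
  expect_equal(ks_one_sample_normal(x)$statistic,
               ks_one_sample_normal(x + 100)$statistic, tolerance = 1e-9)
  expect_error(ks_one_sample_normal(rep(1, 10)), "zero variance")
  expect_error(ks_one_sample_normal(1:3), "at least 5")
})

test_that("AUC matches pair counting, trapezoid oracle and pROC", {
  expect_equal(roc_auc(c(2, 3), c(1, 2))$auc, 0.875)
  x <- c(1.2, 3.4, 3.4, 5)
  expect_equal(roc_auc(x, x)$auc, 0.5)
  expect_equal(roc_auc(rep(0.5, 10), rep(0.5, 10))$se, 0.1323,
               tolerance = 1e-3)   # Hanley-McNeil at AUC = 0.5, n = 10/10
  set.seed(41)
  for (i in 1:50) {
    pos <- rnorm(sample(3:30, 1), mean = runif(1, 0, 2))
    neg <- rnorm(sample(3:30, 1))
    r <- roc_auc(pos, neg)
    expect_equal(r$auc, trapezoid_auc(pos, neg), tolerance = 1e-9)
    # flipping class labels maps AUC -> 1 - AUC exactly
    expect_equal(roc_auc(neg, pos)$auc, 1 - r$auc, tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(43)
    pos <- rnorm(50, 1)
    neg <- rnorm(60)
    pr <- pROC::roc(response = rep(c(1, 0), c(50, 60)),
                    predictor = c(pos, neg), quiet = TRUE,
                    direction = "<")
    expect_equal(roc_auc(pos, neg)$auc, as.numeric(pROC::auc(pr)),
                 tolerance = 1e-9)
  }
})

test_that("AUC comparison reproduces the published significance pattern", {
  mk <- function(auc, se) {
    structure(list(descriptor = "d", auc = auc, se = se,
                   n_pos = 1267L, n_neg = 1832L, direction = "as_is"),
              class = "roc_result")
  }
  same <- compare_aucs(mk(0.7, 0.01), mk(0.7, 0.01))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # strongly discriminating vs uninformative descriptor: highly significant
  strong <- compare_aucs(mk(0.86, 0.0067), mk(0.5039, 0.0113))
  expect_lt(strong$p_value, 1e-6)
  # two near-equal top descriptors: not significant at 0.05
  close <- compare_aucs(mk(0.86, 0.0067), mk(0.8446, 0.0070))
  expect_gt(close$p_value, 0.05)
  # antisymmetric statistic, symmetric p
  ab <- compare_aucs(mk(0.8, 0.01), mk(0.75, 0.012))
  ba <- compare_aucs(mk(0.75, 0.012), mk(0.8, 0.01))
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("rank_parameters orders by AUC with stable name tie-breaks", {
  set.seed(51)
  ft <- data.frame(group_label = rep(c("treated", "untreated"), each = 40),
                   roundness = c(rnorm(40, 2), rnorm(40, 1)),
                   area = rnorm(80))
  ft$zz_copy <- ft$roundness           # identical values -> tied AUC
  rep1 <- rank_parameters(ft, descriptors = c("roundness", "zz_copy", "area"))
  expect_equal(rep1$ranking$descriptor[1:2], c("roundness", "zz_copy"))
  expect_equal(rep1$ranking$rank, 1:3)
  expect_true(all(is.na(rep1$pairwise_p[lower.tri(rep1$pairwise_p,
                                                  diag = TRUE)])))
  expect_equal(rep1$pairwise_p["roundness", "zz_copy"], 1)
  one <- rank_parameters(ft, descriptors = "roundness")
  expect_equal(nrow(one$ranking), 1L)
  expect_error(rank_parameters(ft[ft$group_label == "treated", ]),
               "negative group")
})
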