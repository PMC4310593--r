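test_that("one-way ANOVA matches hand-computed sums of squares", {
  # identical groups: no between-group variance at all
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(one_way_anova(same), list(F = 0, p = 1, df1 = 1, df2 = 4))

  # {1,2,3},{2,3,4},{9,10,11}: SSB = 114, SSW = 6 -> F = 57 on (2, 6) df
  toy <- list(c(1, 2, 3), c(2, 3, 4), c(9, 10, 11))
  got <- one_way_anova(toy)
  expect_equal(got$F, 57)
  expect_equal(got$p, pf(57, 2, 6, lower.tail = FALSE))

  # zero within-group variance with unequal means
  degen <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(degen$F, Inf)
  expect_equal(degen$p, 0)

  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(1, c(1, 2))), "at least 2 values")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(8 + i); b <- rnorm(12, mean = 0.5)
    f <- one_way_anova(list(a, b))$F
    t2 <- unname(t.test(a, b, var.equal = TRUE)$statistic)^2
    expect_equal(f, t2, tolerance = 1e-10)
  }
})

test_that("ANOVA holds its nominal type-I error rate", {
  set.seed(99)
  rej <- mean(replicate(1000, {
    g <- list(rnorm(10), rnorm(10), rnorm(10))
    one_way_anova(g)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Tukey HSD agrees with the studentized range computation", {
  toy <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(9, 10, 11))
  got <- tukey_hsd(toy)
  # independent computation: q = |diff| / sqrt(MSW / n), p from ptukey
  msw <- 6 / 6; n <- 3
  for (r in seq_len(nrow(got))) {
    q <- abs(got$diff[r]) / sqrt(msw / n)
    expect_equal(got$p_adj[r],
                 ptukey(q, nmeans = 3, df = 6, lower.tail = FALSE),
                 tolerance = 1e-8)
  }

  ident <- tukey_hsd(list(c(5, 5.1), c(5, 5.1)))
  expect_true(all(ident$p_adj > 0.99))

  far <- tukey_hsd(list(rnorm(10, 0, 0.01), rnorm(10, 50, 0.01)))
  expect_lt(far$p_adj[1], 1e-6)
})

test_that("Tukey p-values are never smaller than the unadjusted pair test", {
  set.seed(21)
  for (i in 1:20) {
    g <- list(rnorm(6), rnorm(6, 0.8), rnorm(6, 1.6))
    tk <- tukey_hsd(g)
    for (r in seq_len(nrow(tk))) {
      i1 <- match(tk$group1[r], c("g1", "g2", "g3"))
      i2 <- match(tk$group2[r], c("g1", "g2", "g3"))
      praw <- t.test(g[[i1]], g[[i2]], var.equal = TRUE)$p.value
      expect_gte(tk$p_adj[r], praw - 0.05)
    }
  }
})

test_that("group summaries encode box-plot statistics", {
  gs <- group_summary(1:9, rep("a", 9))
  expect_equal(gs$median, 5)
  expect_equal(gs$q25, 3)
  expect_equal(gs$q75, 7)

  gs2 <- group_summary(c(1, 1, 1, 1, 100), rep("a", 5))
  out <- attr(gs2, "outliers")$a
  expect_equal(out, 100)

  # quartiles agree with the order-statistic interpolation definition
  set.seed(8)
  for (i in 1:50) {
    v <- round(rnorm(sample(5:15, 1)), 2)
    gs <- group_summary(v, rep("g", length(v)))
    s <- sort(v); n <- length(v)
    manual <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h)
      s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
    }
    expect_equal(gs$q25, manual(0.25))
    expect_equal(gs$median, manual(0.5))
    expect_equal(gs$q75, manual(0.75))
  }
})

test_that("empirical AUC equals all-pairs concordance", {
  # separable scores
  roc <- empirical_roc(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(roc$auc, 1)

  # random instances with ties
  set.seed(5)
  for (i in 1:20) {
    scores <- sample(1:6, 16, replace = TRUE) / 2
    labels <- rep(c(FALSE, TRUE), each = 8)
    roc <- empirical_roc(scores, labels)
    expect_equal(roc$auc, concordance_auc(scores, labels), tolerance = 1e-12)
  }

  # uninformative scores
  set.seed(6)
  s <- rnorm(1e4); l <- rep(c(TRUE, FALSE), 5e3)
  expect_lt(abs(empirical_roc(s, l)$auc - 0.5), 0.02)

  expect_error(empirical_roc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC is invariant to monotone transforms and flips with labels", {
  set.seed(7)
  s <- rlnorm(40); l <- rep(c(TRUE, FALSE), 20)
  a <- empirical_roc(s, l)$auc
  expect_equal(empirical_roc(log(s), l)$auc, a)
  expect_equal(empirical_roc(s^3, l)$auc, a)
  expect_equal(empirical_roc(s, !l)$auc, 1 - a, tolerance = 1e-12)
})

test_that("empirical AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- c(rnorm(30, 1), rnorm(25)); l <- rep(c(TRUE, FALSE), c(30, 25))
  a <- empirical_roc(s, l)$auc
  b <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                      direction = "<")))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("ROC points are monotone and the operating point maximizes J", {
  set.seed(10)
  s <- c(rnorm(20, 1.2), rnorm(20)); l <- rep(c(TRUE, FALSE), each = 20)
  roc <- empirical_roc(s, l)
  expect_true(all(diff(roc$points$sensitivity) >= 0))
  expect_true(all(diff(roc$points$specificity) <= 0))

  op <- operating_point(roc)
  J <- roc$points$sensitivity + roc$points$specificity - 1
  expect_equal(op$sensitivity_pct / 100 + op$specificity_pct / 100 - 1,
               max(J))
  expect_equal(unname(op$rates["TP"] + op$rates["FN"]), 1)
  expect_equal(unname(op$rates["TN"] + op$rates["FP"]), 1)

  # 4-point set, enumerable by hand: cutoff at 3 separates {1,2} from {3,4}
  roc4 <- empirical_roc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  op4 <- operating_point(roc4)
  expect_equal(op4$cutoff, 3)
  expect_equal(op4$sensitivity_pct, 100)
  expect_equal(op4$specificity_pct, 100)

  sep <- empirical_roc(c(0.1, 0.2, 0.9, 1), c(F, F, T, T))
  ops <- operating_point(sep)
  expect_equal(c(ops$sensitivity_pct, ops$specificity_pct), c(100, 100))
})

test_that("discrimination simulation summarizes replicates reproducibly", {
  a <- simulate_discrimination(n_reps = 10, seed = 3)
  b <- simulate_discrimination(n_reps = 10, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a$replicates), 10L)
  expect_true(all(a$replicates$auc >= 0 & a$replicates$auc <= 1))
  expect_true(all(a$replicates$anova_p >= 0 & a$replicates$anova_p <= 1))
})
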