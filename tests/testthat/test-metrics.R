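# Metric suite: printed-formula arithmetic, degenerate inputs, and oracle
# equivalence against explicit-loop implementations.

test_that("confusion counts match elementwise comparison", {
  g <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(confusion_counts(g, g)[c("fp", "fn")], list(fp = 0L, fn = 0L))
  inv <- 1 - g
  cc <- confusion_counts(inv, g)
  expect_equal(cc[c("tp", "tn")], list(tp = 0L, tn = 0L))
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")

  set.seed(30)
  for (r in 1:10) {
    p <- matrix(rbinom(64, 1, 0.4), 8, 8)
    t <- matrix(rbinom(64, 1, 0.3), 8, 8)
    expect_identical(confusion_counts(p, t), loop_confusion(p, t))
  }
})

test_that("basic rates and Dice follow the printed formulas", {
  cc <- list(tp = 3, fp = 1, tn = 4, fn = 2)
  r <- basic_rates(cc)
  expect_equal(r, list(sen = 0.6, spe = 0.8, acc = 0.7, fdr = 0.25))
  expect_equal(dice(cc), 6 / 9)

  perfect <- list(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(basic_rates(perfect),
               list(sen = 1, spe = 1, acc = 1, fdr = 0))
  expect_equal(dice(perfect), 1)
  expect_equal(dice(list(tp = 0, fp = 2, tn = 6, fn = 2)), 0)

  degenerate <- list(tp = 0, fp = 0, tn = 8, fn = 2)
  expect_true(is.na(basic_rates(degenerate)$fdr))
  expect_true(is.na(dice(list(tp = 0, fp = 0, tn = 8, fn = 0))))
})

test_that("kappa follows the marginal expansion and its limits", {
  expect_equal(kappa_score(list(tp = 4, fp = 0, tn = 6, fn = 0)), 1)
  # matched marginals, prediction independent of truth
  expect_equal(kappa_score(list(tp = 1, fp = 1, tn = 1, fn = 1)), 0)
  # hand-evaluated: pe = ((3+2)(3+1) + (4+1)(4+2))/100 = 0.5
  k <- kappa_score(list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(k, (0.7 - 0.5) / 0.5, tolerance = 1e-12)
  expect_equal(k, cohen_kappa_standard(list(tp = 3, fp = 1, tn = 4, fn = 2)),
               tolerance = 1e-12)
  expect_true(is.na(kappa_score(list(tp = 4, fp = 0, tn = 0, fn = 0))))
})

test_that("G-mean uses the root form with the product as an option", {
  expect_equal(g_mean(list(tp = 5, fp = 0, tn = 5, fn = 0)), 1)
  expect_equal(g_mean(list(tp = 0, fp = 0, tn = 4, fn = 2)), 0)
  cc <- list(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(g_mean(cc), sqrt(0.48), tolerance = 1e-12)
  expect_equal(g_mean(cc), 0.6928, tolerance = 1e-4)
  expect_equal(g_mean(cc, no_sqrt = TRUE), 0.48, tolerance = 1e-12)
})

test_that("AUC is the pairwise ranking probability", {
  g <- c(1, 1, 0, 0, 0, 0)
  expect_equal(auc_score(c(.9, .8, .3, .2, .1, .05), g), 1)
  expect_equal(auc_score(rep(0.4, 6), g), 0.5)
  expect_true(is.na(auc_score(runif(6), rep(1, 6))))

  set.seed(31)
  for (r in 1:10) {
    s <- round(runif(6), 1)   # coarse grid provokes ties
    gt <- rbinom(6, 1, 0.5)
    if (sum(gt) %in% c(0, 6)) next
    expect_equal(auc_score(s, gt), loop_auc(s, gt))
  }
  # invariance under strictly monotone transforms
  s <- runif(64); gt <- rbinom(64, 1, 0.3)
  expect_equal(auc_score(exp(3 * s) - 1, gt), auc_score(s, gt))
})

test_that("every metric matches its loop oracle on random grids", {
  set.seed(32)
  for (r in 1:50) {
    scores <- matrix(runif(64), 8, 8)
    gt <- matrix(rbinom(64, 1, runif(1, 0.2, 0.8)), 8, 8)
    pred <- (scores >= 0.5) + 0
    cc <- confusion_counts(pred, gt)
    lc <- loop_confusion(pred, gt)
    expect_identical(cc, lc)
    lr <- list(sen = if (lc$tp + lc$fn > 0) lc$tp / (lc$tp + lc$fn) else NA_real_,
               spe = if (lc$tn + lc$fp > 0) lc$tn / (lc$tn + lc$fp) else NA_real_,
               acc = (lc$tp + lc$tn) / 64,
               fdr = if (lc$fp + lc$tp > 0) lc$fp / (lc$fp + lc$tp) else NA_real_)
    expect_equal(basic_rates(cc), lr)
    if (sum(gt) %in% c(0, 64)) next
    expect_equal(auc_score(scores, gt), loop_auc(scores, gt))
    expect_equal(kappa_score(cc), cohen_kappa_standard(cc), tolerance = 1e-12)
    expect_identical(cc$tp + cc$fp + cc$tn + cc$fn, 64L)
  }
})

test_that("dataset evaluation aggregates per image or pooled", {
  set.seed(33)
  s1 <- matrix(runif(16), 4, 4); g1 <- matrix(rbinom(16, 1, 0.5), 4, 4)
  s2 <- matrix(runif(16), 4, 4); g2 <- matrix(rbinom(16, 1, 0.5), 4, 4)

  one <- evaluate_dataset(list(s1), list(g1))
  expect_identical(nrow(one), 2L)
  expect_equal(as.numeric(one[1, metric_names]),
               as.numeric(one[2, metric_names]))

  dup <- evaluate_dataset(list(s1, s1), list(g1, g1))
  expect_equal(as.numeric(dup[3, metric_names]),
               as.numeric(one[2, metric_names]))

  two <- evaluate_dataset(list(s1, s2), list(g1, g2))
  r1 <- metric_row(s1, g1, 0.5, FALSE)
  r2 <- metric_row(s2, g2, 0.5, FALSE)
  expect_equal(two$dice[3], mean(c(r1$dice, r2$dice)))
  expect_equal(two$kappa[3], mean(c(r1$kappa, r2$kappa)))

  pooled <- evaluate_dataset(list(s1, s2), list(g1, g2),
                             aggregation = "pooled")
  ccp <- confusion_counts(cbind(s1 >= 0.5, s2 >= 0.5) + 0, cbind(g1, g2))
  expect_equal(pooled$dice[3], dice(ccp))

  expect_error(evaluate_dataset(list(), list()), "empty")
})

test_that("metric reports round-trip through CSV", {
  set.seed(34)
  s <- matrix(runif(16), 4, 4); g <- matrix(rbinom(16, 1, 0.5), 4, 4)
  rep1 <- evaluate_dataset(list(s), list(g))
  path <- tempfile(fileext = ".csv")
  write_metrics_report(rep1, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("image", metric_names))
  expect_equal(back$dice, rep1$dice, tolerance = 1e-12)
})
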