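test_that("roc_auc matches pairwise enumeration, ties counted 1/2", {
  expect_equal(roc_auc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 0, 0, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "undefined")

  set.seed(5)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # coarse grid forces ties
    expect_equal(roc_auc(s, y), auc_bruteforce(s, y))
  }
})

test_that("roc_auc agrees with pROC and is invariant to monotone transforms", {
  set.seed(8)
  for (rep in 1:10) {
    n <- 60
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- runif(n)
    expect_equal(roc_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
    expect_equal(roc_auc(s, y), roc_auc(plogis(5 * s - 2), y))
    expect_equal(roc_auc(s, y), roc_auc(s^3, y))
  }
})

test_that("pr_auc follows the average-precision formulation", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  # ranked list: 0.8 negative first, then the positive at precision 1/2
  expect_equal(pr_auc(c(0.2, 0.8), c(1, 0)), 0.5)
  expect_error(pr_auc(c(0.2, 0.8), c(0, 0)), "positive")

  # random scores: AUPRC converges to the prevalence
  set.seed(9)
  y <- rbinom(1e4, 1, 0.2)
  s <- runif(1e4)
  expect_equal(pr_auc(s, y), mean(y), tolerance = 0.03)
})

test_that("binary metrics evaluate the standard formulas", {
  bm <- binary_metrics(list(tp = 8, tn = 80, fp = 10, fn = 2))
  expect_equal(bm$f1, 16 / 28)
  expect_equal(bm$mcc, (8 * 80 - 10 * 2) / sqrt(18 * 10 * 90 * 82))
  expect_equal(bm$sensitivity, 0.8)
  expect_false(bm$degenerate)

  perfect <- binary_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(c(perfect$mcc, perfect$f1, perfect$sensitivity), c(1, 1, 1))

  allneg <- binary_metrics(list(tp = 0, tn = 8, fp = 0, fn = 2))
  expect_equal(c(allneg$mcc, allneg$f1, allneg$sensitivity), c(0, 0, 0))
  expect_true(allneg$degenerate)
})

test_that("MCC matches the correlation oracle on random confusion tables", {
  set.seed(21)
  for (rep in 1:200) {
    cc <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("tp", "tn", "fp", "fn")))
    if (sum(unlist(cc)) == 0) next
    oracle <- mcc_cor_oracle(cc$tp, cc$tn, cc$fp, cc$fn)
    got <- binary_metrics(cc)$mcc
    if (is.na(oracle)) expect_equal(got, 0) else expect_equal(got, oracle)
  }
})

test_that("threshold calibration matches the native disorder count", {
  refs <- list(P = ref_entry("P", "MKKL", c(1, 1, 0, 0)))
  prof <- list(P = score_profile("P", "m", c(0.9, 0.8, 0.3, 0.1)))
  t <- calibrate_threshold(prof, refs)
  expect_equal(t$threshold, 0.3)
  expect_equal(t$achieved_count, 2L)
  expect_equal(t$target_count, 2L)

  # no native disorder: the max score is the threshold, nothing called
  refs0 <- list(P = ref_entry("P", "MKKL", c(0, 0, 0, 0)))
  t0 <- calibrate_threshold(prof, refs0)
  expect_equal(t0$threshold, 0.9)
  expect_equal(t0$achieved_count, 0L)

  # fully tied scores: strict '>' makes the target unattainable; the tie
  # rule prefers fewer predicted disordered residues
  reft <- list(P = ref_entry("P", "MKKL", c(1, 1, 0, 0)))
  proft <- list(P = score_profile("P", "m", rep(0.5, 4)))
  tt <- calibrate_threshold(proft, reft)
  expect_equal(tt$threshold, 0.5)
  expect_equal(tt$achieved_count, 0L)
})

test_that("calibration is exact on distinct pools and minimal on tied pools", {
  set.seed(33)
  for (rep in 1:40) {
    n <- sample(5:60, 1)
    y <- sample(0:1, n, replace = TRUE)
    refs <- list(P = ref_entry("P", paste(rep("A", n), collapse = ""), y))
    s_distinct <- sample(seq_len(1000), n) / 1000
    t1 <- calibrate_threshold(list(P = score_profile("P", "m", s_distinct)), refs)
    expect_equal(t1$achieved_count, sum(y))

    s_tied <- sample(c(0.2, 0.5, 0.8), n, replace = TRUE)
    t2 <- calibrate_threshold(list(P = score_profile("P", "m", s_tied)), refs)
    best_obj <- min(vapply(c(0, unique(s_tied)),
                           function(t) abs(sum(s_tied > t) - sum(y)), 0))
    expect_equal(abs(t2$achieved_count - sum(y)), best_obj)
  }
})

test_that("binarization uses a strict cut-off", {
  p <- binarize(score_profile("P", "m", c(0.4, 0.6)), 0.5)
  expect_equal(p$binary, c(0L, 1L))
  expect_equal(binarize(score_profile("P", "m", c(0.5, 0.5)), 0.5)$binary,
               c(0L, 0L))
  expect_equal(binarize(score_profile("P", "m", c(0.1, 0.2)), 0.5)$binary,
               c(0L, 0L))
})

test_that("content metrics: fraction, MAE and Spearman correlation", {
  expect_equal(disorder_content(c(0, 0, 0, 0)), 0)
  expect_equal(disorder_content(c(1, 1, 1, 1)), 1)
  expect_equal(disorder_content(c(1, 0, 1, 0, 1)), 0.6)

  expect_equal(content_mae(c(0.5, 0.2), c(0.5, 0.2)), 0)
  expect_equal(content_mae(0.5, 0.2), 0.3)
  expect_equal(content_mae(c(0, 1), c(1, 0)), 1)
  expect_error(content_mae(c(0.1, 0.2), 0.3), "length")

  expect_equal(content_scc(1:5 / 5, 1:5 / 5), 1)
  expect_equal(content_scc(1:5 / 5, 5:1 / 5), -1)
  expect_equal(content_scc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 1 - 6 * 2 / (4 * 15))
  expect_error(content_scc(c(0.5, 0.5), c(0.1, 0.9)), "variance")
})

test_that("SCC equals the classical no-tie formula on tie-free inputs", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    x <- sample(seq_len(500), n) / 500
    y <- sample(seq_len(500), n) / 500
    d <- rank(x) - rank(y)
    expect_equal(content_scc(x, y), 1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
})

test_that("FDP evaluation applies strict content cut-offs with nesting", {
  expect_equal(fdp_eval(c(1, 0.5), c(1, 0.5), 0.9)$f1, 1)
  r <- fdp_eval(c(1.0, 1.0), c(1.0, 0.5), 0.90)
  expect_equal(r$f1, 2 / 3)
  expect_equal(r$sensitivity, 1)
  expect_error(fdp_eval(c(0.5, 0.6), c(0.5, 0.6), 0.9), "no natively")

  set.seed(4)
  pred <- runif(60)
  for (k in 1:10) {
    p99 <- which(pred > 0.99); p90 <- which(pred > 0.90); p80 <- which(pred > 0.80)
    expect_true(all(p99 %in% p90) && all(p90 %in% p80))
    pred <- runif(60)
  }
})

test_that("metric outputs respect their declared ranges on random inputs", {
  set.seed(55)
  for (rep in 1:30) {
    n <- sample(10:100, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- runif(n)
    expect_true(roc_auc(s, y) >= 0 && roc_auc(s, y) <= 1)
    expect_true(pr_auc(s, y) >= 0 && pr_auc(s, y) <= 1)
    bm <- binary_metrics(confusion_counts(as.integer(s > 0.5), y))
    expect_true(bm$mcc >= -1 && bm$mcc <= 1)
    expect_true(bm$f1 >= 0 && bm$f1 <= 1)
  }
})
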