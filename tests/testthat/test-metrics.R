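test_that("confusion counting and label symmetry", {
  truth <- rep(c("BTT", "IDA"), c(7, 3))
  cm0 <- confusion_matrix(truth, truth)
  expect_equal(c(cm0$fp, cm0$fn), c(0, 0))

  cm1 <- confusion_matrix(truth, rep("BTT", 10))
  expect_equal(unlist(cm1[c("tp", "fp", "fn", "tn")]),
               c(tp = 7, fp = 3, fn = 0, tn = 0))

  pred <- c(rep("BTT", 5), rep("IDA", 5))
  cm <- confusion_matrix(truth, pred)
  flipped <- confusion_matrix(truth, ifelse(pred == "BTT", "IDA", "BTT"))
  expect_equal(c(flipped$tp, flipped$tn), c(cm$fn, cm$fp))

  expect_error(confusion_matrix("BTT", "beta"), "Unknown label")
})

test_that("metric_set reproduces the reconstructed published rows", {
  # cells recovered from printed Youden 81.58 / accuracy 91.51 at 708/470
  ms <- metric_set(new_confusion_matrix(668, 60, 40, 410))
  expect_equal(round(ms$dor, 2), 114.12)
  expect_equal(round(100 * ms$f_measure, 2), 93.04)
  expect_equal(round(100 * ms$youden, 2), 81.58)

  perfect <- metric_set(new_confusion_matrix(708, 0, 0, 470))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$nlr, 0)
  expect_equal(perfect$dor, Inf)

  # fn = 0 with false positives: sensitivity 1, NLR 0, DOR infinite
  sl <- metric_set(new_confusion_matrix(708, 398, 0, 72))
  expect_equal(sl$sensitivity, 1)
  expect_equal(sl$nlr, 0)
  expect_equal(sl$dor, Inf)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(101)
  for (i in 1:50) {
    cm <- random_confusion()
    ms <- metric_set(cm)
    expect_equal(ms$fpr, 1 - ms$specificity)
    expect_equal(ms$fnr, 1 - ms$sensitivity)
    expect_equal(ms$youden, ms$sensitivity + ms$specificity - 1)
    expect_equal(ms$plr, ms$sensitivity / (1 - ms$specificity))
    expect_equal(ms$nlr, (1 - ms$sensitivity) / ms$specificity)
    # identity chain: DOR = PLR/NLR = tp*tn/(fp*fn)
    expect_equal(ms$dor, ms$plr / ms$nlr)
    expect_equal(ms$dor, (cm$tp * cm$tn) / (cm$fp * cm$fn))
    expect_equal(ms$f_measure,
                 2 * ms$ppv * ms$sensitivity / (ms$ppv + ms$sensitivity))
    # binary-classifier AUC identities
    expect_equal(ms$auc, (ms$sensitivity + ms$specificity) / 2)
    expect_equal(ms$auc, (ms$youden + 1) / 2)
  }
})

test_that("confidence intervals behave at boundaries and shrink with level", {
  cis0 <- suppressWarnings(metric_cis(new_confusion_matrix(0, 0, 10, 10)))
  expect_equal(unname(cis0$lower[cis0$measure == "sensitivity"]), 0)

  cis <- metric_cis(new_confusion_matrix(668, 60, 40, 410))
  dor <- cis[cis$measure == "dor", ]
  # log-method interval for DOR 114.12: same order as the published 75-173
  expect_gt(dor$lower, 65); expect_lt(dor$lower, 85)
  expect_gt(dor$upper, 160); expect_lt(dor$upper, 185)
  # hand-computed log-method bounds
  se <- sqrt(1 / 668 + 1 / 60 + 1 / 40 + 1 / 410)
  expect_equal(unname(dor$lower), exp(log(114.1166667) - qnorm(0.975) * se),
               tolerance = 1e-6)

  narrow <- metric_cis(new_confusion_matrix(668, 60, 40, 410), level = 0.5)
  for (m in c("sensitivity", "dor", "youden")) {
    expect_gte(narrow$lower[narrow$measure == m], cis$lower[cis$measure == m])
    expect_lte(narrow$upper[narrow$measure == m], cis$upper[cis$measure == m])
  }

  # Clopper-Pearson cross-check against the exact binomial test interval
  bt <- stats::binom.test(668, 708)$conf.int
  expect_equal(unname(unlist(cis[cis$measure == "sensitivity", c("lower", "upper")])),
               c(bt[1], bt[2]), tolerance = 1e-9)
})

test_that("empirical AUC equals Mann-Whitney concordance with ties at one half", {
  truth <- rep(c("BTT", "IDA"), c(60, 40))

  expect_equal(empirical_auc(rep(1, 100), truth)$auc, 0.5)
  expect_equal(empirical_auc(c(rep(2, 60), rep(1, 40)), truth)$auc, 1.0)

  set.seed(7)
  scores <- c(rnorm(60, 1), rnorm(40))
  idx <- sample(100, 30)
  scores[idx] <- round(scores[idx])  # force some ties
  roc <- empirical_auc(scores, truth)
  # brute-force pairwise concordance
  pos <- scores[truth == "BTT"]; neg <- scores[truth == "IDA"]
  conc <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc$auc, conc)
  # independent implementation cross-check
  proc <- suppressMessages(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("IDA", "BTT"),
    direction = "<")))
  expect_equal(roc$auc, as.numeric(proc))

  # binary 0/1 score: AUC = (sens + spec) / 2, e.g. 0.9675/0.9128 -> 0.940
  sens <- 685 / 708; spec <- 429 / 470
  truth2 <- rep(c("BTT", "IDA"), c(708, 470))
  pred2 <- c(rep(c(1, 0), c(685, 23)), rep(c(1, 0), c(41, 429)))
  roc2 <- empirical_auc(pred2, truth2)
  expect_equal(roc2$auc, (sens + spec) / 2)
  expect_equal(round(roc2$auc, 3), 0.940)

  # lower-is-BTT orientation
  expect_equal(empirical_auc(c(rep(1, 60), rep(2, 40)), truth,
                             direction = "lower-is-BTT")$auc, 1.0)

  expect_error(empirical_auc(1:5, rep("BTT", 5)), "Both classes")

  # ROC points are monotone in both coordinates
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
})

test_that("paired DeLong comparison is antisymmetric and calibrated", {
  truth <- rep(c("BTT", "IDA"), c(300, 200))
  set.seed(21)
  good <- c(rnorm(300, 3.5), rnorm(200))   # AUC near 0.99
  noise <- rnorm(500)                      # AUC near 0.5

  ra <- empirical_auc(good, truth); rb <- empirical_auc(noise, truth)
  self <- compare_auc(ra, ra)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)

  ab <- compare_auc(ra, rb); ba <- compare_auc(rb, ra)
  expect_equal(ab$z, -ba$z)
  expect_lt(ab$p_value, 0.001)

  # cross-check z against the reference DeLong implementation
  roc_a <- suppressMessages(pROC::roc(truth, good, levels = c("IDA", "BTT"),
                                      direction = "<"))
  roc_b <- suppressMessages(pROC::roc(truth, noise, levels = c("IDA", "BTT"),
                                      direction = "<"))
  ref <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
  expect_equal(abs(ab$z), abs(unname(ref$statistic)), tolerance = 1e-6)

  rc <- empirical_auc(good[1:400], truth[1:400])
  expect_error(compare_auc(ra, rc), "paired")
})

test_that("summary reconstruction inverts the metric computation", {
  cm <- recover_confusion_from_summary(81.58, 91.51, 708, 470)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 668, fp = 60, fn = 40, tn = 410))

  expect_equal(unlist(recover_confusion_from_summary(100, 100, 10, 5)[
    c("tp", "fp", "fn", "tn")]), c(tp = 10, fp = 0, fn = 0, tn = 5))

  cm3 <- recover_confusion_from_summary(88.03, 94.57, 708, 470)
  expect_equal(unlist(cm3[c("tp", "fp", "fn", "tn")]),
               c(tp = 685, fp = 41, fn = 23, tn = 429))

  # round trip: recover(metric_set(cm)) is the identity at the study sizes
  set.seed(33)
  for (i in 1:25) {
    tp <- sample(0:708, 1); tn <- sample(0:470, 1)
    cm0 <- new_confusion_matrix(tp, 470 - tn, 708 - tp, tn)
    ms <- metric_set(cm0)
    back <- recover_confusion_from_summary(round(100 * ms$youden, 2),
                                           round(100 * ms$accuracy, 2),
                                           708, 470)
    ms2 <- metric_set(back)
    expect_equal(round(100 * ms2$youden, 2), round(100 * ms$youden, 2))
    expect_equal(round(100 * ms2$accuracy, 2), round(100 * ms$accuracy, 2))
  }

  expect_error(recover_confusion_from_summary(90, 50, 708, 470), "outside")
  expect_error(recover_confusion_from_summary(50, 75, 100, 100), "unequal")
})
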