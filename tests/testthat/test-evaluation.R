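test_that("confusion counts partition the data with the >= tie rule", {
  cc <- confusion_counts(c(1, 0), c(0.9, 0.1))
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(1L, 1L, 0L, 0L))

  # scores exactly at the threshold predict positive
  tie <- confusion_counts(c(1, 0, 1), rep(0.5, 3))
  expect_equal(tie$TP, 2L)
  expect_equal(tie$FP, 1L)
  expect_equal(tie$TN + tie$FN, 0L)

  expect_error(confusion_counts(numeric(0), numeric(0)), "empty")

  # brute-force loop oracle on a random set
  set.seed(41)
  y <- rbinom(100, 1, 0.3)
  s <- runif(100)
  cc <- confusion_counts(y, s, 0.4)
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in 1:100) {
    if (s[i] >= 0.4) { if (y[i] == 1) tp <- tp + 1L else fp <- fp + 1L }
    else { if (y[i] == 1) fn <- fn + 1L else tn <- tn + 1L }
  }
  expect_equal(c(cc$TP, cc$FP, cc$TN, cc$FN), c(tp, fp, tn, fn))
  expect_equal(cc$TP + cc$FN, sum(y == 1))
  expect_equal(cc$TN + cc$FP, sum(y == 0))
})

test_that("threshold metrics follow their formulas and conventions", {
  # perfect classifier
  perf <- eval_metrics(structure(list(TP = 10L, FP = 0L, TN = 90L, FN = 0L,
                                      threshold = 0.5),
                                 class = "confusion_counts"))
  expect_equal(perf$Sens, 1)
  expect_equal(perf$Spec, 1)
  expect_equal(perf$ACC, 1)
  expect_equal(perf$MCC, 1)
  expect_equal(perf$GM, 1)

  # all-negative predictions: MCC denominator is zero -> 0, precision -> 0
  degen <- eval_metrics(structure(list(TP = 0L, FP = 0L, TN = 90L, FN = 10L,
                                       threshold = 0.5),
                                  class = "confusion_counts"))
  expect_equal(degen$MCC, 0)
  expect_equal(degen$Precision, 0)
  expect_equal(degen$GM, 0)

  expect_error(eval_metrics(structure(list(TP = 0L, FP = 0L, TN = 5L,
                                           FN = 0L, threshold = 0.5),
                                      class = "confusion_counts")),
               "both classes")

  # accuracy identity ACC = (Sens*P + Spec*N) / (P + N) on random counts
  set.seed(42)
  for (i in 1:20) {
    cnt <- as.list(rmultinom(1, 200, c(0.2, 0.1, 0.6, 0.1))[, 1] + 1L)
    names(cnt) <- c("TP", "FP", "TN", "FN")
    cnt$threshold <- 0.5
    m <- eval_metrics(structure(cnt, class = "confusion_counts"))
    P <- cnt$TP + cnt$FN
    N <- cnt$TN + cnt$FP
    expect_equal(m$ACC, (m$Sens * P + m$Spec * N) / (P + N))
    expect_equal(m$GM, sqrt(m$Sens * m$Spec))
    expect_equal(m$GM_pr, sqrt(m$Precision * m$Sens))
    expect_gte(m$MCC, -1); expect_lte(m$MCC, 1)
  }
})

test_that("AUC equals the Mann-Whitney pair statistic", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc_score(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(auc_score(c(1, 1), c(0.5, 0.6)), "both classes")

  set.seed(43)
  for (i in 1:10) {
    y <- c(rbinom(28, 1, 0.4), 0, 1)   # both classes guaranteed
    s <- round(runif(30), 2)           # rounding forces ties
    expect_equal(auc_score(y, s), reference_auc(y, s))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(44)
  y <- c(rbinom(48, 1, 0.3), 0, 1)
  s <- runif(50)
  a <- auc_score(y, s)
  expect_equal(auc_score(y, 10 * s - 2), a)
  expect_equal(auc_score(y, exp(s)), a)
  expect_equal(auc_score(y, rank(s)), a)
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(45)
  y <- c(rbinom(98, 1, 0.25), 0, 1)
  s <- round(runif(100), 2)
  expect_equal(auc_score(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("AUPRC follows the grouped descending sweep", {
  expect_equal(auprc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  # all scores equal: precision is the prevalence everywhere
  expect_equal(auprc_score(c(1, 0, 0, 0), rep(0.3, 4)), 0.25)
  expect_error(auprc_score(c(0, 0), c(0.1, 0.2)), "no positive")

  set.seed(46)
  for (i in 1:10) {
    y <- c(rbinom(28, 1, 0.3), 1, 0)
    s <- round(runif(30), 2)
    expect_equal(auprc_score(y, s), reference_auprc(y, s))
  }

  # better-than-random classifier never dips below prevalence
  d <- toy_motif_set(n_pos = 10L, n_neg = 40L, length = 30L, seed = 47L)
  sc <- consensus_scan_scores(d$seq, list(motif_model(
    "m", enhancerPRS:::consensus_pwm("TGACGTCATT", 0.99), 1)), 1L)
  expect_gte(auprc_score(d$label, sc), 0.2)
})

test_that("two-fold cross-validation aggregates per-fold reports by their mean", {
  d <- toy_motif_set(n_pos = 10L, n_neg = 30L, length = 60L, seed = 48L)
  cv <- cross_validate(d, tiny_net_cfg(), fast_obj_cfg(3L, 48L), k = 2L,
                       inner_val_fraction = 0.2)
  expect_length(cv$folds, 2L)
  expect_equal(cv$mean[["AUC"]],
               mean(c(cv$folds[[1]]$AUC, cv$folds[[2]]$AUC)))
  expect_equal(cv$mean[["GM"]],
               mean(c(cv$folds[[1]]$GM, cv$folds[[2]]$GM)))
})

test_that("cross-validated models separate planted-motif data", {
  spec <- synthetic_spec(
    shared_motifs = list(
      motif_model("m1", enhancerPRS:::consensus_pwm("TGACTCAGCA", 0.95), 0.9),
      motif_model("m2", enhancerPRS:::consensus_pwm("CACGTGAC", 0.95), 0.9),
      motif_model("m3", enhancerPRS:::consensus_pwm("GATAAGCGATAA", 0.95), 0.9)),
    length = 150L, n_pretrain_pos = 300L, ratio = 5L)
  cfg <- network_config(filter_number = 12L, filter_length = 9L,
                        pool_size = 8L, gru_units = 8L, input_length = 150L)
  aucs <- vapply(1:3, function(seed) {
    d <- generate_pretraining_set(spec, seed = 10L + seed)
    cv <- cross_validate(d, cfg,
                         objective_config(max_epochs = 20L, seed = seed,
                                          learning_rate = 5e-3), k = 3L)
    cv$mean[["AUC"]]
  }, numeric(1))
  expect_gt(mean(aucs), 0.9)
})

test_that("strategy comparison implements the paired one-sided t test", {
  # identical strategies: t = 0, p = 0.5
  x <- c(0.7, 0.8, 0.6, 0.75)
  same <- compare_strategies(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 0.5)

  # constant shift: zero variance of differences, degenerate branch
  shift <- compare_strategies(x + 1, x)
  expect_true(shift$degenerate)
  expect_equal(shift$p_value, 0)
  expect_equal(compare_strategies(x, x + 1)$p_value, 1)

  expect_error(compare_strategies(c(1, 2), c(1, 2)), "at least 3")

  # textbook-formula recomputation on random paired samples
  set.seed(49)
  a <- runif(23, 0.5, 0.9)
  b <- a - rnorm(23, 0.15, 0.08)
  cmp <- compare_strategies(a, b)
  d <- a - b
  expect_equal(cmp$t, mean(d) / (sd(d) / sqrt(23)))
  expect_equal(cmp$p_value, pt(cmp$t, 22, lower.tail = FALSE))
  tt <- t.test(a, b, paired = TRUE, alternative = "greater")
  expect_equal(cmp$t, unname(tt$statistic))
  expect_equal(cmp$p_value, tt$p.value)

  # Welch variant against the base implementation
  w <- compare_strategies(a, b, paired = FALSE)
  tw <- t.test(a, b, alternative = "greater")
  expect_equal(w$t, unname(tw$statistic))
  expect_equal(w$p_value, tw$p.value)
})

test_that("evaluation reports serialize to the table column order", {
  set.seed(50)
  y <- c(rbinom(48, 1, 0.3), 1, 0)
  s <- runif(50)
  rep <- eval_report(y, s)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  eval_report_tsv(rep, tsv)
  df <- read.delim(tsv)
  expect_equal(names(df), c("ACC", "AUC", "SEN", "SPE", "MCC", "GM"))
  expect_equal(df$GM, rep$GM)
  js <- withr::local_tempfile(fileext = ".json")
  eval_report_json(rep, js)
  back <- jsonlite::read_json(js)
  expect_equal(back$AUC, rep$AUC)
})
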