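#' Confusion counts at a score threshold
#'
#' A score greater than or equal to the threshold predicts the positive
#' class (so scores tied exactly at the threshold count as positive calls).
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param threshold decision threshold (default 0.5).
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN` and the threshold used.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  pred <- scores >= threshold
  structure(list(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1),
                 threshold = threshold),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts (threshold ", x$threshold, "): TP=", x$TP, " FP=",
      x$FP, " TN=", x$TN, " FN=", x$FN, "\n", sep = "")
  invisible(x)
}

#' Threshold-based evaluation metrics
#'
#' Sensitivity (recall), specificity, precision, accuracy, Matthews
#' correlation and two geometric-mean variants: `GM_ss = sqrt(Sens * Spec)`
#' and `GM_pr = sqrt(Precision * Recall)`. `GM_ss` is reported as the
#' default `GM` — it is the balance index the reference result tables use
#' for imbalanced enhancer data. Conventions for degenerate counts: MCC with
#' a zero denominator factor is 0; precision with no positive calls is 0.
#'
#' @param counts a [confusion_counts()] object, requiring at least one
#'   positive and one negative record.
#' @return An object of class `eval_report` (a list of named metrics).
#' @export
eval_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  P <- counts$TP + counts$FN
  N <- counts$TN + counts$FP
  if (P == 0L || N == 0L) {
    stop("both classes must be present (P = ", P, ", N = ", N, ")")
  }
  sens <- counts$TP / P
  spec <- counts$TN / N
  prec <- if (counts$TP + counts$FP == 0) 0 else counts$TP / (counts$TP + counts$FP)
  acc <- (counts$TP + counts$TN) / (P + N)
  den <- prod(sqrt(c(counts$TP + counts$FN, counts$TP + counts$FP,
                     counts$TN + counts$FP, counts$TN + counts$FN)))
  mcc <- if (den == 0) 0 else
    (counts$TP * counts$TN - counts$FP * counts$FN) / den
  structure(list(Sens = sens, Spec = spec, Precision = prec, ACC = acc,
                 MCC = mcc, GM = sqrt(sens * spec),
                 GM_pr = sqrt(prec * sens), threshold = counts$threshold),
            class = "eval_report")
}

#' Full evaluation report including ranking metrics
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param threshold decision threshold (default 0.5).
#' @return An `eval_report` including `AUC` and `AUPRC`.
#' @export
eval_report <- function(labels, scores, threshold = 0.5) {
  rep <- eval_metrics(confusion_counts(labels, scores, threshold))
  rep$AUC <- auc_score(labels, scores)
  rep$AUPRC <- auprc_score(labels, scores)
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Sens %.3f  Spec %.3f  Prec %.3f  ACC %.3f  MCC %.3f  GM %.3f",
              x$Sens, x$Spec, x$Precision, x$ACC, x$MCC, x$GM))
  if (!is.null(x$AUC)) cat(sprintf("  AUC %.3f  AUPRC %.3f", x$AUC, x$AUPRC))
  cat("\n")
  invisible(x)
}

#' Serialize an evaluation report
#'
#' `eval_report_tsv()` mirrors the reference table column order (ACC, AUC,
#' SEN, SPE, MCC, GM); `eval_report_json()` writes all fields.
#'
#' @param x an `eval_report`.
#' @param path output path.
#' @export
eval_report_tsv <- function(x, path) {
  df <- data.frame(ACC = x$ACC, AUC = if (is.null(x$AUC)) NA else x$AUC,
                   SEN = x$Sens, SPE = x$Spec, MCC = x$MCC, GM = x$GM)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname eval_report_tsv
#' @export
eval_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic via midranks:
#' `(concordant positive-negative pairs + ties/2) / (P*N)`, which makes it
#' invariant under any strictly monotone transform of the scores.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0L || N == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Step-curve area from a descending-score sweep with tied scores grouped:
#' `sum over thresholds of (recall increment) * precision`. With all scores
#' equal this reduces to the positive-class prevalence.
#'
#' @param labels 0/1 vector with at least one positive.
#' @param scores numeric scores.
#' @return AUPRC in `(0, 1]`.
#' @export
auprc_score <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  P <- sum(labels == 1)
  if (P == 0L) stop("no positive records")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp_end <- cumsum(rle(sc)$lengths)   # last index of each tied score group
  tp <- cumsum(lab)[grp_end]
  n_pred <- grp_end
  prec <- tp / n_pred
  recall <- tp / P
  sum(diff(c(0, recall)) * prec)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Trains k models, each on k-1 folds with an inner validation split carved
#' from the training folds for epoch selection, evaluates each on its
#' held-out fold, and reports per-fold and (unweighted) mean metrics.
#'
#' @param dataset a `sequence_set`.
#' @param cfg a [network_config()].
#' @param obj_cfg an [objective_config()].
#' @param k fold count (default 5).
#' @param inner_val_fraction fraction of the training folds held out as the
#'   inner validation set (default 1/11).
#' @return A list: `folds` (list of per-fold `eval_report`s) and `mean`
#'   (named numeric vector of averaged metrics).
#' @export
cross_validate <- function(dataset, cfg, obj_cfg = objective_config(),
                           k = 5L, inner_val_fraction = 1 / 11) {
  sp <- make_splits(dataset, split_spec(k = k, seed = obj_cfg$seed))
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_set <- sp$folds[[f]]
    if (length(unique(test_set$label)) < 2L) {
      stop("fold ", f, " contains a single class")
    }
    train_pool <- subset_sequence_set(dataset, which(sp$fold_ids != f))
    inner <- stratified_holdout(train_pool, inner_val_fraction,
                                seed = obj_cfg$seed + f)
    params <- build_network(cfg, seed = obj_cfg$seed + f)
    run <- train_network(params, inner$train, inner$val, obj_cfg,
                         select_epoch = TRUE)
    reports[[f]] <- eval_report(test_set$label, forward(run$params, test_set))
  }
  keys <- c("Sens", "Spec", "Precision", "ACC", "MCC", "GM", "GM_pr",
            "AUC", "AUPRC")
  means <- vapply(keys, function(kk) {
    mean(vapply(reports, function(r) r[[kk]], numeric(1)))
  }, numeric(1))
  list(folds = reports, mean = means)
}

#' Paired one-sided comparison of two training strategies
#'
#' Given matched per-tissue performance values for two strategies, tests
#' whether strategy `a` exceeds strategy `b` with a paired one-sided t test
#' on the differences (`t = mean(d) / (sd(d)/sqrt(n))`, p from the t
#' distribution with n-1 df). Zero-variance differences are reported as the
#' degenerate branch: p = 0 if the constant difference favours `a`, 1 if it
#' favours `b`, and 0.5 (t = 0) when the strategies are identical. An
#' unpaired Welch variant is available.
#'
#' @param a,b numeric vectors of matched per-tissue values (length >= 3,
#'   same tissue order).
#' @param paired paired test (default) or Welch two-sample.
#' @return An object of class `strategy_comparison`: means, `t`, `df`,
#'   `p_value`, `degenerate` flag.
#' @export
compare_strategies <- function(a, b, paired = TRUE) {
  if (length(a) != length(b)) stop("a and b must have matched length")
  if (length(a) < 3L) stop("need at least 3 matched tissues")
  out <- list(mean_a = mean(a), mean_b = mean(b), n = length(a),
              paired = paired, degenerate = FALSE)
  if (paired) {
    d <- a - b
    if (stats::sd(d) == 0) {
      out$degenerate <- TRUE
      out$t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      out$df <- length(d) - 1L
      out$p_value <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    } else {
      out$t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
      out$df <- length(d) - 1L
      out$p_value <- stats::pt(out$t, out$df, lower.tail = FALSE)
    }
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      out$degenerate <- TRUE
      d <- mean(a) - mean(b)
      out$t <- if (d == 0) 0 else sign(d) * Inf
      out$df <- 2L * (length(a) - 1L)
      out$p_value <- if (d > 0) 0 else if (d < 0) 1 else 0.5
    } else {
      tt <- stats::t.test(a, b, alternative = "greater", paired = FALSE)
      out$t <- unname(tt$statistic)
      out$df <- unname(tt$parameter)
      out$p_value <- tt$p.value
    }
  }
  structure(out, class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf(
    "%s one-sided comparison over %d tissues: mean(a) %.3f vs mean(b) %.3f\n",
    if (x$paired) "paired" else "Welch", x$n, x$mean_a, x$mean_b))
  cat(sprintf("  t = %.3f (df %.1f), p = %.3g%s\n", x$t, as.numeric(x$df),
              x$p_value, if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}
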