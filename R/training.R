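#' Training objective configuration
#'
#' The loss is mean binary cross-entropy plus L1 penalties on the three
#' parameter groups: `lambda1 * |M|_1 + lambda2 * |WU|_1 + lambda3 * |WM|_1`.
#' The same penalized form, evaluated on the validation set, is the epoch
#' selection objective. Defaults: small equal penalties (1e-6), adaptive
#' moment estimation at learning rate 1e-3, minibatches of 64.
#'
#' @param lambda1,lambda2,lambda3 non-negative L1 weights for the filter
#'   bank, recurrent matrices and dense weights.
#' @param learning_rate positive optimizer step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param seed integer seed driving shuffling, dropout and initialization.
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(lambda1 = 1e-6, lambda2 = 1e-6, lambda3 = 1e-6,
                             learning_rate = 1e-3, batch_size = 64L,
                             max_epochs = 100L, seed = 1L) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0, learning_rate > 0,
            batch_size >= 1L, max_epochs >= 1L)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "objective_config")
}

#' Mean binary cross-entropy
#'
#' `-(1/n) * sum(y*log(s) + (1-y)*log(1-s))`.
#'
#' @param labels 0/1 vector.
#' @param scores predicted probabilities strictly inside (0, 1).
#' @return A single non-negative number.
#' @export
cross_entropy <- function(labels, scores) {
  if (length(labels) == 0L) stop("cross_entropy of an empty vector")
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (any(scores <= 0 | scores >= 1)) stop("scores must be strictly inside (0, 1)")
  -mean(labels * log(scores) + (1 - labels) * log(1 - scores))
}

#' Penalized validation objective
#'
#' Cross-entropy of the model on a held-out batch plus the weighted L1 norms
#' of the three parameter groups. Minimizing this (rather than the training
#' loss) selects the checkpoint epoch and guards against overfitting.
#'
#' @param params a `network_params` object.
#' @param val_batch an `encoded_batch` or `sequence_set` disjoint from the
#'   training data (the caller's responsibility; ids are checked by the
#'   training drivers).
#' @param obj_cfg an [objective_config()].
#' @return A single number.
#' @export
validation_objective <- function(params, val_batch, obj_cfg) {
  if (inherits(val_batch, "sequence_set")) val_batch <- encode_batch(val_batch)
  scores <- forward(params, val_batch, train_mode = FALSE)
  ce <- cross_entropy(val_batch$labels,
                      pmin(pmax(scores, 1e-12), 1 - 1e-12))
  nrm <- l1_norms(params)
  ce + obj_cfg$lambda1 * nrm[["M"]] + obj_cfg$lambda2 * nrm[["WU"]] +
    obj_cfg$lambda3 * nrm[["WM"]]
}

add_l1_subgradient <- function(g, params, obj_cfg) {
  g$M <- g$M + obj_cfg$lambda1 * sign(params$M)
  for (dir in c("gru_fwd", "gru_bwd")) {
    for (w in c("Wz", "Wr", "Wh", "Uz", "Ur", "Uh")) {
      g[[dir]][[w]] <- g[[dir]][[w]] + obj_cfg$lambda2 * sign(params[[dir]][[w]])
    }
  }
  g$dense_W <- g$dense_W + obj_cfg$lambda3 * sign(params$dense_W)
  g
}

freeze_groups_map <- list(M = c("M", "conv_b"),
                          WU = c("gru_fwd", "gru_bwd"),
                          WM = c("dense_W", "dense_b"))

zero_frozen <- function(g, freeze) {
  for (grp in freeze) {
    for (leaf in freeze_groups_map[[grp]]) {
      g[[leaf]] <- map_params(function(p) p * 0, g[[leaf]])
    }
  }
  g
}

adam_update <- function(params, g, state, lr, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, gg) b1 * m + (1 - b1) * gg, state$m, g)
  state$v <- map_params(function(v, gg) b2 * v + (1 - b2) * gg^2, state$v, g)
  corr <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  new <- map_params(function(p, m, v) {
    r <- p - corr * m / (sqrt(v) + eps)
    attributes(r) <- attributes(p)   # gradients may carry different dims
    r
  }, unclass(params), state$m, state$v)
  attributes(new) <- attributes(params)
  list(params = new, state = state)
}

training_divergence <- function(msg, history) {
  structure(class = c("training_divergence", "error", "condition"),
            list(message = msg, call = sys.call(-1L), history = history))
}

#' Minibatch training with validation-based epoch selection
#'
#' Trains the penalized cross-entropy loss by minibatch adaptive-moment
#' gradient descent for `obj_cfg$max_epochs` epochs. After every epoch the
#' validation objective is recorded; with `select_epoch = TRUE` (the
#' pretraining protocol) the returned parameters are the checkpoint of the
#' epoch minimizing it, never simply the last epoch. With
#' `select_epoch = FALSE` (the fixed-budget retraining protocol) the final
#' epoch's parameters are returned.
#'
#' @param params initial `network_params` (random for ab-initio training, a
#'   loaded checkpoint for warm starts).
#' @param train_set,val_set non-empty `sequence_set`s containing both
#'   classes; their ids must be disjoint.
#' @param obj_cfg an [objective_config()].
#' @param select_epoch choose the validation-objective-minimizing epoch?
#' @param freeze character subset of `c("M", "WU", "WM")`: parameter groups
#'   (with their biases) excluded from updates.
#' @param provenance tag recorded in the run (`"ab_initio"` or
#'   `"warm_start"`).
#' @return An object of class `training_run`: `history` (one row per epoch),
#'   `selected_epoch`, `params`, `provenance`.
#' @export
train_network <- function(params, train_set, val_set, obj_cfg,
                          select_epoch = TRUE, freeze = character(0),
                          provenance = "ab_initio") {
  stopifnot(inherits(params, "network_params"),
            inherits(obj_cfg, "objective_config"))
  if (length(unique(train_set$label)) < 2L || length(unique(val_set$label)) < 2L) {
    stop("train and validation sets must each contain both classes")
  }
  if (length(intersect(train_set$id, val_set$id)) > 0L) {
    stop("train and validation sets share record ids")
  }
  stopifnot(all(freeze %in% names(freeze_groups_map)))
  cfg <- attr(params, "config")
  x_train <- encode_cube(train_set)
  y_train <- as.numeric(train_set$label)
  x_val <- encode_cube(val_set)
  y_val <- as.numeric(val_set$label)
  n <- length(y_train)
  bs <- min(obj_cfg$batch_size, n)

  set.seed(obj_cfg$seed)
  state <- list(t = 0L, m = zero_like(params), v = zero_like(params))
  history <- NULL
  best_obj <- Inf
  best_epoch <- 0L
  best_params <- params
  nrm_lambda <- function(p) {
    nrm <- l1_norms(p)
    obj_cfg$lambda1 * nrm[["M"]] + obj_cfg$lambda2 * nrm[["WU"]] +
      obj_cfg$lambda3 * nrm[["WM"]]
  }

  for (epoch in seq_len(obj_cfg$max_epochs)) {
    ord <- sample.int(n)
    batch_losses <- numeric(0)
    for (b in seq_len(ceiling(n / bs))) {
      idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
      xb <- x_train[, , idx, drop = FALSE]
      mask <- if (cfg$dropout_rate > 0) dropout_mask(cfg, length(idx)) else NULL
      res <- .cpp_nn_run(unclass(params), cfg$pool_size, xb, mask,
                         y_train[idx], TRUE)
      if (!is.finite(res$loss)) {
        stop(training_divergence(
          paste0("non-finite training loss at epoch ", epoch), history))
      }
      batch_losses <- c(batch_losses, res$loss)
      g <- add_l1_subgradient(res$grads, params, obj_cfg)
      g <- zero_frozen(g, freeze)
      upd <- adam_update(params, g, state, obj_cfg$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    val <- .cpp_nn_run(unclass(params), cfg$pool_size, x_val, NULL, y_val,
                       FALSE)
    val_scores <- as.numeric(val$scores)
    val_ce <- val$loss
    val_obj <- val_ce + nrm_lambda(params)
    cc <- confusion_counts(y_val, val_scores)
    met <- eval_metrics(cc)
    history <- rbind(history, data.frame(
      epoch = epoch, train_ce = mean(batch_losses), val_ce = val_ce,
      val_objective = val_obj, val_gm = met$GM, val_sens = met$Sens,
      val_auc = auc_score(y_val, val_scores)))
    if (val_obj < best_obj) {
      best_obj <- val_obj
      best_epoch <- epoch
      if (select_epoch) best_params <- params
    }
  }

  selected <- if (select_epoch) best_epoch else obj_cfg$max_epochs
  final <- if (select_epoch) best_params else params
  if (select_epoch &&
      abs(history$val_objective[selected] - min(history$val_objective)) > 1e-12) {
    stop("internal error: selected epoch does not minimize the validation objective")
  }
  structure(list(history = history, selected_epoch = selected,
                 params = final, provenance = provenance,
                 obj_cfg = obj_cfg),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat("training run (", x$provenance, "): ", nrow(x$history),
      " epoch(s), selected epoch ", x$selected_epoch, "\n", sep = "")
  if (nrow(x$history) > 0L) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final val CE %.4f, val objective %.4f, val GM %.3f\n",
                last$val_ce, last$val_objective, last$val_gm))
  }
  invisible(x)
}

check_imbalance <- function(dataset, expected_ratio = 10) {
  npos <- sum(dataset$label == 1L)
  nneg <- sum(dataset$label == 0L)
  if (npos == 0L || abs(nneg / npos - expected_ratio) > 0.5) {
    warning("dataset positive:negative ratio is 1:",
            round(nneg / max(npos, 1L), 2),
            ", not the expected 1:", expected_ratio, "; proceeding")
  }
  invisible(NULL)
}

#' Pretrain on the full enhancer pool
#'
#' The first PRS stage: splits the dataset 10/12 train, 1/12 validation,
#' 1/12 test (stratified), trains with validation-based epoch selection,
#' evaluates the selected checkpoint on the held-out test split, and
#' optionally writes a checkpoint file.
#'
#' @param dataset a `sequence_set`, conventionally at a 1:10
#'   positive:negative ratio (a different ratio warns and proceeds).
#' @param cfg a [network_config()].
#' @param obj_cfg an [objective_config()].
#' @param out_path optional checkpoint path.
#' @param split a [split_spec()]; defaults to 10/12, 1/12, 1/12 with the
#'   objective seed.
#' @return A list: `run` (the `training_run`), `report` (test-split
#'   `eval_report`), `splits`, `checkpoint` (path or `NULL`).
#' @export
pretrain <- function(dataset, cfg, obj_cfg = objective_config(),
                     out_path = NULL, split = NULL) {
  check_imbalance(dataset)
  if (is.null(split)) split <- split_spec(seed = obj_cfg$seed)
  sp <- make_splits(dataset, split)
  params <- build_network(cfg, seed = obj_cfg$seed)
  run <- train_network(params, sp$train, sp$val, obj_cfg,
                       select_epoch = TRUE, provenance = "ab_initio")
  report <- eval_report(sp$test$label, forward(run$params, sp$test))
  if (!is.null(out_path)) save_checkpoint(run$params, out_path)
  list(run = run, report = report, splits = sp, checkpoint = out_path)
}

resolve_checkpoint <- function(checkpoint) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  stopifnot(inherits(checkpoint, "network_params"))
  checkpoint
}

#' Warm-start retraining on a tissue-specific dataset
#'
#' The second PRS stage: training resumes from the pretrained checkpoint and
#' runs for exactly `epochs` epochs (a fixed budget with no early stopping,
#' so an `epochs`-epoch run is exactly the FANTOM-epN protocol). With
#' `epochs = 0` the checkpoint is returned unchanged. Parameter groups named
#' in `freeze` are held at their checkpoint values.
#'
#' @param checkpoint a `network_params` object or a checkpoint path.
#' @param dataset the tissue-specific `sequence_set`.
#' @param epochs retraining epoch budget (default 20).
#' @param freeze subset of `c("M", "WU", "WM")` to hold fixed.
#' @param obj_cfg an [objective_config()]; its `max_epochs` is overridden by
#'   `epochs`.
#' @param split a [split_spec()] (default 10/12, 1/12, 1/12).
#' @param select_epoch use validation-based epoch selection instead of the
#'   fixed budget (off by default, matching the FANTOM-epN definition).
#' @return A list: `run` (tagged `"warm_start"`), `report` (test-split
#'   `eval_report`), `splits`.
#' @export
retrain <- function(checkpoint, dataset, epochs = 20L,
                    freeze = character(0), obj_cfg = objective_config(),
                    split = NULL, select_epoch = FALSE) {
  params <- resolve_checkpoint(checkpoint)
  cfg <- attr(params, "config")
  if (cfg$input_length != attr(dataset, "fixed_length")) {
    stop("checkpoint input_length ", cfg$input_length,
         " does not match dataset fixed length ",
         attr(dataset, "fixed_length"))
  }
  if (is.null(split)) split <- split_spec(seed = obj_cfg$seed)
  sp <- make_splits(dataset, split)
  if (epochs == 0L) {
    run <- structure(list(history = data.frame(), selected_epoch = 0L,
                          params = params, provenance = "warm_start",
                          obj_cfg = obj_cfg),
                     class = "training_run")
  } else {
    obj_cfg$max_epochs <- as.integer(epochs)
    run <- train_network(params, sp$train, sp$val, obj_cfg,
                         select_epoch = select_epoch, freeze = freeze,
                         provenance = "warm_start")
  }
  report <- eval_report(sp$test$label, forward(run$params, sp$test))
  list(run = run, report = report, splits = sp)
}

#' Fixed-budget ab-initio training on a tissue-specific dataset
#'
#' The None-epN baseline: random initialization, the same fixed epoch budget
#' as [retrain()], no validation-based selection.
#'
#' @param dataset the tissue-specific `sequence_set`.
#' @param cfg a [network_config()].
#' @param epochs epoch budget (the protocol uses 10, 20, 50 or 100).
#' @param obj_cfg an [objective_config()].
#' @param split a [split_spec()].
#' @return As [retrain()], with the run tagged `"ab_initio"`.
#' @export
ab_initio <- function(dataset, cfg, epochs = 20L,
                      obj_cfg = objective_config(), split = NULL) {
  stopifnot(epochs >= 1L)
  if (is.null(split)) split <- split_spec(seed = obj_cfg$seed)
  sp <- make_splits(dataset, split)
  obj_cfg$max_epochs <- as.integer(epochs)
  params <- build_network(cfg, seed = obj_cfg$seed)
  run <- train_network(params, sp$train, sp$val, obj_cfg,
                       select_epoch = FALSE, provenance = "ab_initio")
  report <- eval_report(sp$test$label, forward(run$params, sp$test))
  list(run = run, report = report, splits = sp)
}

#' Two-stage hyperparameter grid search
#'
#' Stage 1 varies filter number and filter length at a fixed small pool size;
#' the filter number of the best-GM cell is then fixed and stage 2 varies
#' filter length and pool size. Each cell trains with validation-based epoch
#' selection on splits fixed across all combinations and reports GM and AUC
#' on the held-out test split. `mode = "full"` evaluates the complete cross
#' of all three axes instead.
#'
#' @param dataset a `sequence_set`.
#' @param cfg_base a [network_config()] supplying the non-searched fields.
#' @param obj_cfg an [objective_config()] (its `max_epochs` is the per-cell
#'   training budget).
#' @param filter_numbers,filter_lengths,pool_sizes grid axes. Filter lengths
#'   must be odd and within `[5, 25]`; pool sizes within
#'   `{3, 5, 8, 11, 14, 17}`.
#' @param mode `"two_stage"` (the reference protocol) or `"full"`.
#' @param stage1_pool pool size used throughout stage 1 (default 3).
#' @return A data frame with columns `stage`, `filter_number`,
#'   `filter_length`, `pool_size`, `GM`, `AUC`.
#' @export
grid_search <- function(dataset, cfg_base = network_config(),
                        obj_cfg = objective_config(),
                        filter_numbers = c(32L, 64L, 128L, 256L),
                        filter_lengths = seq(5L, 25L, by = 2L),
                        pool_sizes = c(3L, 5L, 8L, 11L, 14L, 17L),
                        mode = c("two_stage", "full"), stage1_pool = 3L) {
  mode <- match.arg(mode)
  if (length(filter_numbers) == 0L || length(filter_lengths) == 0L ||
      length(pool_sizes) == 0L) {
    stop("empty hyperparameter grid")
  }
  if (any(filter_lengths %% 2L == 0L | filter_lengths < 5L | filter_lengths > 25L)) {
    stop("filter_lengths must be odd numbers in [5, 25]")
  }
  if (!all(pool_sizes %in% c(3L, 5L, 8L, 11L, 14L, 17L))) {
    stop("pool_sizes must be within {3, 5, 8, 11, 14, 17}")
  }
  sp <- make_splits(dataset, split_spec(seed = obj_cfg$seed))
  eval_cell <- function(fn, fl, ps, stage) {
    cfg <- network_config(filter_number = fn, filter_length = fl,
                          pool_size = ps, gru_units = cfg_base$gru_units,
                          dense_units = cfg_base$dense_units,
                          dropout_rate = cfg_base$dropout_rate,
                          input_length = cfg_base$input_length)
    params <- build_network(cfg, seed = obj_cfg$seed)
    run <- train_network(params, sp$train, sp$val, obj_cfg,
                         select_epoch = TRUE)
    scores <- forward(run$params, sp$test)
    met <- eval_metrics(confusion_counts(sp$test$label, scores))
    data.frame(stage = stage, filter_number = fn, filter_length = fl,
               pool_size = ps, GM = met$GM,
               AUC = auc_score(sp$test$label, scores))
  }
  if (mode == "full") {
    grid <- expand.grid(fn = filter_numbers, fl = filter_lengths,
                        ps = pool_sizes)
    res <- do.call(rbind, Map(eval_cell, grid$fn, grid$fl, grid$ps, "full"))
    rownames(res) <- NULL
    return(res)
  }
  g1 <- expand.grid(fn = filter_numbers, fl = filter_lengths)
  s1 <- do.call(rbind, Map(eval_cell, g1$fn, g1$fl, stage1_pool, "stage1"))
  best_fn <- s1$filter_number[which.max(s1$GM)]
  g2 <- expand.grid(fl = filter_lengths, ps = pool_sizes)
  s2 <- do.call(rbind, Map(eval_cell, best_fn, g2$fl, g2$ps, "stage2"))
  res <- rbind(s1, s2)
  rownames(res) <- NULL
  res
}
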