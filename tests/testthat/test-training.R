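test_that("cross-entropy matches analytic values and term-by-term summation", {
  expect_equal(cross_entropy(1, 0.5), log(2))
  expect_lt(cross_entropy(c(1, 0), c(1 - 1e-9, 1e-9)), 1e-6)
  set.seed(31)
  y <- rbinom(20, 1, 0.4)
  s <- runif(20, 0.01, 0.99)
  byhand <- -sum(ifelse(y == 1, log(s), log(1 - s))) / 20
  expect_equal(cross_entropy(y, s), byhand)
  expect_error(cross_entropy(numeric(0), numeric(0)), "empty")
  expect_error(cross_entropy(c(1, 0), c(0.5, 1)), "strictly inside")
})

test_that("the validation objective composes cross-entropy and L1 norms", {
  cfg <- tiny_net_cfg(30L)
  p <- build_network(cfg, seed = 2L)
  d <- toy_motif_set(n_pos = 6L, n_neg = 6L, length = 30L, seed = 3L)
  b <- encode_batch(d)

  # lambda = 0: exactly the validation cross-entropy
  o0 <- objective_config(lambda1 = 0, lambda2 = 0, lambda3 = 0)
  expect_equal(validation_objective(p, b, o0),
               cross_entropy(b$labels, forward(p, b)))

  # zero parameters on balanced labels: objective is exactly ln 2
  zero <- enhancerPRS:::map_params(function(x) x * 0, unclass(p))
  attributes(zero) <- attributes(p)
  o1 <- objective_config(lambda1 = 1)
  expect_equal(validation_objective(zero, b, o1), log(2))

  # random case equals an independent composition
  oc <- objective_config(lambda1 = 0.3, lambda2 = 0.05, lambda3 = 0.7)
  nrm <- l1_norms(p)
  want <- cross_entropy(b$labels, forward(p, b)) +
    0.3 * nrm[["M"]] + 0.05 * nrm[["WU"]] + 0.7 * nrm[["WM"]]
  expect_equal(validation_objective(p, b, oc), want)
})

test_that("training reduces the loss on separable motif data", {
  for (seed in 1:5) {
    d <- toy_motif_set(seed = seed)
    sp <- enhancerPRS:::stratified_holdout(d, 0.2, seed)
    run <- train_network(build_network(tiny_net_cfg(), seed), sp$train,
                         sp$val, fast_obj_cfg(6L, seed))
    h <- run$history
    expect_lt(h$train_ce[run$selected_epoch], h$train_ce[1L])
  }
})

test_that("epoch selection returns the validation-objective minimizer", {
  d <- toy_motif_set(n_pos = 15L, n_neg = 15L, length = 40L, seed = 12L)
  sp <- enhancerPRS:::stratified_holdout(d, 0.25, 12L)
  cfg <- tiny_net_cfg(40L)
  run <- train_network(build_network(cfg, 12L), sp$train, sp$val,
                       objective_config(max_epochs = 25L, seed = 12L,
                                        batch_size = 8L,
                                        learning_rate = 5e-3))
  h <- run$history
  expect_equal(run$selected_epoch, which.min(h$val_objective))
  # on tiny data with a long budget the objective rises again: the selected
  # epoch is strictly before the last epoch, never simply the final one
  expect_lt(run$selected_epoch, nrow(h))
  # and the returned parameters reproduce that epoch's objective
  b <- encode_batch(sp$val)
  expect_equal(validation_objective(run$params, b, run$obj_cfg),
               min(h$val_objective), tolerance = 1e-10)

  # max_epochs = 1 trivially selects epoch 1
  run1 <- train_network(build_network(cfg, 1L), sp$train, sp$val,
                        objective_config(max_epochs = 1L, seed = 1L))
  expect_equal(run1$selected_epoch, 1L)
})

test_that("training is reproducible from the seed", {
  d <- toy_motif_set(seed = 20L)
  sp <- enhancerPRS:::stratified_holdout(d, 0.2, 20L)
  args <- list(build_network(tiny_net_cfg(), 20L), sp$train, sp$val,
               fast_obj_cfg(4L, 20L))
  r1 <- do.call(train_network, args)
  r2 <- do.call(train_network, args)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$selected_epoch, r2$selected_epoch)
  expect_equal(unclass(r1$params), unclass(r2$params))
})

test_that("zero-epoch retraining returns the checkpoint unchanged", {
  d <- toy_motif_set(n_pos = 20L, n_neg = 40L, length = 60L, seed = 14L)
  ck <- build_network(tiny_net_cfg(), 14L)
  res <- retrain(ck, d, epochs = 0L)
  expect_equal(unclass(res$run$params), unclass(ck))
  expect_equal(res$run$selected_epoch, 0L)
  expect_equal(res$run$provenance, "warm_start")
})

test_that("freezing all penalized groups leaves only the output layer trainable", {
  d <- toy_motif_set(n_pos = 20L, n_neg = 40L, length = 60L, seed = 15L)
  ck <- build_network(tiny_net_cfg(), 15L)
  res <- retrain(ck, d, epochs = 2L, freeze = c("M", "WU", "WM"),
                 obj_cfg = fast_obj_cfg(2L, 15L))
  p <- res$run$params
  expect_identical(p$M, ck$M)
  expect_identical(p$conv_b, ck$conv_b)
  expect_identical(p$gru_fwd, ck$gru_fwd)
  expect_identical(p$gru_bwd, ck$gru_bwd)
  expect_identical(p$dense_W, ck$dense_W)
  expect_identical(p$dense_b, ck$dense_b)
  expect_false(identical(p$out_w, ck$out_w))
})

test_that("retraining validates checkpoint and dataset compatibility", {
  d <- toy_motif_set(n_pos = 10L, n_neg = 20L, length = 60L, seed = 16L)
  ck <- build_network(tiny_net_cfg(40L), 16L)   # wrong input length
  expect_error(retrain(ck, d, epochs = 1L), "input_length")
})

test_that("pretraining writes a loadable checkpoint and selects reproducibly", {
  spec <- synthetic_spec(
    shared_motifs = list(
      motif_model("m1", enhancerPRS:::consensus_pwm("TGACTCAGCA", 0.95), 0.9),
      motif_model("m2", enhancerPRS:::consensus_pwm("CACGTGAC", 0.95), 0.9),
      motif_model("m3", enhancerPRS:::consensus_pwm("GATAAGCGATAA", 0.95), 0.9)),
    length = 150L, n_pretrain_pos = 300L, ratio = 5L)
  cfg <- network_config(filter_number = 12L, filter_length = 9L,
                        pool_size = 8L, gru_units = 8L, input_length = 150L)
  aucs <- numeric(0)
  for (seed in 1:3) {
    d <- generate_pretraining_set(spec, seed = seed)
    ocfg <- objective_config(max_epochs = 25L, seed = seed,
                             learning_rate = 5e-3)
    path <- withr::local_tempfile(fileext = ".rds")
    res <- suppressWarnings(pretrain(d, cfg, ocfg, out_path = path))
    aucs <- c(aucs, res$report$AUC)
    if (seed == 1L) {
      # checkpoint round-trips with its configuration
      ck <- load_checkpoint(path)
      expect_equal(unclass(ck), unclass(res$run$params))
      expect_equal(attr(ck, "config"), cfg)
      # re-running the same seed selects the same epoch
      res2 <- suppressWarnings(pretrain(d, cfg, ocfg))
      expect_equal(res2$run$selected_epoch, res$run$selected_epoch)
    }
  }
  # planted-motif data is separable by construction
  expect_gt(mean(aucs), 0.9)
})

test_that("grid search follows the two-stage protocol and is re-evaluable", {
  d <- toy_motif_set(n_pos = 30L, n_neg = 60L, length = 60L, seed = 17L)
  cfg <- tiny_net_cfg()
  ocfg <- objective_config(max_epochs = 2L, seed = 17L, batch_size = 32L)
  res <- grid_search(d, cfg, ocfg, filter_numbers = c(2L, 4L),
                     filter_lengths = c(5L, 7L), pool_sizes = c(3L, 5L))
  s1 <- res[res$stage == "stage1", ]
  s2 <- res[res$stage == "stage2", ]
  expect_equal(nrow(s1), 4L)               # 2 filter numbers x 2 lengths
  expect_equal(nrow(s2), 4L)               # 2 lengths x 2 pools
  expect_true(all(is.finite(res$GM)) && all(is.finite(res$AUC)))
  expect_true(all(s1$pool_size == 3L))
  expect_length(unique(s2$filter_number), 1L)   # stage 2 never re-varies it
  expect_equal(unique(s2$filter_number),
               s1$filter_number[which.max(s1$GM)])

  # every cell is reproducible: the full-cross mode re-evaluates the same
  # combinations to identical metrics
  full <- grid_search(d, cfg, ocfg, filter_numbers = c(2L, 4L),
                      filter_lengths = c(5L, 7L), pool_sizes = c(3L, 5L),
                      mode = "full")
  for (i in seq_len(nrow(s2))) {
    match_row <- full[full$filter_number == s2$filter_number[i] &
                        full$filter_length == s2$filter_length[i] &
                        full$pool_size == s2$pool_size[i], ]
    expect_equal(match_row$GM, s2$GM[i])
    expect_equal(match_row$AUC, s2$AUC[i])
  }

  expect_error(grid_search(d, cfg, ocfg, filter_numbers = integer(0)),
               "empty")
  expect_error(grid_search(d, cfg, ocfg, filter_lengths = 6L), "odd")
})
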