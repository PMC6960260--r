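#' Pretraining-retraining versus ab-initio benchmark on synthetic data
#'
#' The package's core comparison, run end to end on generated data: for each
#' seed, a model is pretrained on the synthetic housekeeping pool; for each
#' tissue, the pretrained checkpoint is warm-start retrained for a fixed
#' epoch budget and an identically configured model is trained ab initio
#' for the same budget; both are scored on the tissue test split.
#'
#' @param spec a [synthetic_spec()]; the fast 200 bp profile
#'   (`synthetic_spec(length = 200)`) keeps a 5-seed run on one CPU within
#'   minutes.
#' @param cfg a [network_config()] matching `spec$length`; the default is
#'   the desk-scale configuration (16 filters of 11 bp, pool 8, 16 GRU
#'   units per direction).
#' @param seeds integer vector of seeds (default `1:5`).
#' @param retrain_epochs fixed retraining budget (default 20).
#' @param pretrain_epochs pretraining epoch cap with validation-based
#'   selection (default 30).
#' @param obj_cfg base [objective_config()]; its seed is replaced per run.
#' @param tissues tissues to evaluate (default all in the spec).
#' @param verbose print one line per run.
#' @return A list with `results` (data frame: seed, tissue, strategy, GM,
#'   Sens, Spec, AUC, pretrain test AUC) and `summary` (per-strategy mean GM
#'   and Sens).
#' @export
prs_benchmark <- function(spec = synthetic_spec(length = 200L),
                          cfg = network_config(filter_number = 16L,
                                               filter_length = 11L,
                                               pool_size = 8L,
                                               gru_units = 16L,
                                               input_length = spec$length),
                          seeds = 1:5, retrain_epochs = 20L,
                          pretrain_epochs = 30L,
                          obj_cfg = objective_config(),
                          tissues = names(spec$tissue_motifs),
                          verbose = FALSE) {
  stopifnot(cfg$input_length == spec$length)
  rows <- list()
  for (seed in seeds) {
    ocfg <- obj_cfg
    ocfg$seed <- as.integer(seed)
    ocfg$max_epochs <- as.integer(pretrain_epochs)
    pre_set <- generate_pretraining_set(spec, seed = spec$seed + 100L * seed)
    pre <- pretrain(pre_set, cfg, ocfg)
    if (verbose) {
      message(sprintf("seed %d: pretrain test AUC %.3f (epoch %d)", seed,
                      pre$report$AUC, pre$run$selected_epoch))
    }
    for (tissue in tissues) {
      tset <- generate_tissue_set(
        spec, tissue,
        seed = spec$seed + 100L * seed + match(tissue, names(spec$tissue_motifs)))
      warm <- retrain(pre$run$params, tset, epochs = retrain_epochs,
                      obj_cfg = ocfg)
      cold <- ab_initio(tset, cfg, epochs = retrain_epochs, obj_cfg = ocfg)
      for (res in list(list(tag = "warm_start", rep = warm$report),
                       list(tag = "ab_initio", rep = cold$report))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, tissue = tissue, strategy = res$tag,
          GM = res$rep$GM, Sens = res$rep$Sens, Spec = res$rep$Spec,
          AUC = res$rep$AUC, pretrain_auc = pre$report$AUC)
      }
      if (verbose) {
        message(sprintf("  %s: warm GM %.3f / ab-initio GM %.3f", tissue,
                        warm$report$GM, cold$report$GM))
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$strategy),
                                   function(d) {
    data.frame(strategy = d$strategy[[1L]], mean_GM = mean(d$GM),
               mean_Sens = mean(d$Sens), mean_AUC = mean(d$AUC))
  }))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
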