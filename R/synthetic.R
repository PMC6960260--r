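#' Position-weight-matrix motif model
#'
#' A probabilistic sequence motif: one base distribution per position, plus
#' the probability with which the motif is planted into a positive sequence.
#' Stands in for the transcription-factor binding motifs the convolution
#' filters are expected to learn.
#'
#' @param name motif name.
#' @param pwm a `width x 4` matrix of base probabilities (columns A, C, G,
#'   T); every row must sum to 1 and width must be at least 4.
#' @param planting_probability fraction of positive sequences carrying the
#'   motif.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(name, pwm, planting_probability = 0.8) {
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 4L || nrow(pwm) < 4L) stop("pwm must be width x 4 with width >= 4")
  if (any(abs(rowSums(pwm) - 1) > 1e-8) || any(pwm < 0)) {
    stop("each pwm position must be a probability distribution over A,C,G,T")
  }
  if (planting_probability <= 0 || planting_probability > 1) {
    stop("planting_probability must be in (0, 1]")
  }
  colnames(pwm) <- c("A", "C", "G", "T")
  structure(list(name = name, pwm = pwm,
                 planting_probability = planting_probability),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cons <- paste(c("A", "C", "G", "T")[apply(x$pwm, 1L, which.max)],
                collapse = "")
  cat("motif '", x$name, "': width ", nrow(x$pwm), ", consensus ", cons,
      ", planting probability ", x$planting_probability, "\n", sep = "")
  invisible(x)
}

# A sharp PWM around a consensus: the consensus base gets `dominant`, the
# rest share the remainder.
consensus_pwm <- function(consensus, dominant = 0.85) {
  idx <- match(strsplit(consensus, "")[[1L]], c("A", "C", "G", "T"))
  stopifnot(!anyNA(idx))
  pwm <- matrix((1 - dominant) / 3, nrow = length(idx), ncol = 4L)
  pwm[cbind(seq_along(idx), idx)] <- dominant
  pwm
}

default_shared_motifs <- function() {
  list(motif_model("shared_ap1", consensus_pwm("TGACTCAGCA"), 0.8),
       motif_model("shared_ebox", consensus_pwm("CACGTGAC"), 0.8),
       motif_model("shared_gata", consensus_pwm("GATAAGCGATAA"), 0.8))
}

default_tissue_motifs <- function() {
  list(tissueA = motif_model("private_A", consensus_pwm("TTCGAACGGT"), 0.9),
       tissueB = motif_model("private_B", consensus_pwm("AGGTCACAGT"), 0.9),
       tissueC = motif_model("private_C", consensus_pwm("CCGGAAGTGA"), 0.9))
}

#' Synthetic dataset specification
#'
#' Describes the statistical structure the pretraining-retraining strategy
#' assumes: a large class of sequences sharing common ("housekeeping")
#' motifs, and small tissue classes carrying those shared motifs plus one
#' tissue-private motif each, against i.i.d. background DNA of a fixed GC
#' content. Defaults: three shared motifs planted with probability 0.8, one
#' private motif per tissue planted with probability 0.9, GC 0.42
#' (human-like), 600 pretraining and 200 per-tissue positives, a 1:10
#' positive:negative ratio and 1000 bp sequences. `length = 200` gives the
#' fast desk-scale profile.
#'
#' @param shared_motifs list of [motif_model()]s every positive may carry.
#' @param tissue_motifs named list of per-tissue private [motif_model()]s.
#' @param gc background GC fraction in (0, 1).
#' @param length sequence length in bp.
#' @param n_pretrain_pos,n_tissue_pos positive counts for the pretraining
#'   and per-tissue sets.
#' @param ratio negatives per positive (default 10).
#' @param seed base seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shared_motifs = default_shared_motifs(),
                           tissue_motifs = default_tissue_motifs(),
                           gc = 0.42, length = 1000L,
                           n_pretrain_pos = 600L, n_tissue_pos = 200L,
                           ratio = 10L, seed = 1L) {
  stopifnot(gc > 0, gc < 1, length >= 1L, n_pretrain_pos >= 1L,
            n_tissue_pos >= 1L, ratio >= 1L)
  stopifnot(all(vapply(shared_motifs, inherits, logical(1), "motif_model")),
            all(vapply(tissue_motifs, inherits, logical(1), "motif_model")))
  if (is.null(names(tissue_motifs)) || any(!nzchar(names(tissue_motifs)))) {
    stop("tissue_motifs must be a named list")
  }
  structure(list(shared_motifs = shared_motifs,
                 tissue_motifs = tissue_motifs, gc = gc,
                 length = as.integer(length),
                 n_pretrain_pos = as.integer(n_pretrain_pos),
                 n_tissue_pos = as.integer(n_tissue_pos),
                 ratio = as.integer(ratio), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Random background DNA
#'
#' i.i.d. bases with `P(G) + P(C) = gc`, split equally within each pair.
#'
#' @param n number of sequences.
#' @param length sequence length in bp.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed.
#' @param id_prefix identifier prefix.
#' @return A `sequence_set` with label 0 and source `"background"`.
#' @export
generate_background <- function(n, length, gc = 0.42, seed = 1L,
                                id_prefix = "bg") {
  stopifnot(gc > 0, gc < 1, n >= 0L, length >= 1L)
  set.seed(as.integer(seed))
  if (n == 0L) {
    return(sequence_set(character(0), character(0), integer(0)))
  }
  seqs <- random_dna(n, length, gc)
  sequence_set(id = sprintf("%s_%06d", id_prefix, seq_len(n)), seq = seqs,
               label = 0L, source = "background")
}

random_dna <- function(n, length, gc) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bases <- sample(c("A", "C", "G", "T"), n * length, replace = TRUE,
                  prob = prob)
  m <- matrix(bases, nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Plant a motif instance into a sequence
#'
#' One instance is sampled position-wise from the PWM and written at a
#' uniform random start; the start (0-based) is returned as ground truth.
#'
#' @param seq a DNA string at least as long as the motif.
#' @param motif a [motif_model()].
#' @param seed optional seed; by default the current RNG state is used.
#' @return A list with `seq` (the modified string) and `start` (0-based
#'   planted position).
#' @export
plant_motif <- function(seq, motif, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- nrow(motif$pwm)
  L <- nchar(seq)
  stopifnot(w <= L)
  inst <- paste(vapply(seq_len(w), function(i) {
    sample(c("A", "C", "G", "T"), 1L, prob = motif$pwm[i, ])
  }, character(1)), collapse = "")
  start0 <- sample.int(L - w + 1L, 1L) - 1L
  list(seq = paste0(substr(seq, 1L, start0), inst,
                    substr(seq, start0 + w + 1L, L)),
       start = start0)
}

# Plant each motif independently with its planting probability; returns the
# modified sequences and a per-record annotation string "name:start;...".
plant_motif_set <- function(seqs, motifs) {
  ann <- character(length(seqs))
  for (mo in motifs) {
    hit <- stats::runif(length(seqs)) < mo$planting_probability
    for (i in which(hit)) {
      pl <- plant_motif(seqs[i], mo)
      seqs[i] <- pl$seq
      ann[i] <- paste0(ann[i], mo$name, ":", pl$start, ";")
    }
  }
  list(seqs = seqs, motifs = sub(";$", "", ann))
}

#' Generate the synthetic pretraining dataset
#'
#' Positives are background sequences into which each shared motif is
#' planted independently with its planting probability; negatives are pure
#' background at the configured imbalance ratio. Each record's `motifs`
#' column lists the planted motifs and positions (machine-readable ground
#' truth).
#'
#' @param spec a [synthetic_spec()].
#' @param seed seed (defaults to `spec$seed`).
#' @return A `sequence_set` with a `motifs` column.
#' @export
generate_pretraining_set <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))
  npos <- spec$n_pretrain_pos
  nneg <- npos * spec$ratio
  pos_raw <- random_dna(npos, spec$length, spec$gc)
  planted <- plant_motif_set(pos_raw, spec$shared_motifs)
  neg <- random_dna(nneg, spec$length, spec$gc)
  sequence_set(
    id = c(sprintf("pre_pos_%06d", seq_len(npos)),
           sprintf("pre_neg_%06d", seq_len(nneg))),
    seq = c(planted$seqs, neg),
    label = c(rep(1L, npos), rep(0L, nneg)),
    source = c(rep("housekeeping", npos), rep("background", nneg)),
    motifs = c(planted$motifs, rep("", nneg)))
}

#' Generate a synthetic tissue-specific dataset
#'
#' Positives carry the shared motifs (same probabilities as the pretraining
#' set) plus the tissue's private motif at its planting probability;
#' negatives are pure background at the imbalance ratio. Tissues differ only
#' in the private motif.
#'
#' @param spec a [synthetic_spec()].
#' @param tissue a name from `spec$tissue_motifs`.
#' @param seed seed (defaults to `spec$seed` offset by the tissue index).
#' @return A `sequence_set` with a `motifs` column.
#' @export
generate_tissue_set <- function(spec, tissue, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ti <- match(tissue, names(spec$tissue_motifs))
  if (is.na(ti)) {
    stop("unknown tissue '", tissue, "'; available: ",
         paste(names(spec$tissue_motifs), collapse = ", "))
  }
  if (is.null(seed)) seed <- spec$seed + 1000L * ti
  set.seed(as.integer(seed))
  npos <- spec$n_tissue_pos
  nneg <- npos * spec$ratio
  pos_raw <- random_dna(npos, spec$length, spec$gc)
  planted <- plant_motif_set(pos_raw,
                             c(spec$shared_motifs,
                               list(spec$tissue_motifs[[ti]])))
  neg <- random_dna(nneg, spec$length, spec$gc)
  sequence_set(
    id = c(sprintf("%s_pos_%06d", tissue, seq_len(npos)),
           sprintf("%s_neg_%06d", tissue, seq_len(nneg))),
    seq = c(planted$seqs, neg),
    label = c(rep(1L, npos), rep(0L, nneg)),
    source = c(rep(tissue, npos), rep("background", nneg)),
    motifs = c(planted$motifs, rep("", nneg)))
}

#' Generate a synthetic enhancer activity matrix with ground truth
#'
#' Emulates the TPM structure the dataset filters assume: designated
#' "housekeeping" rows have every entry nonzero in `[0.1, 0.75]` (so their
#' minimum nonzero TPM clears the 0.08 pretraining cutoff and no entry
#' reaches the 0.8 tissue cutoff); designated "tissue-active" rows exceed
#' 0.8 in exactly one sample column and are otherwise sparse with small
#' nonzero values below 0.08; all remaining rows are sparse and small.
#' Applying [select_pretraining_enhancers()] and [select_tissue_enhancers()]
#' must therefore recover exactly the designated rows.
#'
#' @param n_regions total rows (default 400).
#' @param n_samples sample columns, at least 2 (default 4).
#' @param frac_housekeeping fraction of rows designated housekeeping
#'   (default 0.2).
#' @param n_tissue_active tissue-active rows designated per sample (default
#'   `ceiling(0.05 * n_regions)`).
#' @param seed integer seed.
#' @return A list: `matrix` (an `enhancer_activity`) and `truth` (data frame
#'   of `region_id`, `class` in `{housekeeping, tissue_active, inactive}`,
#'   `active_sample`).
#' @export
generate_activity_matrix <- function(n_regions = 400L, n_samples = 4L,
                                     frac_housekeeping = 0.2,
                                     n_tissue_active = NULL, seed = 1L) {
  stopifnot(n_regions >= 10L, n_samples >= 2L)
  if (is.null(n_tissue_active)) n_tissue_active <- ceiling(0.05 * n_regions)
  set.seed(as.integer(seed))
  n_hk <- round(frac_housekeeping * n_regions)
  n_ta <- n_tissue_active * n_samples
  stopifnot(n_hk + n_ta < n_regions)
  classes <- sample(c(rep("housekeeping", n_hk), rep("tissue_active", n_ta),
                      rep("inactive", n_regions - n_hk - n_ta)))
  samples <- sprintf("tissue%02d", seq_len(n_samples))
  active_sample <- rep(NA_character_, n_regions)
  ta_rows <- which(classes == "tissue_active")
  active_sample[ta_rows] <- rep(samples, length.out = length(ta_rows))

  sparse_row <- function(ns) {
    v <- ifelse(stats::runif(ns) < 0.5, 0, stats::runif(ns, 0.005, 0.05))
    if (all(v == 0)) v[sample.int(ns, 1L)] <- stats::runif(1L, 0.005, 0.05)
    v
  }
  tpm <- matrix(0, n_regions, n_samples, dimnames = list(NULL, samples))
  for (i in seq_len(n_regions)) {
    if (classes[i] == "housekeeping") {
      tpm[i, ] <- stats::runif(n_samples, 0.1, 0.75)
    } else if (classes[i] == "tissue_active") {
      # a small nonzero entry in a non-active column keeps the row's minimum
      # nonzero TPM below the housekeeping cutoff
      others <- setdiff(samples, active_sample[i])
      tpm[i, others] <- sparse_row(length(others))
      tpm[i, active_sample[i]] <- stats::runif(1L, 1, 5)
    } else {
      tpm[i, ] <- sparse_row(n_samples)
    }
  }
  starts <- 2000L * seq_len(n_regions)
  regions <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(starts + 1L, starts + 400L))
  S4Vectors::mcols(regions)$region_id <-
    sprintf("chrS:%d-%d", starts, starts + 400L)
  m <- enhancer_activity(regions, tpm)
  list(matrix = m,
       truth = data.frame(region_id = region_id(regions), class = classes,
                          active_sample = active_sample,
                          stringsAsFactors = FALSE))
}
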