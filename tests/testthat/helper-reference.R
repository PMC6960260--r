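# Independent reference implementations used as oracles. These deliberately
# use naive loops and share no code with the package internals.

# Plain-R forward pass of the Conv -> ReLU -> MaxPool -> Bi-GRU -> Dense ->
# sigmoid pipeline for a single sequence.
reference_forward <- function(params, cfg, seq) {
  x <- one_hot(seq)
  L <- nrow(x)
  m <- cfg$filter_length
  nf <- cfg$filter_number
  tc <- L - m + 1L
  A <- matrix(0, tc, nf)
  for (pos in seq_len(tc)) {
    for (f in seq_len(nf)) {
      acc <- params$conv_b[f]
      for (j in seq_len(m)) {
        for (ch in 1:4) acc <- acc + x[pos + j - 1L, ch] * params$M[j, ch, f]
      }
      A[pos, f] <- acc
    }
  }
  A <- pmax(A, 0)
  tp <- tc %/% cfg$pool_size
  pooled <- matrix(0, tp, nf)
  for (t in seq_len(tp)) {
    rows <- ((t - 1L) * cfg$pool_size + 1L):(t * cfg$pool_size)
    for (f in seq_len(nf)) pooled[t, f] <- max(A[rows, f])
  }
  gru_scan <- function(w, xs) {
    h <- rep(0, length(w$bz))
    for (t in seq_len(nrow(xs))) {
      xt <- xs[t, ]
      z <- 1 / (1 + exp(-(as.numeric(xt %*% w$Wz) + as.numeric(h %*% w$Uz) + w$bz)))
      r <- 1 / (1 + exp(-(as.numeric(xt %*% w$Wr) + as.numeric(h %*% w$Ur) + w$br)))
      hc <- tanh(as.numeric(xt %*% w$Wh) + as.numeric((r * h) %*% w$Uh) + w$bh)
      h <- (1 - z) * h + z * hc
    }
    h
  }
  hf <- gru_scan(params$gru_fwd, pooled)
  hb <- gru_scan(params$gru_bwd, pooled[rev(seq_len(tp)), , drop = FALSE])
  dense <- pmax(as.numeric(c(hf, hb) %*% params$dense_W) + params$dense_b, 0)
  1 / (1 + exp(-(sum(dense * params$out_w) + params$out_b)))
}

# AUC by exhaustive enumeration of all positive-negative pairs.
reference_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# AUPRC by a naive sweep over the distinct score values.
reference_auprc <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prev_recall <- 0
  area <- 0
  for (th in thr) {
    called <- scores >= th
    tp <- sum(labels == 1 & called)
    prec <- tp / sum(called)
    recall <- tp / npos
    area <- area + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  area
}

# Full-offset ungapped identity (no k-mer prefilter): fraction of matching
# bases at the best shift, over the shorter sequence.
reference_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0L
  for (off in (-(nb - 1L)):(na - 1L)) {
    ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
    n <- min(na - ia, nb - ib) + 1L
    if (n <= 0L) next
    mm <- sum(av[ia:(ia + n - 1L)] == bv[ib:(ib + n - 1L)])
    if (mm > best) best <- mm
  }
  best / min(na, nb)
}

# Greedy longest-first filter using the full-offset identity above.
reference_reduce <- function(seqs, cutoff) {
  ord <- order(-nchar(seqs), seq_along(seqs))
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in kept) {
      if (reference_identity(seqs[i], seqs[j]) >= cutoff) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  sort(kept)
}

# PWM consensus scanner: counts windows within `max_mismatch` of each shared
# consensus, a deliberately simple classifier used to certify that generated
# positives are separable.
consensus_scan_scores <- function(seqs, motifs, max_mismatch = 2L) {
  consensi <- vapply(motifs, function(m) {
    paste(c("A", "C", "G", "T")[apply(m$pwm, 1, which.max)], collapse = "")
  }, "")
  sapply(seqs, function(s) {
    subj <- Biostrings::DNAString(s)
    sum(vapply(consensi, function(cs) {
      Biostrings::countPattern(cs, subj, max.mismatch = max_mismatch)
    }, numeric(1)))
  }, USE.NAMES = FALSE)
}
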