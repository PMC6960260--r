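#' Construct a labeled sequence set
#'
#' The common currency of the pipeline: fixed-length DNA records with a
#' binary enhancer label and optional genomic provenance. Stored as a plain
#' data frame (one row per record) with a `fixed_length` attribute.
#'
#' @param id unique record identifiers.
#' @param seq DNA strings over `{A,C,G,T,N}`; all the same length.
#' @param label integer labels, 1 = enhancer, 0 = non-enhancer.
#' @param chrom,start,end optional source coordinates (0-based half-open).
#' @param source optional free-text provenance (e.g. "housekeeping",
#'   "intergenic").
#' @param ... further per-record columns (e.g. planted motif annotations).
#' @return An object of class `sequence_set` (also a `data.frame`).
#' @export
sequence_set <- function(id, seq, label, chrom = NA_character_,
                         start = NA_integer_, end = NA_integer_,
                         source = NA_character_, ...) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  label <- as.integer(label)
  if (length(label) == 1L) label <- rep_len(label, length(id))
  if (length(chrom) == 1L) chrom <- rep_len(chrom, length(id))
  if (length(start) == 1L) start <- rep_len(start, length(id))
  if (length(end) == 1L) end <- rep_len(end, length(id))
  if (length(source) == 1L) source <- rep_len(source, length(id))
  if (length(id) != length(seq) || length(id) != length(label)) {
    stop("id, seq and label must have equal length")
  }
  if (anyDuplicated(id)) stop("record ids must be unique")
  if (!all(label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  lens <- nchar(seq)
  if (length(seq) > 0L && length(unique(lens)) != 1L) {
    stop("all sequences must have the same length; saw lengths ",
         paste(utils::head(unique(lens), 3L), collapse = ", "))
  }
  if (length(grep("[^ACGTN]", seq)) > 0L) {
    stop("sequences may only contain A, C, G, T, N")
  }
  df <- data.frame(id = id, seq = seq, label = label, chrom = chrom,
                   start = start, end = end, source = source, ...,
                   stringsAsFactors = FALSE)
  attr(df, "fixed_length") <- if (length(seq) > 0L) lens[[1L]] else NA_integer_
  class(df) <- c("sequence_set", "data.frame")
  df
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence set: ", nrow(x), " records of length ",
      attr(x, "fixed_length"), " bp (", sum(x$label == 1L), " positive / ",
      sum(x$label == 0L), " negative)\n", sep = "")
  invisible(x)
}

#' Combine and subset sequence sets
#'
#' @param ... `sequence_set` objects of the same fixed length.
#' @return A `sequence_set`.
#' @export
bind_sequence_sets <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "sequence_set")))
  lens <- unique(vapply(sets, function(s) attr(s, "fixed_length"), integer(1)))
  if (length(lens) > 1L) stop("sequence sets have different fixed lengths")
  common <- Reduce(intersect, lapply(sets, names))
  df <- do.call(rbind, lapply(sets, function(s) as.data.frame(s)[common]))
  if (anyDuplicated(df$id)) stop("combined sets share record ids")
  attr(df, "fixed_length") <- lens
  class(df) <- c("sequence_set", "data.frame")
  rownames(df) <- NULL
  df
}

subset_sequence_set <- function(x, idx) {
  fl <- attr(x, "fixed_length")
  out <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fixed_length") <- fl
  class(out) <- c("sequence_set", "data.frame")
  out
}

#' Write a labeled sequence set as FASTA plus a TSV manifest
#'
#' The FASTA description encodes the label (`label=1`); the manifest carries
#' id, coordinates, label and source so the set round-trips exactly.
#'
#' @param x a `sequence_set`.
#' @param fasta,manifest output paths (either may be `NULL` to skip).
#' @export
write_sequence_set <- function(x, fasta, manifest = NULL) {
  stopifnot(inherits(x, "sequence_set"))
  if (!is.null(fasta)) {
    dna <- Biostrings::DNAStringSet(x$seq)
    names(dna) <- paste0(x$id, " label=", x$label)
    Biostrings::writeXStringSet(dna, fasta)
  }
  if (!is.null(manifest)) {
    utils::write.table(
      as.data.frame(x)[c("id", "chrom", "start", "end", "label", "source")],
      manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' Read a labeled sequence set from FASTA (plus optional manifest)
#'
#' Labels are taken from `label=<0|1>` in the FASTA descriptions; the
#' manifest, when given, supplies coordinates and provenance.
#'
#' @param fasta FASTA path.
#' @param manifest optional TSV manifest path written by
#'   [write_sequence_set()].
#' @return A `sequence_set`.
#' @export
read_sequence_set <- function(fasta, manifest = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta)
  desc <- names(dna)
  id <- sub("\\s.*$", "", desc)
  lab <- regmatches(desc, regexpr("label=[01]", desc))
  if (length(lab) != length(desc)) {
    stop("every FASTA description must carry a label=<0|1> tag")
  }
  label <- as.integer(sub("label=", "", lab))
  x <- sequence_set(id, as.character(dna), label)
  if (!is.null(manifest)) {
    man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    m <- match(x$id, man$id)
    if (anyNA(m)) stop("manifest is missing ids present in the FASTA")
    x$chrom <- man$chrom[m]
    x$start <- man$start[m]
    x$end <- man$end[m]
    x$source <- man$source[m]
  }
  x
}

#' Extract fixed-length windows centred on enhancer regions
#'
#' Regions shorter than `min_len` are rejected; accepted regions yield a
#' window of exactly `target` bp centred on the region midpoint
#' (`floor((start + end) / 2)` in 0-based coordinates), which preserves the
#' bidirectional eRNA transcription midpoint. Windows that would overrun a
#' chromosome end are rejected rather than clipped.
#'
#' @param regions `GRanges` of enhancer loci.
#' @param genome a named [Biostrings::DNAStringSet] (one entry per
#'   chromosome).
#' @param target window size in bp (default 1000).
#' @param min_len minimum region length in bp (default 100).
#' @return A data frame with one row per input region: `region_id`, `status`
#'   (`"ok"`, `"below_min_length"` or `"out_of_bounds"`), window coordinates
#'   (`chrom`, `start`, `end`, 0-based half-open, `NA` when rejected) and the
#'   extracted `seq`.
#' @export
fix_length <- function(regions, genome, target = 1000L, min_len = 100L) {
  stopifnot(methods::is(regions, "GRanges"),
            methods::is(genome, "DNAStringSet"))
  target <- as.integer(target)
  min_len <- as.integer(min_len)
  stopifnot(target >= 1L, min_len >= 1L)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  missing_chr <- setdiff(unique(chrom), names(genome))
  if (length(missing_chr) > 0L) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  s0 <- GenomicRanges::start(regions) - 1L   # back to 0-based half-open
  e0 <- GenomicRanges::end(regions)
  len <- e0 - s0
  mid <- (s0 + e0) %/% 2L
  w0 <- mid - target %/% 2L
  w1 <- w0 + target
  chrlen <- Biostrings::width(genome)[match(chrom, names(genome))]

  status <- rep("ok", length(regions))
  status[len < min_len] <- "below_min_length"
  status[status == "ok" & (w0 < 0L | w1 > chrlen)] <- "out_of_bounds"
  seqs <- rep(NA_character_, length(regions))
  ok <- which(status == "ok")
  if (length(ok) > 0L) {
    seqs[ok] <- vapply(ok, function(i) {
      as.character(Biostrings::subseq(genome[[chrom[i]]],
                                      start = w0[i] + 1L, width = target))
    }, character(1))
  }
  data.frame(region_id = region_id(regions), status = status,
             chrom = chrom,
             start = ifelse(status == "ok", w0, NA_integer_),
             end = ifelse(status == "ok", w1, NA_integer_),
             seq = seqs, stringsAsFactors = FALSE)
}

# All candidate alignment offsets (shifts of b relative to a) on which the
# two sequences share at least one exact k-mer. Near-identical pairs always
# share seeds on the true diagonal, so restricting the ungapped scan to these
# offsets is the same short-word pruning idea CD-HIT uses.
shared_kmer_offsets <- function(a, b, k = 8L) {
  na <- length(a); nb <- length(b)
  if (na < k || nb < k) return(integer(0))
  ka <- substring(paste(a, collapse = ""), seq_len(na - k + 1L),
                  seq_len(na - k + 1L) + k - 1L)
  kb <- substring(paste(b, collapse = ""), seq_len(nb - k + 1L),
                  seq_len(nb - k + 1L) + k - 1L)
  common <- intersect(ka, kb)
  if (length(common) == 0L) return(integer(0))
  offs <- unlist(lapply(common, function(w) {
    outer(which(ka == w), which(kb == w), `-`)
  }), use.names = FALSE)
  unique(as.integer(offs))
}

# Ungapped identity: matches at the best shared-seed offset divided by the
# shorter sequence length.
ungapped_identity <- function(a, b, offsets) {
  if (length(offsets) == 0L) return(0)
  na <- length(a); nb <- length(b)
  best <- 0L
  for (off in offsets) {
    ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
    n <- min(na - ia, nb - ib) + 1L
    if (n <= 0L) next
    matches <- sum(a[ia:(ia + n - 1L)] == b[ib:(ib + n - 1L)])
    if (matches > best) best <- matches
  }
  best / min(na, nb)
}

#' Greedy redundancy reduction of a sequence collection
#'
#' Greedy incremental clustering in the CD-HIT style: sequences are visited
#' longest-first (ties broken by input order) and a sequence is discarded
#' when its identity to any already-retained representative reaches
#' `identity_cutoff`. Identity is the fraction of matching bases in the best
#' ungapped offset alignment, measured over the shorter sequence; only
#' offsets on which the pair shares an exact `word_size`-mer are scanned
#' (pairs sharing no such word are taken to be below the cutoff).
#'
#' @param seqs character vector of DNA strings.
#' @param identity_cutoff identity threshold in `(0, 1]` (default 0.8).
#' @param word_size seed word length for the offset prefilter (default 8).
#' @param method `"builtin"` for the internal clustering, `"cdhit"` to shell
#'   out to a `cd-hit-est` executable if one is on the `PATH`.
#' @return Integer indices (ascending, relative to the input order) of the
#'   retained sequences.
#' @export
reduce_redundancy <- function(seqs, identity_cutoff = 0.8, word_size = 8L,
                              method = c("builtin", "cdhit")) {
  method <- match.arg(method)
  if (!is.numeric(identity_cutoff) || length(identity_cutoff) != 1L ||
      identity_cutoff <= 0 || identity_cutoff > 1) {
    stop("identity_cutoff must be in (0, 1]")
  }
  if (length(seqs) == 0L) return(integer(0))
  if (method == "cdhit") {
    return(reduce_redundancy_cdhit(seqs, identity_cutoff))
  }
  ord <- order(-nchar(seqs), seq_along(seqs))
  chars <- lapply(strsplit(toupper(seqs), ""), identity)
  retained <- integer(0)
  for (i in ord) {
    keep <- TRUE
    for (j in retained) {
      offs <- shared_kmer_offsets(chars[[i]], chars[[j]], k = word_size)
      if (length(offs) == 0L) next
      if (ungapped_identity(chars[[i]], chars[[j]], offs) >= identity_cutoff) {
        keep <- FALSE
        break
      }
    }
    if (keep) retained <- c(retained, i)
  }
  sort(retained)
}

reduce_redundancy_cdhit <- function(seqs, identity_cutoff) {
  bin <- Sys.which("cd-hit-est")
  if (!nzchar(bin)) {
    stop("method = 'cdhit' requires a cd-hit-est executable on the PATH")
  }
  td <- tempfile("cdhit")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fin <- file.path(td, "in.fa"); fout <- file.path(td, "out.fa")
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- sprintf("s%08d", seq_along(seqs))
  Biostrings::writeXStringSet(dna, fin)
  status <- system2(bin, c("-i", fin, "-o", fout, "-c", identity_cutoff,
                           "-n", "5", "-d", "0"), stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("cd-hit-est exited with status ", status)
  kept <- names(Biostrings::readDNAStringSet(fout))
  sort(as.integer(sub("^s", "", sub("\\s.*$", "", kept))))
}

#' Sample intergenic negative windows
#'
#' Draws `n` windows of `length` bp uniformly over all genome positions not
#' covered by the exclusion intervals (exons, introns, known enhancers,
#' supplied pre-flattened as BED-style ranges). Windows containing any
#' ambiguous base (N) are rejected and redrawn. Every returned window is
#' disjoint from every exclusion interval by construction.
#'
#' @param genome a named `DNAStringSet`.
#' @param exclusions `GRanges` of intervals the windows must avoid (may be
#'   empty).
#' @param n number of windows to draw.
#' @param length window size in bp (default 1000).
#' @param seed integer seed; draws are reproducible.
#' @param id_prefix prefix for record identifiers.
#' @return A `sequence_set` with label 0 and source coordinates.
#' @export
sample_negatives <- function(genome, exclusions, n, length = 1000L,
                             seed = 1L, id_prefix = "neg") {
  stopifnot(methods::is(genome, "DNAStringSet"), n >= 1L, length >= 1L)
  length <- as.integer(length)
  chrom_gr <- GenomicRanges::GRanges(
    names(genome), IRanges::IRanges(1L, Biostrings::width(genome)))
  allowed <- GenomicRanges::setdiff(chrom_gr, exclusions, ignore.strand = TRUE)
  allowed <- allowed[GenomicRanges::width(allowed) >= length]
  if (methods::is(exclusions, "GRanges") && length(exclusions) > 0L) {
    # setdiff can only shrink; re-check defensively in case of strand quirks
    hits <- GenomicRanges::findOverlaps(allowed, exclusions, ignore.strand = TRUE)
    allowed <- allowed[setdiff(seq_along(allowed), S4Vectors::queryHits(hits))]
  }
  if (base::length(allowed) == 0L) {
    stop("no allowed interval of at least ", length, " bp remains after ",
         "applying the exclusions; drew 0 of ", n, " windows")
  }
  n_starts <- GenomicRanges::width(allowed) - length + 1L
  a_chrom <- as.character(GenomicRanges::seqnames(allowed))
  a_start <- GenomicRanges::start(allowed)

  set.seed(as.integer(seed))
  out_chrom <- character(0); out_start <- integer(0); out_seq <- character(0)
  attempts <- 0L
  max_attempts <- max(1000L, 200L * n)
  while (base::length(out_seq) < n && attempts < max_attempts) {
    todo <- n - base::length(out_seq)
    iv <- sample.int(base::length(allowed), todo, replace = TRUE,
                     prob = n_starts)
    off <- floor(stats::runif(todo) * n_starts[iv])  # 0 .. n_starts-1
    ws <- a_start[iv] + as.integer(off)              # 1-based window start
    seqs <- vapply(seq_len(todo), function(i) {
      as.character(Biostrings::subseq(genome[[a_chrom[iv[i]]]],
                                      start = ws[i], width = length))
    }, character(1))
    ok <- !grepl("N", seqs, fixed = TRUE)
    out_chrom <- c(out_chrom, a_chrom[iv][ok])
    out_start <- c(out_start, ws[ok])
    out_seq <- c(out_seq, seqs[ok])
    attempts <- attempts + todo
  }
  if (base::length(out_seq) < n) {
    stop("allowed space exhausted by N-containing windows: drew ",
         base::length(out_seq), " of ", n, " requested windows")
  }
  start0 <- out_start - 1L
  sequence_set(id = sprintf("%s_%06d", id_prefix, seq_len(n)),
               seq = out_seq, label = 0L, chrom = out_chrom,
               start = start0, end = start0 + length, source = "intergenic")
}

#' Specify a train/validation/test split (or k folds)
#'
#' @param train,val,test positive fractions summing to 1 (default 10/12,
#'   1/12, 1/12).
#' @param k optional fold count for cross-validation splits.
#' @param seed integer seed controlling the shuffle.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train = 10 / 12, val = 1 / 12, test = 1 / 12,
                       k = NULL, seed = 1L) {
  fr <- c(train = train, val = val, test = test)
  if (any(fr <= 0)) stop("all split fractions must be positive")
  if (abs(sum(fr) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (!is.null(k)) stopifnot(k >= 2L)
  structure(list(train = train, val = val, test = test, k = k,
                 seed = as.integer(seed)), class = "split_spec")
}

# Largest-remainder apportionment of n into parts proportional to fr.
apportion <- function(n, fr) {
  raw <- n * fr
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Stratified train/validation/test split or k folds
#'
#' Partitions a labeled sequence set stratified by label: each class is
#' shuffled and apportioned by largest remainder, so every split's class
#' ratio matches the global ratio to within one record per class. With
#' `spec$k` set, returns `k` disjoint, exhaustive stratified folds instead.
#'
#' @param data a `sequence_set` containing both classes.
#' @param spec a [split_spec()].
#' @return A list `(train, val, test)` of `sequence_set`s, or, when `spec$k`
#'   is set, a list with element `folds` (list of `sequence_set`s) and
#'   `fold_ids` (integer fold assignment per record).
#' @export
make_splits <- function(data, spec = split_spec()) {
  stopifnot(inherits(data, "sequence_set"), inherits(spec, "split_spec"))
  if (length(unique(data$label)) < 2L) {
    stop("data must contain at least one record of each label")
  }
  set.seed(spec$seed)
  idx_by_class <- split(seq_len(nrow(data)), data$label)
  idx_by_class <- lapply(idx_by_class, sample)

  if (!is.null(spec$k)) {
    k <- spec$k
    fold_ids <- integer(nrow(data))
    for (cls in idx_by_class) {
      if (length(cls) < k) stop("a class has fewer records than folds")
      fold_ids[cls] <- rep_len(seq_len(k), length(cls))
    }
    folds <- lapply(seq_len(k), function(f) {
      subset_sequence_set(data, which(fold_ids == f))
    })
    return(list(folds = folds, fold_ids = fold_ids))
  }

  fr <- c(spec$train, spec$val, spec$test)
  take <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cls in idx_by_class) {
    counts <- apportion(length(cls), fr)
    cuts <- cumsum(counts)
    take$train <- c(take$train, cls[seq_len(counts[1L])])
    if (counts[2L] > 0L) take$val <- c(take$val, cls[(cuts[1L] + 1L):cuts[2L]])
    if (counts[3L] > 0L) take$test <- c(take$test, cls[(cuts[2L] + 1L):cuts[3L]])
  }
  if (any(lengths(take) == 0L)) {
    stop("split fractions yield an empty train, val or test partition for ",
         nrow(data), " records")
  }
  lapply(take, function(i) subset_sequence_set(data, sort(i)))
}

# Stratified two-way holdout: `fraction` of each class (at least one record)
# goes to the validation side.
stratified_holdout <- function(data, fraction, seed = 1L) {
  stopifnot(inherits(data, "sequence_set"), fraction > 0, fraction < 1)
  set.seed(as.integer(seed))
  val_idx <- integer(0)
  for (cls in split(seq_len(nrow(data)), data$label)) {
    nv <- max(1L, round(length(cls) * fraction))
    val_idx <- c(val_idx, sample(cls, nv))
  }
  list(train = subset_sequence_set(data, setdiff(seq_len(nrow(data)), val_idx)),
       val = subset_sequence_set(data, sort(val_idx)))
}

#' Read BED intervals as GRanges
#'
#' Minimal 3+ column BED reader (0-based half-open converted to 1-based
#' closed ranges).
#'
#' @param path BED file path.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(bed) < 3L) stop("BED file must have at least 3 columns")
  GenomicRanges::GRanges(bed[[1L]],
                         IRanges::IRanges(as.integer(bed[[2L]]) + 1L,
                                          as.integer(bed[[3L]])))
}
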