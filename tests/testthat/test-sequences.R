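test_that("length fixing rejects short regions and centres accepted windows", {
  genome <- toy_genome()
  regions <- parse_region_ids(c(
    "chrA:5000-5099",    # 99 bp, below minimum
    "chrA:4000-5000",    # exactly 1000 bp: returns its own sequence
    "chrA:6000-6200",    # 200 bp centred window
    "chrA:100-400",      # window would underrun the chromosome start
    "chrB:2800-2950"))   # window would overrun chrB (3000 bp)
  res <- fix_length(regions, genome, target = 1000L, min_len = 100L)
  expect_equal(res$status, c("below_min_length", "ok", "ok",
                             "out_of_bounds", "out_of_bounds"))
  expect_true(all(nchar(res$seq[res$status == "ok"]) == 1000L))

  # identity case: a region already at target length keeps its coordinates
  expect_equal(res$start[2L], 4000L)
  expect_equal(res$end[2L], 5000L)
  expect_equal(res$seq[2L],
               as.character(Biostrings::subseq(genome[["chrA"]], 4001L, 5000L)))

  # centred case: midpoint 6100, window [5600, 6600) against the raw string
  expect_equal(res$start[3L], 5600L)
  expect_equal(res$seq[3L],
               substr(as.character(genome[["chrA"]]), 5601L, 6600L))

  expect_error(fix_length(parse_region_ids("chrZ:0-1000"), genome),
               "chrZ")
})

test_that("redundancy reduction collapses duplicates and keeps distinct sequences", {
  set.seed(3)
  a <- random_dna_string(100)
  b <- random_dna_string(100)
  expect_equal(reduce_redundancy(c(a, a)), 1L)
  expect_equal(reduce_redundancy(c(a, b)), c(1L, 2L))
  expect_error(reduce_redundancy(c(a, b), identity_cutoff = 0), "\\(0, 1\\]")
  expect_error(reduce_redundancy(c(a, b), identity_cutoff = 1.2), "\\(0, 1\\]")

  # a shifted copy sharing 90% of its bases is redundant at cutoff 0.8
  shifted <- paste0(substr(b, 11, 100), substr(random_dna_string(10), 1, 10))
  expect_equal(reduce_redundancy(c(b, shifted)), 1L)
})

test_that("redundancy reduction agrees with the all-pairs brute-force filter", {
  set.seed(11)
  base <- vapply(1:20, function(i) random_dna_string(60), "")
  dups <- base[sample(20, 5)]
  seqs <- sample(c(base, dups))   # shuffle duplicates through the input
  got <- reduce_redundancy(seqs, 0.8)
  want <- reference_reduce(seqs, 0.8)
  expect_equal(got, want)

  # idempotence: re-running on its own output changes nothing
  again <- reduce_redundancy(seqs[got], 0.8)
  expect_equal(again, seq_along(got))
})

test_that("negative sampling respects exclusions, bounds and the seed", {
  genome <- toy_genome(c(chr1 = 10000L))
  none <- GenomicRanges::GRanges()
  s <- sample_negatives(genome, none, n = 3L, length = 1000L, seed = 5L)
  expect_equal(nrow(s), 3L)
  expect_true(all(s$start >= 0L & s$end <= 10000L))
  expect_true(all(s$label == 0L))
  expect_true(all(s$seq == vapply(seq_len(3), function(i) {
    substr(as.character(genome[["chr1"]]), s$start[i] + 1L, s$end[i])
  }, "")))

  # fully excluded genome
  full <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 10000L))
  expect_error(sample_negatives(genome, full, n = 1L, length = 1000L),
               "no allowed interval")

  # windows avoid a central exclusion, by independent interval arithmetic
  excl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001L, 8000L))
  s2 <- sample_negatives(genome, excl, n = 1000L, length = 1000L, seed = 7L)
  left <- s2$start >= 0L & s2$end <= 2000L
  right <- s2$start >= 8000L & s2$end <= 10000L
  expect_true(all(left | right))
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(s2$chrom, IRanges::IRanges(s2$start + 1L, s2$end)),
    excl)
  expect_length(ov, 0L)

  # reproducibility
  s3 <- sample_negatives(genome, excl, n = 1000L, length = 1000L, seed = 7L)
  expect_identical(s2$seq, s3$seq)
})

test_that("windows containing ambiguous bases are rejected", {
  raw <- strsplit(random_dna_string(3000), "")[[1]]
  raw[1500:1600] <- "N"
  genome <- Biostrings::DNAStringSet(paste(raw, collapse = ""))
  names(genome) <- "chrN"
  s <- sample_negatives(genome, GenomicRanges::GRanges(), n = 50L,
                        length = 500L, seed = 2L)
  expect_false(any(grepl("N", s$seq, fixed = TRUE)))
})

test_that("stratified splits have exact sizes and preserve class ratios", {
  d <- toy_motif_set(n_pos = 12L, n_neg = 108L, length = 30L, seed = 4L)
  sp <- make_splits(d, split_spec(seed = 9L))
  expect_equal(nrow(sp$train), 100L)
  expect_equal(nrow(sp$val), 10L)
  expect_equal(nrow(sp$test), 10L)
  expect_equal(sum(sp$train$label), 10L)
  expect_equal(sum(sp$val$label), 1L)
  expect_equal(sum(sp$test$label), 1L)

  # disjoint and exhaustive
  ids <- c(sp$train$id, sp$val$id, sp$test$id)
  expect_setequal(ids, d$id)
  expect_equal(anyDuplicated(ids), 0L)

  # determinism
  sp2 <- make_splits(d, split_spec(seed = 9L))
  expect_identical(sp$train$id, sp2$train$id)
  expect_identical(sp$test$id, sp2$test$id)

  expect_error(make_splits(subset(d, d$label == 1L), split_spec()),
               "each label")
})

test_that("k-fold splits are disjoint, exhaustive and ratio-balanced", {
  d <- toy_motif_set(n_pos = 10L, n_neg = 40L, length = 30L, seed = 5L)
  sp <- make_splits(d, split_spec(k = 5L, seed = 1L))
  expect_length(sp$folds, 5L)
  expect_equal(sort(unlist(lapply(sp$folds, `[[`, "id"))), sort(d$id))
  sizes <- vapply(sp$folds, nrow, integer(1))
  expect_equal(sum(sizes), 50L)
  # global ratio 1:4 preserved within one record per class
  pos_per_fold <- vapply(sp$folds, function(f) sum(f$label), integer(1))
  expect_true(all(abs(pos_per_fold - 2L) <= 1L))
  neg_per_fold <- sizes - pos_per_fold
  expect_true(all(abs(neg_per_fold - 8L) <= 1L))
})

test_that("sequence sets survive a FASTA + manifest round-trip", {
  d <- toy_motif_set(n_pos = 5L, n_neg = 5L, length = 40L, seed = 6L)
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sequence_set(d, fa, tsv)
  back <- read_sequence_set(fa, tsv)
  expect_equal(back$id, d$id)
  expect_equal(back$seq, d$seq)
  expect_equal(back$label, d$label)
})
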