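#' Parse BED-style region identifiers
#'
#' Region identifiers of the form `"chrom:start-end"` use 0-based, half-open
#' coordinates (BED convention). They are converted to 1-based closed
#' [GenomicRanges::GRanges] internally; the original identifier is kept in the
#' `region_id` metadata column so files round-trip byte-identically.
#'
#' @param ids character vector of `"chrom:start-end"` strings.
#' @return A [GenomicRanges::GRanges] with a `region_id` metadata column.
#' @export
parse_region_ids <- function(ids) {
  stopifnot(is.character(ids))
  m <- regexec("^(.+):([0-9]+)-([0-9]+)$", ids)
  parts <- regmatches(ids, m)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L) {
    stop("malformed region identifier(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  chrom <- vapply(parts, `[[`, character(1), 2L)
  start0 <- as.numeric(vapply(parts, `[[`, character(1), 3L))
  end0 <- as.numeric(vapply(parts, `[[`, character(1), 4L))
  bad <- which(start0 >= end0)
  if (length(bad) > 0L) {
    stop("invalid region(s), start must be < end: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  S4Vectors::mcols(gr)$region_id <- ids
  gr
}

#' Format regions back to BED-style identifiers
#'
#' @param gr a `GRanges`.
#' @return character vector of `"chrom:start-end"` (0-based half-open).
#' @export
region_id <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$region_id)) return(as.character(mc$region_id))
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

#' Construct an enhancer activity matrix
#'
#' A lightweight container for a regions-by-samples table of eRNA expression
#' (TPM, tags per million). Rows are genomic enhancer regions, columns are
#' tissues or cell lines.
#'
#' @param regions `GRanges` of enhancer loci, one per row of `tpm`.
#' @param tpm numeric matrix of non-negative TPM values, one column per
#'   sample; column names are the sample names.
#' @return An object of class `enhancer_activity`.
#' @export
enhancer_activity <- function(regions, tpm) {
  tpm <- as.matrix(tpm)
  if (length(regions) != nrow(tpm)) {
    stop("number of regions (", length(regions), ") does not match number of ",
         "matrix rows (", nrow(tpm), ")")
  }
  if (is.null(colnames(tpm))) {
    stop("tpm matrix must have sample names as column names")
  }
  if (anyNA(tpm) || any(tpm < 0)) stop("TPM values must be non-negative")
  ids <- region_id(regions)
  if (anyDuplicated(ids)) {
    stop("duplicate region id(s): ", paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))], collapse = ", "))
  }
  rownames(tpm) <- ids
  structure(list(regions = regions, samples = colnames(tpm), tpm = tpm),
            class = "enhancer_activity")
}

#' @export
print.enhancer_activity <- function(x, ...) {
  cat("enhancer activity matrix: ", nrow(x$tpm), " regions x ",
      ncol(x$tpm), " samples\n", sep = "")
  cat("TPM range: [", format(min(x$tpm)), ", ", format(max(x$tpm)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.enhancer_activity <- function(x) dim(x$tpm)

#' Read an enhancer activity matrix from tab-separated text
#'
#' Expected dialect: a header row whose cells after the first are sample
#' names, then one row per enhancer whose first field is a BED-style region
#' identifier `"chrom:start-end"` and whose remaining fields are numeric TPM
#' values. Malformed rows are reported with their line numbers.
#'
#' @param path path to the TSV file.
#' @param sample_names optional character vector renaming the columns (for
#'   matrices whose header carries library identifiers rather than tissue
#'   names); must match the column count.
#' @return An `enhancer_activity` object.
#' @export
parse_activity_matrix <- function(path, sample_names = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no header: file '", path, "' is empty")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop("no header: expected sample name columns in '", path, "'")
  samples <- header[-1L]
  if (!is.null(sample_names)) {
    if (length(sample_names) != length(samples)) {
      stop("sample_names has length ", length(sample_names),
           " but the file has ", length(samples), " sample columns")
    }
    samples <- sample_names
  }
  if (length(lines) == 1L) stop("file '", path, "' has a header but no data rows")

  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(body)
  bad <- which(nf != length(header))
  if (length(bad) > 0L) {
    stop("malformed row(s) at line ", paste(utils::head(bad + 1L, 5L), collapse = ", "),
         ": expected ", length(header), " tab-separated fields")
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate region id(s): ", paste(utils::head(dup, 3L), collapse = ", "))
  }
  raw <- t(vapply(body, function(f) f[-1L], character(length(samples))))
  if (length(samples) == 1L) raw <- matrix(raw, ncol = 1L)
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric TPM value '", raw[idx[1L], idx[2L]], "' at line ",
         idx[1L] + 1L, " (region ", ids[idx[1L]], "), sample '",
         samples[idx[2L]], "'")
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop("negative TPM value at line ", idx[1L] + 1L, ", sample '",
         samples[idx[2L]], "'")
  }
  colnames(vals) <- samples
  enhancer_activity(parse_region_ids(ids), vals)
}

#' Write an enhancer activity matrix as tab-separated text
#'
#' Inverse of [parse_activity_matrix()]; the first column holds the BED-style
#' region identifier.
#'
#' @param m an `enhancer_activity` object.
#' @param path output path.
#' @export
write_activity_matrix <- function(m, path) {
  stopifnot(inherits(m, "enhancer_activity"))
  header <- paste(c("region", m$samples), collapse = "\t")
  rows <- paste(rownames(m$tpm),
                apply(m$tpm, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = "\t")),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Select broadly active enhancers for the pretraining pool
#'
#' Keeps regions whose minimum *nonzero* TPM across all samples is at least
#' `tpm_min_cutoff` (default 0.08). A region that is expressed at all in every
#' tissue where it is detected is taken as broadly ("housekeeping") active and
#' contributes to the large pretraining positive set. All-zero rows carry no
#' nonzero value and are always excluded.
#'
#' @param m an `enhancer_activity` object.
#' @param tpm_min_cutoff non-negative TPM threshold on the per-region minimum
#'   nonzero value.
#' @return `GRanges` of the selected regions.
#' @export
select_pretraining_enhancers <- function(m, tpm_min_cutoff = 0.08) {
  stopifnot(inherits(m, "enhancer_activity"))
  if (!is.numeric(tpm_min_cutoff) || length(tpm_min_cutoff) != 1L ||
      tpm_min_cutoff < 0) {
    stop("tpm_min_cutoff must be a single non-negative number")
  }
  if (nrow(m$tpm) == 0L) stop("activity matrix is empty")
  tpm <- m$tpm
  tpm[tpm == 0] <- NA_real_
  min_nonzero <- suppressWarnings(apply(tpm, 1L, min, na.rm = TRUE))
  keep <- is.finite(min_nonzero) & min_nonzero >= tpm_min_cutoff
  m$regions[keep]
}

#' Select enhancers active in one tissue or cell line
#'
#' Keeps regions whose TPM in the named sample is strictly greater than
#' `tpm_cutoff` (default 0.8, the upper-quartile activity level used to call
#' a region active in a tissue).
#'
#' @param m an `enhancer_activity` object.
#' @param sample a sample name present in `m$samples`.
#' @param tpm_cutoff strict lower TPM bound.
#' @return `GRanges` of the selected regions.
#' @export
select_tissue_enhancers <- function(m, sample, tpm_cutoff = 0.8) {
  stopifnot(inherits(m, "enhancer_activity"))
  if (!is.character(sample) || length(sample) != 1L || !(sample %in% m$samples)) {
    stop("unknown sample '", sample, "'; available samples: ",
         paste(m$samples, collapse = ", "))
  }
  if (!is.numeric(tpm_cutoff) || length(tpm_cutoff) != 1L || tpm_cutoff < 0) {
    stop("tpm_cutoff must be a single non-negative number")
  }
  keep <- m$tpm[, sample] > tpm_cutoff
  m$regions[keep]
}
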