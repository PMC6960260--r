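#' One-hot encode a DNA sequence
#'
#' Channel order is (A, C, G, T); an ambiguous base N encodes as an all-zero
#' row, keeping the representation binary and pooling behaviour monotone.
#'
#' @param seq a DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @return An `L x 4` 0/1 matrix with column names `A,C,G,T`.
#' @export
one_hot <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1L]]
  code <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) {
    pos <- which(is.na(code))[[1L]]
    stop("invalid base '", chars[pos], "' at position ", pos)
  }
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  keep <- code <= 4L
  m[cbind(which(keep), code[keep])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot()]: all-zero rows decode to N.
#'
#' @param m an `L x 4` one-hot matrix.
#' @return A DNA string.
#' @export
decode_one_hot <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  bases <- c("A", "C", "G", "T")
  out <- rep("N", nrow(m))
  hit <- which(m == 1, arr.ind = TRUE)
  out[hit[, 1L]] <- bases[hit[, 2L]]
  paste(out, collapse = "")
}

#' Encode a labeled sequence set as a numeric batch
#'
#' Order-preserving: row `i` of the array, `labels[i]` and `ids[i]` all refer
#' to record `i` of the input set.
#'
#' @param data a non-empty `sequence_set` of uniform length.
#' @return An object of class `encoded_batch`: a list with `x` (an
#'   `N x L x 4` array), `labels` (integer) and `ids` (character).
#' @export
encode_batch <- function(data) {
  stopifnot(inherits(data, "sequence_set"))
  if (nrow(data) == 0L) stop("cannot encode an empty sequence set")
  lens <- nchar(data$seq)
  if (length(unique(lens)) != 1L) stop("sequences have mixed lengths")
  L <- lens[[1L]]
  n <- nrow(data)
  codes <- encode_codes(data$seq, L)
  x <- array(0, dim = c(n, L, 4L),
             dimnames = list(data$id, NULL, c("A", "C", "G", "T")))
  keep <- which(codes <= 4L)
  pos <- arrayInd(keep, c(n, L))
  x[cbind(pos[, 1L], pos[, 2L], codes[keep])] <- 1
  structure(list(x = x, labels = data$label, ids = data$id),
            class = "encoded_batch")
}

# Integer base codes (A=1 .. T=4, N=5) as an N x L matrix.
encode_codes <- function(seqs, L) {
  chars <- strsplit(toupper(seqs), "")
  flat <- unlist(chars, use.names = FALSE)
  code <- match(flat, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) {
    bad <- which(is.na(code))[[1L]]
    rec <- ceiling(bad / L)
    stop("invalid base '", flat[bad], "' in record ", rec,
         " at position ", bad - (rec - 1L) * L)
  }
  matrix(code, nrow = length(seqs), ncol = L, byrow = TRUE)
}

# Network-facing layout: an (L, 4, N) array, one slice per sequence.
encode_cube <- function(data) {
  b <- encode_batch(data)
  aperm(b$x, c(2L, 3L, 1L))
}
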