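#' Remove duplicate read pairs (exact and reverse-complement)
#'
#' Pair-aware dereplication in the two modes relevant to opposite-strand
#' artefacts: a pair is a duplicate of an earlier pair if both mate sequences
#' are byte-identical, or if its mate 1 equals the reverse complement of the
#' other pair's mate 2 and vice versa (the same fragment read from the
#' opposite strand). The first occurrence, in input order, is kept.
#'
#' @param reads A read table (see [read_fastq_pair()]) containing both mates
#'   of every pair.
#' @return A list with `reads` (kept rows) and `removed` (number of pairs
#'   removed).
#' @export
dereplicate_pairs <- function(reads) {
  p <- .pairs_wide(reads)
  if (!nrow(p)) return(list(reads = reads, removed = 0L))
  key_fwd <- paste(p$seq1, p$seq2, sep = "|")
  key_rc <- paste(revcomp(p$seq2), revcomp(p$seq1), sep = "|")
  canon <- ifelse(key_fwd <= key_rc, key_fwd, key_rc)
  dup <- duplicated(canon)
  keep_ids <- p$id[!dup]
  list(reads = reads[reads$id %in% keep_ids, , drop = FALSE],
       removed = sum(dup))
}

#' Remove duplicate single reads, pooling mates
#'
#' Exact-sequence dereplication across all reads regardless of pairing (the
#' single-end second pass run after the pair-aware stage). Reads are scanned
#' in input order and the first occurrence of each sequence is kept.
#'
#' @param reads A read table; mates are pooled, pairing is ignored.
#' @return The kept rows of `reads`.
#' @export
dereplicate_single <- function(reads) {
  reads[!duplicated(reads$sequence), , drop = FALSE]
}

# Reshape a read table to one row per pair; errors on unmatched mates.
.pairs_wide <- function(reads) {
  if (!nrow(reads)) {
    return(data.frame(id = character(), seq1 = character(), seq2 = character(),
                      stringsAsFactors = FALSE))
  }
  m1 <- reads[reads$mate == 1L, , drop = FALSE]
  m2 <- reads[reads$mate == 2L, , drop = FALSE]
  bad <- c(setdiff(m1$id, m2$id), setdiff(m2$id, m1$id),
           m1$id[duplicated(m1$id)], m2$id[duplicated(m2$id)])
  if (length(bad))
    stop("unmatched or repeated mates for read id(s): ",
         paste(unique(head(bad, 5L)), collapse = ", "))
  idx <- match(m1$id, m2$id)
  data.frame(id = m1$id, seq1 = m1$sequence, seq2 = m2$sequence[idx],
             qual1 = m1$quality, qual2 = m2$quality[idx],
             chast1 = m1$chastity_pass, chast2 = m2$chastity_pass[idx],
             stringsAsFactors = FALSE)
}
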