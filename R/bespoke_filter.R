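#' Read-filter configuration
#'
#' Parameters of the Sol-B aware read filter. Defaults encode the published
#' filtering recipe for tagged random-primed plasma libraries: minimum length
#' 70 bp, homopolymer runs of more than 20 bases disallowed, at least 2/3 of
#' first-half bases at Q >= 30, removal of reads still containing the full
#' 18-mer Sol-B primer, DUST low-complexity threshold 7, and trimming of a
#' residual 5' B-tail (a suffix of the primer) with at most one mismatch for
#' tails of 10+ bases (shorter tails must match exactly).
#'
#' @param solb_primer The tag sequence (default [SOLB_PRIMER]).
#' @param min_length Minimum post-trim read length in bases.
#' @param homopolymer_max Longest permitted single-base run.
#' @param q_threshold Phred quality counted as "high".
#' @param q_fraction Required fraction of high-quality bases in the first
#'   `floor(L/2)` bases (strict `<` comparison fails the read).
#' @param dust_threshold Reads with [dust_score()] strictly above this are
#'   removed.
#' @param tail_max_mismatch Maximum mismatches when matching a B-tail of 10
#'   or more bases.
#' @param dust_window,dust_step Window geometry for [dust_score()].
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(solb_primer = SOLB_PRIMER, min_length = 70L,
                          homopolymer_max = 20L, q_threshold = 30L,
                          q_fraction = 2 / 3, dust_threshold = 7,
                          tail_max_mismatch = 1L,
                          dust_window = 64L, dust_step = 32L) {
  stopifnot(min_length > 0L, homopolymer_max >= 1L, q_threshold >= 0L,
            q_fraction > 0, q_fraction <= 1, dust_threshold >= 0,
            tail_max_mismatch >= 0L, nchar(solb_primer) >= 1L)
  structure(list(solb_primer = solb_primer, min_length = as.integer(min_length),
                 homopolymer_max = as.integer(homopolymer_max),
                 q_threshold = as.integer(q_threshold), q_fraction = q_fraction,
                 dust_threshold = dust_threshold,
                 tail_max_mismatch = as.integer(tail_max_mismatch),
                 dust_window = as.integer(dust_window),
                 dust_step = as.integer(dust_step)),
            class = "filter_config")
}

# Rule order used for attribution when several rules fail.
.bespoke_rules <- c("chastity", "homopolymer", "n_content", "lowq_half",
                    "solb_contained", "too_short")

# Vectorised: index into .bespoke_rules of the first failing rule per read,
# or NA_integer_ when the read passes all six.
.bespoke_rule_index <- function(sequence, quality, chastity_pass, config) {
  n <- length(sequence)
  if (!n) return(integer())
  len <- nchar(sequence)
  half <- len %/% 2L
  fail_lowq <- vapply(seq_len(n), function(i) {
    h <- half[i]
    if (h == 0L) return(FALSE)
    q <- phred_decode(substr(quality[i], 1L, h))
    sum(q >= config$q_threshold) < config$q_fraction * h
  }, logical(1))
  fails <- cbind(
    chastity = !chastity_pass,
    homopolymer = grepl(sprintf("(.)\\1{%d,}", config$homopolymer_max),
                        sequence, perl = TRUE),
    n_content = grepl("N", sequence, fixed = TRUE),
    lowq_half = fail_lowq,
    solb_contained = grepl(config$solb_primer, sequence, fixed = TRUE),
    too_short = len < config$min_length
  )
  first <- apply(fails, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else NA_integer_
  })
  as.integer(first)
}

#' Apply the six bespoke per-read rules to one read pair
#'
#' A read fails if it failed the chastity filter, has a single-base run longer
#' than `homopolymer_max` ("more than 20 in a row"), contains an `N`, has
#' fewer than `q_fraction` of its first `floor(L/2)` bases at
#' `Q >= q_threshold`, still contains the full Sol-B primer, or is shorter
#' than `min_length`. The pair is removed when either mate fails, and the
#' removal is attributed to the first failing rule in that order (mate order
#' does not matter; rule order does). B-tail trimming ([trim_b_tail()]) is
#' assumed to have already happened.
#'
#' @param pair A read table with the two mates of one pair (two rows).
#' @param config A [filter_config()].
#' @return A list: `keep` (logical) and `rule` (the attributed rule name, or
#'   `NA` when kept).
#' @export
apply_bespoke_filter <- function(pair, config = filter_config()) {
  stopifnot(is.data.frame(pair), nrow(pair) %in% 1:2)
  idx <- .bespoke_rule_index(pair$sequence, pair$quality, pair$chastity_pass, config)
  first <- suppressWarnings(min(idx, na.rm = TRUE))
  if (!is.finite(first)) list(keep = TRUE, rule = NA_character_)
  else list(keep = FALSE, rule = .bespoke_rules[first])
}

#' Trim a residual 5' B-tail
#'
#' BpmI digestion of the amplified library leaves a short 5' fragment of the
#' Sol-B primer (the "B-tail") on some reads. This removes the longest read
#' prefix (1-18 bases) that matches a suffix of the primer, with mismatch
#' allowance scaled to the match length: `min(tail_max_mismatch,
#' floor(len/10))` mismatches, i.e. exact match below 10 bases. Qualities are
#' trimmed in lockstep; reads with no matching prefix are unchanged. The
#' allowance means a read whose start coincides with a primer suffix by chance
#' can be over-trimmed by a few bases; at default lengths this is harmless.
#'
#' @param reads A read table (any number of rows).
#' @param config A [filter_config()].
#' @return `reads` with `sequence` and `quality` trimmed.
#' @export
trim_b_tail <- function(reads, config = filter_config()) {
  if (!nrow(reads)) return(reads)
  prim <- config$solb_primer
  plen <- nchar(prim)
  seqs <- reads$sequence
  cut <- integer(length(seqs))
  remaining <- nchar(seqs) > 0L
  for (k in seq.int(plen, 1L)) {
    if (!any(remaining)) break
    allowed <- min(config$tail_max_mismatch, k %/% 10L)
    suf <- substr(prim, plen - k + 1L, plen)
    cand <- which(remaining & cut == 0L & nchar(seqs) >= k)
    if (!length(cand)) next
    mism <- integer(length(cand))
    for (j in seq_len(k)) {
      mism <- mism + (substr(seqs[cand], j, j) != substr(suf, j, j))
    }
    hit <- mism <= allowed
    cut[cand[hit]] <- k
  }
  trim <- cut > 0L
  if (any(trim)) {
    reads$sequence[trim] <- substr(reads$sequence[trim], cut[trim] + 1L,
                                   nchar(reads$sequence[trim]))
    reads$quality[trim] <- substr(reads$quality[trim], cut[trim] + 1L,
                                  nchar(reads$quality[trim]))
  }
  reads
}
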