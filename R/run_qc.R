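#' Run the full read-QC stack on paired reads
#'
#' Applies the cleaning stages in pipeline order:
#' \enumerate{
#'   \item DUST low-complexity removal (either mate scoring above
#'     `dust_threshold`),
#'   \item pair-aware dereplication (exact and reverse-complement duplicates,
#'     [dereplicate_pairs()]),
#'   \item B-tail trimming ([trim_b_tail()]),
#'   \item the six bespoke per-read rules ([apply_bespoke_filter()]),
#'   \item single-read dereplication pooling mates ([dereplicate_single()]);
#'     a pair whose mate is a single-level duplicate is dropped whole so the
#'     report stays pair-consistent.
#' }
#' Every input pair is accounted for exactly once: either it survives or it is
#' attributed to the first stage/rule that removed it. The surviving read
#' count (`2 * surviving pairs`) is the `filtered_read_count` denominator used
#' to normalise taxon counts downstream.
#'
#' @param reads A read table (see [read_fastq_pair()]) with both mates of
#'   every pair, or a length-2 character vector of FASTQ paths
#'   (mate 1, mate 2).
#' @param config A [filter_config()].
#' @return A list of class `qc_result`: `reads` (surviving, trimmed read
#'   table) and `report` (class `qc_report`: `input_pairs`, `surviving_pairs`,
#'   `filtered_read_count`, and named per-rule removal counts).
#' @examples
#' sim <- simulate_reads(sim_config(seed = 1, n_read_pairs = 200))
#' res <- run_qc(sim$reads)
#' res$report
#' @export
run_qc <- function(reads, config = filter_config()) {
  if (is.character(reads)) {
    stopifnot(length(reads) == 2L)
    reads <- read_fastq_pair(reads[1L], reads[2L])
  }
  p <- .pairs_wide(reads)
  n_in <- nrow(p)
  removed <- setNames(integer(9L),
                      c("low_complexity", "duplicate_pair", .bespoke_rules,
                        "duplicate_single"))

  # 1. DUST
  if (nrow(p)) {
    d1 <- dust_score(p$seq1, config$dust_window, config$dust_step)
    d2 <- dust_score(p$seq2, config$dust_window, config$dust_step)
    fail <- d1 > config$dust_threshold | d2 > config$dust_threshold
    removed["low_complexity"] <- sum(fail)
    p <- p[!fail, , drop = FALSE]
  }

  # 2. pair dereplication (exact + reverse-complement)
  if (nrow(p)) {
    key_fwd <- paste(p$seq1, p$seq2, sep = "|")
    key_rc <- paste(revcomp(p$seq2), revcomp(p$seq1), sep = "|")
    canon <- ifelse(key_fwd <= key_rc, key_fwd, key_rc)
    dup <- duplicated(canon)
    removed["duplicate_pair"] <- sum(dup)
    p <- p[!dup, , drop = FALSE]
  }

  # 3. B-tail trim (both mates; no removals)
  if (nrow(p)) {
    t1 <- trim_b_tail(data.frame(sequence = p$seq1, quality = p$qual1,
                                 stringsAsFactors = FALSE), config)
    t2 <- trim_b_tail(data.frame(sequence = p$seq2, quality = p$qual2,
                                 stringsAsFactors = FALSE), config)
    p$seq1 <- t1$sequence; p$qual1 <- t1$quality
    p$seq2 <- t2$sequence; p$qual2 <- t2$quality
  }

  # 4. bespoke rules; pair removed when either mate fails, attributed to the
  #    first failing rule in rule order
  if (nrow(p)) {
    i1 <- .bespoke_rule_index(p$seq1, p$qual1, p$chast1, config)
    i2 <- .bespoke_rule_index(p$seq2, p$qual2, p$chast2, config)
    first <- pmin(i1, i2, na.rm = TRUE)
    for (r in seq_along(.bespoke_rules)) {
      removed[.bespoke_rules[r]] <- sum(first == r, na.rm = TRUE)
    }
    p <- p[is.na(first), , drop = FALSE]
  }

  # 5. single-read dereplication, mates pooled in (pair, mate) order
  if (nrow(p)) {
    pooled <- c(rbind(p$seq1, p$seq2))   # interleaved: pair 1 mate 1, mate 2, ...
    dup <- duplicated(pooled)
    pair_dup <- dup[c(TRUE, FALSE)] | dup[c(FALSE, TRUE)]
    removed["duplicate_single"] <- sum(pair_dup)
    p <- p[!pair_dup, , drop = FALSE]
  }

  out <- .pairs_long(p, reads)
  report <- structure(
    list(input_pairs = n_in, surviving_pairs = nrow(p),
         filtered_read_count = 2L * nrow(p), removed = removed),
    class = "qc_report"
  )
  structure(list(reads = out, report = report), class = "qc_result")
}

# Rebuild a long read table from the wide pair table, preserving ancillary
# columns (comment, sample, ...) of the original rows but using trimmed
# sequence/quality.
.pairs_long <- function(p, reads) {
  keep <- reads[reads$id %in% p$id, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  i <- match(keep$id, p$id)
  keep$sequence <- ifelse(keep$mate == 1L, p$seq1[i], p$seq2[i])
  keep$quality <- ifelse(keep$mate == 1L, p$qual1[i], p$qual2[i])
  keep
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Read QC attrition\n")
  cat("  input pairs:     ", x$input_pairs, "\n")
  cat("  surviving pairs: ", x$surviving_pairs,
      " (filtered_read_count = ", x$filtered_read_count, ")\n", sep = "")
  rem <- x$removed[x$removed > 0]
  if (length(rem)) {
    cat("  removed by rule:\n")
    for (r in names(rem)) cat(sprintf("    %-16s %d\n", r, rem[[r]]))
  } else cat("  nothing removed\n")
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(metric = c("input_pairs", "surviving_pairs", "filtered_read_count",
                        names(x$removed)),
             count = c(x$input_pairs, x$surviving_pairs, x$filtered_read_count,
                       unname(x$removed)))
}

#' Write an attrition report to TSV and/or JSON
#'
#' @param report A `qc_report` from [run_qc()].
#' @param tsv,json Optional output paths.
#' @return Invisibly, the report.
#' @export
write_qc_report <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "qc_report"))
  if (!is.null(tsv)) {
    write.table(as.data.frame(report), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(input_pairs = report$input_pairs,
           surviving_pairs = report$surviving_pairs,
           filtered_read_count = report$filtered_read_count,
           removed = as.list(report$removed)),
      json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}
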