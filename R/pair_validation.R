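#' Paired-read concordance for one taxon
#'
#' Low-abundance taxon calls made from single reads are fragile: a spurious
#' alignment affects one mate, a real organism tends to hit both mates of a
#' fragment. This counts, for the given taxon, the total assigned reads, the
#' read pairs whose two mates are *both* assigned to the taxon, the samples
#' contributing assigned reads, and — when a second, independent assignment
#' table is supplied (e.g. a different classifier or database) — the reads
#' confirmed by both tables.
#'
#' @param assignments Assignment table (`read_id`, `sample_id`, `mate`,
#'   `taxon`, ...).
#' @param taxon Taxon to audit; absence yields zeros, not an error.
#' @param second Optional confirmation assignment table.
#' @return An object of class `concordance_stats`: `taxon`, `total_reads`,
#'   `concordant_pairs`, `n_samples`, `confirmed_reads` (`NA` without a
#'   second table).
#' @examples
#' fx <- plant_audit_fixture("Borrelia", 47, 5, 1)
#' pair_concordance(fx$assignments, "Borrelia", fx$confirm)
#' @export
pair_concordance <- function(assignments, taxon, second = NULL) {
  stopifnot(is.data.frame(assignments),
            all(c("read_id", "mate", "taxon") %in% names(assignments)))
  a <- assignments[!is.na(assignments$taxon) & assignments$taxon == taxon, ,
                   drop = FALSE]
  total <- nrow(a)
  pairs <- 0L
  if (total) {
    mates <- split(a$mate, a$read_id)
    pairs <- sum(vapply(mates, function(m) all(1:2 %in% m), logical(1)))
  }
  n_samples <- if ("sample_id" %in% names(a)) length(unique(a$sample_id))
               else NA_integer_
  confirmed <- NA_integer_
  if (!is.null(second)) {
    s <- second[!is.na(second$taxon) & second$taxon == taxon, , drop = FALSE]
    confirmed <- sum(paste(a$read_id, a$mate) %in% paste(s$read_id, s$mate))
  }
  structure(list(taxon = taxon, total_reads = total, concordant_pairs = pairs,
                 n_samples = n_samples, confirmed_reads = confirmed),
            class = "concordance_stats")
}

#' @export
print.concordance_stats <- function(x, ...) {
  cat(sprintf("%s: %d reads assigned, %d concordant pair%s",
              x$taxon, x$total_reads, x$concordant_pairs,
              if (x$concordant_pairs == 1) "" else "s"))
  if (!is.na(x$n_samples)) cat(sprintf(", %d sample%s contributing",
                                       x$n_samples,
                                       if (x$n_samples == 1) "" else "s"))
  if (!is.na(x$confirmed_reads))
    cat(sprintf(", %d read%s confirmed by second classifier",
                x$confirmed_reads, if (x$confirmed_reads == 1) "" else "s"))
  cat("\n")
  invisible(x)
}

#' Verdict on a low-abundance taxon call
#'
#' Turns concordance statistics into an explicit supported/unsupported
#' verdict. The call is "unsupported" when the concordant-pair count is at or
#' below `pairs_per_sample_floor * n_samples_total` *and* the cross-classifier
#' confirmation fraction is below `confirm_frac_floor` (a missing confirmation
#' table leaves the decision to the pair criterion alone). The thresholds are
#' reported alongside the verdict; they are explicit configuration, defaulted
#' to values under which tens of discordant single-mate reads across a
#' ~100-sample study do not count as evidence of presence.
#'
#' @param stats A `concordance_stats` object.
#' @param n_samples_total Number of samples in the study (the denominator for
#'   the pair floor).
#' @param pairs_per_sample_floor Concordant pairs tolerated per study sample
#'   before the pair criterion counts as support (default 1).
#' @param confirm_frac_floor Minimum confirmed fraction of assigned reads for
#'   the confirmation criterion to count as support (default 0.1).
#' @return A list of class `concordance_report`: `verdict` ("supported" /
#'   "unsupported"), `stats`, `thresholds`, `text`.
#' @export
concordance_report <- function(stats, n_samples_total,
                               pairs_per_sample_floor = 1,
                               confirm_frac_floor = 0.1) {
  stopifnot(inherits(stats, "concordance_stats"), n_samples_total >= 1)
  pair_floor <- pairs_per_sample_floor * n_samples_total
  frac <- if (stats$total_reads > 0 && !is.na(stats$confirmed_reads))
    stats$confirmed_reads / stats$total_reads else NA_real_
  weak_pairs <- stats$concordant_pairs <= pair_floor
  weak_confirm <- is.na(frac) || frac < confirm_frac_floor
  verdict <- if (weak_pairs && weak_confirm) "unsupported" else "supported"
  text <- sprintf(
    paste0("%s: %d reads assigned, %d concordant pairs (floor %g over %d ",
           "samples), confirmation fraction %s (floor %g) -> %s"),
    stats$taxon, stats$total_reads, stats$concordant_pairs, pair_floor,
    n_samples_total,
    if (is.na(frac)) "not assessed" else sprintf("%.3f", frac),
    confirm_frac_floor, verdict)
  structure(list(verdict = verdict, stats = stats,
                 thresholds = list(pairs_per_sample_floor = pairs_per_sample_floor,
                                   pair_floor = pair_floor,
                                   confirm_frac_floor = confirm_frac_floor),
                 text = text),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}
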