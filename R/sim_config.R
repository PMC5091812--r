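#' Sol-B primer sequence
#'
#' The 18-nt tag flanking the random nonamers used for reverse transcription
#' and amplification of plasma RNA. Residual copies of the full tag, or of its
#' 5' "B-tail" fragment left behind by BpmI digestion, are sequencing
#' artefacts that the read filter removes.
#'
#' @format A length-one character vector.
#' @export
SOLB_PRIMER <- "GTTTCCCACTGGAGGATA"

#' Defect classes the read simulator can plant
#' @keywords internal
.defect_names <- c(
  "chastity_fail", "homopolymer", "contains_n", "lowq_half", "solb_full",
  "solb_tail", "short", "duplicate_pair", "revcomp_duplicate", "low_complexity"
)

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults emulate
#' the study design the package targets: four study groups (25 CFS cases,
#' 25 healthy controls, 13 ADCLS, 11 SLE), seven plasma-free negative
#' extraction controls and one spiked positive control, processed in three
#' extraction/library/sequencing batches, with a subset of samples
#' re-sequenced (7 CFS, 9 healthy, 2 ADCLS, 2 SLE). Reads are 100 bp paired
#' end; the overwhelming majority of reads are host-derived
#' (`host_fraction = 0.98`), so microbial depth per sample is only
#' `(1 - host_fraction)` of the filtered-read denominator.
#'
#' Count-level truth structure: each taxon has a baseline relative abundance
#' (log-normal across taxa); `n_contaminant_taxa` of them are reagent
#' contaminants, the only taxa with non-zero expectation in negative controls;
#' `n_batch_effect_taxa` receive a planted multiplier of `batch_effect_fold`
#' in batch 3 (on top of log-normal lot jitter with SD `batch_effect_sd`
#' applied to all taxa when non-zero); `n_group_effect_taxa` receive a
#' multiplier of `group_effect_fold` in the CFS group. Effect taxa are drawn
#' from the upper half of baseline abundance so that recovery is identifiable
#' at desk-scale depth, and group-effect taxa are drawn within the
#' batch-effect set when one exists (low-biomass group signals in practice ride
#' on reagent/batch structure).
#'
#' Read-level truth structure: each pair is clean or carries exactly one
#' planted defect, drawn multinomially from `defect_rates` (probabilities must
#' sum to at most 1). Planted defects violate exactly the corresponding filter
#' rule; clean reads violate none.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param n_per_group Named integer vector of sample counts per group. Names
#'   must be among CFS, Healthy, ADCLS, SLE, NegControl, PosControl.
#' @param n_resequenced Named integer vector: how many samples per study group
#'   are sequenced twice (technical replicate libraries).
#' @param n_batches Number of processing batches (default 3).
#' @param n_taxa Total number of taxa in the simulated community.
#' @param n_contaminant_taxa Number of reagent-contaminant taxa.
#' @param n_batch_effect_taxa Taxa with a planted batch-3 fold change.
#' @param n_group_effect_taxa Taxa with a planted CFS fold change.
#' @param batch_effect_sd Log-scale SD of per-batch lot multipliers applied to
#'   every taxon (0 disables lot jitter).
#' @param batch_effect_fold Planted batch-3 multiplier for batch-effect taxa.
#' @param group_effect_fold Planted CFS multiplier for group-effect taxa.
#' @param host_fraction Fraction of filtered reads that are host-derived and
#'   never reach the taxon table.
#' @param library_size_mean Mean filtered library size in read pairs
#'   (desk-scale default 50,000 pairs).
#' @param library_size_cv Coefficient of variation of library sizes
#'   (log-normal).
#' @param dispersion Negative-binomial dispersion of counts around their
#'   expectation (variance mu + dispersion * mu^2).
#' @param defect_rates Named probabilities for the ten read defect classes;
#'   see `.defect_names`. Sum must be <= 1; the remainder is clean reads.
#' @param read_length Read length in bases (default 100).
#' @param n_read_pairs Read pairs generated per sample by [simulate_reads()].
#' @param rank Taxonomic rank label attached to simulated taxa
#'   ("phylum" or "genus").
#' @param concordance Fraction of assignable read pairs whose two mates both
#'   receive the taxon (used by [simulate_assignments()]).
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_taxa = 30)
#' cfg$n_per_group
#' @export
sim_config <- function(seed = 1L,
                       n_per_group = c(CFS = 25L, Healthy = 25L, ADCLS = 13L,
                                       SLE = 11L, NegControl = 7L, PosControl = 1L),
                       n_resequenced = c(CFS = 7L, Healthy = 9L, ADCLS = 2L, SLE = 2L),
                       n_batches = 3L,
                       n_taxa = 100L,
                       n_contaminant_taxa = 50L,
                       n_batch_effect_taxa = 8L,
                       n_group_effect_taxa = 0L,
                       batch_effect_sd = 0.5,
                       batch_effect_fold = 10,
                       group_effect_fold = 10,
                       host_fraction = 0.98,
                       library_size_mean = 50000,
                       library_size_cv = 0.5,
                       dispersion = 0.3,
                       defect_rates = c(chastity_fail = 0.02, homopolymer = 0.02,
                                        contains_n = 0.02, lowq_half = 0.02,
                                        solb_full = 0.02, solb_tail = 0.05,
                                        short = 0.02, duplicate_pair = 0.02,
                                        revcomp_duplicate = 0.01,
                                        low_complexity = 0.02),
                       read_length = 100L,
                       n_read_pairs = 1000L,
                       rank = c("genus", "phylum"),
                       concordance = 0.8) {
  rank <- match.arg(rank)
  groups <- c("CFS", "Healthy", "ADCLS", "SLE", "NegControl", "PosControl")
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% groups))
    stop("n_per_group must be named with groups among: ", paste(groups, collapse = ", "))
  full <- setNames(integer(length(groups)), groups)
  full[names(n_per_group)] <- as.integer(n_per_group)
  n_per_group <- full

  rates <- setNames(numeric(length(.defect_names)), .defect_names)
  if (length(defect_rates)) {
    if (is.null(names(defect_rates)) || !all(names(defect_rates) %in% .defect_names))
      stop("defect_rates must be named with defects among: ",
           paste(.defect_names, collapse = ", "))
    rates[names(defect_rates)] <- defect_rates
  }
  if (any(rates < 0 | rates > 1)) stop("defect rates must be probabilities in [0,1]")
  if (sum(rates) > 1) stop("defect rates sum to more than 1")

  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_batches >= 1L, n_taxa >= 0L,
    n_contaminant_taxa >= 0L, n_contaminant_taxa <= n_taxa,
    n_batch_effect_taxa >= 0L, n_batch_effect_taxa <= n_taxa,
    n_group_effect_taxa >= 0L, n_group_effect_taxa <= n_taxa,
    batch_effect_sd >= 0, batch_effect_fold > 0, group_effect_fold > 0,
    host_fraction >= 0, host_fraction <= 1,
    library_size_mean > 0, library_size_cv > 0, dispersion >= 0,
    read_length >= 1L, n_read_pairs >= 0L,
    concordance >= 0, concordance <= 1,
    all(n_per_group >= 0L), all(n_resequenced >= 0L)
  )
  if (n_batches < 2L && batch_effect_sd > 0)
    stop("batch_effect_sd > 0 requires at least 2 batches")
  if (any(!names(n_resequenced) %in% setdiff(groups, c("NegControl", "PosControl"))))
    stop("n_resequenced only applies to study groups")
  if (any(n_resequenced > n_per_group[names(n_resequenced)]))
    stop("cannot re-sequence more samples than exist in a group")

  structure(
    list(seed = as.integer(seed), n_per_group = n_per_group,
         n_resequenced = n_resequenced, n_batches = as.integer(n_batches),
         n_taxa = as.integer(n_taxa),
         n_contaminant_taxa = as.integer(n_contaminant_taxa),
         n_batch_effect_taxa = as.integer(n_batch_effect_taxa),
         n_group_effect_taxa = as.integer(n_group_effect_taxa),
         batch_effect_sd = batch_effect_sd, batch_effect_fold = batch_effect_fold,
         group_effect_fold = group_effect_fold, host_fraction = host_fraction,
         library_size_mean = library_size_mean, library_size_cv = library_size_cv,
         dispersion = dispersion, defect_rates = rates,
         read_length = as.integer(read_length),
         n_read_pairs = as.integer(n_read_pairs), rank = rank,
         concordance = concordance),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  samples per group: ",
      paste(names(x$n_per_group), x$n_per_group, sep = "=", collapse = ", "), "\n")
  cat("  taxa: ", x$n_taxa, " (", x$n_contaminant_taxa, " contaminant, ",
      x$n_batch_effect_taxa, " batch-effect, ", x$n_group_effect_taxa,
      " group-effect)\n", sep = "")
  cat("  batches: ", x$n_batches, ", lot SD ", x$batch_effect_sd,
      ", batch fold ", x$batch_effect_fold, "\n", sep = "")
  cat("  reads: ", x$n_read_pairs, " pairs x ", x$read_length, " bp, defect mass ",
      round(sum(x$defect_rates), 3), "\n", sep = "")
  invisible(x)
}
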