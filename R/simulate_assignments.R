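#' Expand a count matrix into a per-read assignment table
#'
#' Emits one assignment row per counted read so that rolling the table back
#' up with [build_count_matrix()] reproduces the matrix exactly. For each
#' sample/taxon cell with count \eqn{c}, the number of concordant pairs (both
#' mates assigned the taxon) is drawn binomially from `floor(c/2)` candidate
#' pairs at `config$concordance`; concordant pairs contribute two rows with
#' mates 1 and 2 of the same read id, the remaining reads come from distinct
#' pairs with a random mate. Optionally a fixed number of `HOST`-assigned
#' reads per sample is appended to exercise host subtraction.
#'
#' @param sim Output of [simulate_counts()], or a raw [taxon_matrix()].
#' @param config The [sim_config()] used (supplies `concordance`, `rank`,
#'   `seed`).
#' @param n_host_reads Host (`HOST` taxon) reads appended per sample; a token
#'   stand-in for the overwhelming host content removed upstream at full scale.
#' @return A list: `assignments` (data frame `read_id`, `sample_id`, `mate`,
#'   `taxon`, `rank`) and `truth` (per-taxon totals and concordant-pair
#'   counts).
#' @export
simulate_assignments <- function(sim, config, n_host_reads = 0L) {
  tm <- if (inherits(sim, "taxon_matrix")) sim else sim$matrix
  stopifnot(inherits(tm, "taxon_matrix"), !tm$normalized,
            inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    counts <- tm$counts
    rows <- vector("list", ncol(counts))
    conc <- setNames(integer(nrow(counts)), rownames(counts))
    for (j in seq_along(colnames(counts))) {
      s <- colnames(counts)[j]
      ct <- counts[, j]
      nz <- which(ct > 0)
      if (!length(nz) && n_host_reads == 0L) next
      npair <- integer(length(nz))
      if (length(nz)) {
        npair <- rbinom(length(nz), floor(ct[nz] / 2), config$concordance)
        conc[nz] <- conc[nz] + npair
      }
      n_single <- ct[nz] - 2L * npair
      n_frag <- npair + n_single                     # distinct read pairs used
      frag_taxon <- rep(rownames(counts)[nz], n_frag)
      frag_is_pair <- unlist(lapply(seq_along(nz), function(i) {
        rep(c(TRUE, FALSE), c(npair[i], n_single[i]))
      }), use.names = FALSE)
      ids <- sprintf("%s_P%07d", s, seq_len(sum(n_frag)))
      reps <- ifelse(frag_is_pair, 2L, 1L)
      mate <- unlist(lapply(seq_along(ids), function(i) {
        if (frag_is_pair[i]) 1:2 else sample(1:2, 1L)
      }), use.names = FALSE)
      df <- data.frame(read_id = rep(ids, reps), sample_id = s,
                       mate = mate, taxon = rep(frag_taxon, reps),
                       rank = tm$rank, stringsAsFactors = FALSE)
      if (n_host_reads > 0L) {
        df <- rbind(df, data.frame(
          read_id = sprintf("%s_H%07d", s, seq_len(n_host_reads)),
          sample_id = s, mate = sample(1:2, n_host_reads, replace = TRUE),
          taxon = "HOST", rank = tm$rank, stringsAsFactors = FALSE))
      }
      rows[[j]] <- df
    }
    assignments <- do.call(rbind, rows)
    if (is.null(assignments)) {
      assignments <- data.frame(read_id = character(), sample_id = character(),
                                mate = integer(), taxon = character(),
                                rank = character(), stringsAsFactors = FALSE)
    }
    list(assignments = assignments,
         truth = data.frame(taxon = rownames(counts),
                            total_reads = unname(rowSums(counts)),
                            concordant_pairs = unname(conc),
                            stringsAsFactors = FALSE))
  })
}

#' Build a low-abundance audit fixture
#'
#' Constructs a primary assignment table (and optionally a second,
#' cross-classifier confirmation table) for one taxon with exactly the
#' requested structure: `n_reads` reads in total, of which `n_concordant`
#' pairs have both mates assigned, spread over `n_samples` samples, and
#' `n_confirmed` of the reads also present in the confirmation table. This is
#' the shape of the classic low-abundance audit: a pathogen-like genus called
#' from tens of single-mate reads that melts away under paired-read and
#' second-classifier scrutiny.
#'
#' @param taxon Taxon name.
#' @param n_reads Total reads assigned to the taxon in the primary table.
#' @param n_concordant Pairs with both mates assigned (2 reads each).
#' @param n_confirmed Reads also assigned by the confirmation table.
#' @param n_samples Samples the reads are spread over.
#' @param rank Rank label.
#' @param seed Seed for the layout draw.
#' @return A list `assignments`, `confirm` (both assignment tables).
#' @examples
#' fx <- plant_audit_fixture("Borrelia", 47, 5, 1, n_samples = 16)
#' pair_concordance(fx$assignments, "Borrelia", fx$confirm)
#' @export
plant_audit_fixture <- function(taxon = "Borrelia", n_reads = 47L,
                                n_concordant = 5L, n_confirmed = 1L,
                                n_samples = 16L, rank = "genus", seed = 1L) {
  stopifnot(2L * n_concordant <= n_reads, n_confirmed <= n_reads, n_samples >= 1L)
  withr::with_seed(as.integer(seed), {
    n_single <- n_reads - 2L * n_concordant
    samples <- sprintf("S%03d", seq_len(n_samples))
    pair_ids <- sprintf("AUD_P%05d", seq_len(n_concordant + n_single))
    assignments <- data.frame(
      read_id = c(rep(pair_ids[seq_len(n_concordant)], each = 2L),
                  pair_ids[n_concordant + seq_len(n_single)]),
      sample_id = c(rep(sample(samples, n_concordant, replace = TRUE), each = 2L),
                    sample(samples, n_single, replace = TRUE)),
      mate = c(rep(1:2, n_concordant), sample(1:2, n_single, replace = TRUE)),
      taxon = taxon, rank = rank, stringsAsFactors = FALSE
    )
    idx <- if (n_confirmed) sample.int(nrow(assignments), n_confirmed) else integer()
    confirm <- assignments[idx, , drop = FALSE]
    rownames(confirm) <- NULL
    list(assignments = assignments, confirm = confirm)
  })
}
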