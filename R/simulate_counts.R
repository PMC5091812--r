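#' Simulate a taxon count matrix with contamination and batch structure
#'
#' Draws a sample x taxon count matrix from the generative model
#' \deqn{E[y_{st}] = d_s (1 - h)\, a_t\, b_{t,batch(s)}\, g_{t,group(s)}}
#' where \eqn{d_s} is the sample's filtered-read denominator (log-normal with
#' mean `2 * library_size_mean` reads and CV `library_size_cv`), \eqn{h} the
#' host fraction, \eqn{a_t} the taxon's baseline relative abundance
#' (log-normal across taxa, normalised to sum 1), and \eqn{b}, \eqn{g} the
#' per-batch and per-group truth multipliers described in [sim_config()].
#' Counts are negative-binomial around that expectation with dispersion
#' `config$dispersion` (variance \eqn{\mu + \phi \mu^2}).
#'
#' Negative controls contain only the contaminant taxa (their baseline
#' abundances un-renormalised, so negatives yield fewer microbial reads);
#' non-contaminant taxa have expectation exactly zero there. The positive
#' control behaves like a study sample but is excluded from group statistics
#' downstream. Re-sequenced samples share their parent's biological
#' expectation but draw their own batch, library size and counts, and are
#' linked through `replicate_of` in the metadata.
#'
#' @param config A [sim_config()].
#' @return A list: `matrix` (raw [taxon_matrix()]), `metadata` (its sample
#'   table), and `truth` (list with `base_abundance`, `contaminant`,
#'   `batch_multipliers` (taxa x batches), `group_multipliers` (taxa x
#'   groups), `batch_effect_taxa`, `group_effect_taxa`, `expected_library`,
#'   `realized_library` = column sums, and `expected` = the full expectation
#'   matrix).
#' @examples
#' sim <- simulate_counts(sim_config(seed = 2, n_taxa = 30))
#' sim$matrix
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_batches < 2L && config$batch_effect_sd > 0)
    stop("batch_effect_sd > 0 requires at least 2 batches")
  withr::with_seed(config$seed, .sim_counts_impl(config))
}

.sim_counts_impl <- function(config) {
  groups <- names(config$n_per_group)
  md <- do.call(rbind, lapply(groups, function(g) {
    n <- config$n_per_group[[g]]
    if (!n) return(NULL)
    data.frame(
      sample_id = sprintf("%s%02d", switch(g, NegControl = "NEG", PosControl = "POS",
                                           toupper(substr(g, 1, 3))), seq_len(n)),
      group = g,
      control = switch(g, NegControl = "negative", PosControl = "positive", "none"),
      replicate_of = NA_character_, stringsAsFactors = FALSE
    )
  }))
  # stratified batch assignment keeps group and batch estimable
  md$batch <- NA_integer_
  for (i in split(seq_len(nrow(md)), md$group)) {
    md$batch[i] <- rep_len(seq_len(config$n_batches), length(i))
  }

  # re-sequenced libraries: same biology, own batch/library/noise
  reseq <- config$n_resequenced[config$n_resequenced > 0]
  if (length(reseq)) {
    extra <- do.call(rbind, lapply(names(reseq), function(g) {
      pool <- md$sample_id[md$group == g]
      parents <- pool[seq_len(min(reseq[[g]], length(pool)))]
      data.frame(sample_id = paste0(parents, "b"), group = g, control = "none",
                 replicate_of = parents,
                 batch = sample.int(config$n_batches, length(parents), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    md <- rbind(md, extra)
  }
  n_samp <- nrow(md)

  # filtered-read denominators (reads, not pairs)
  mean_reads <- 2 * config$library_size_mean
  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  md$filtered_read_count <- pmax(1, round(rlnorm(n_samp,
                                                 log(mean_reads) - sdlog^2 / 2, sdlog)))

  nt <- config$n_taxa
  taxa <- sprintf("taxon_%03d", seq_len(nt))
  base <- rlnorm(nt, 0, 1.5)
  base <- base / sum(base)
  names(base) <- taxa
  contaminant <- setNames(logical(nt), taxa)
  if (config$n_contaminant_taxa)
    contaminant[sample.int(nt, config$n_contaminant_taxa)] <- TRUE

  # effect taxa drawn from the upper half of baseline abundance so planted
  # fold changes are identifiable at desk-scale depth
  upper <- which(rank(base, ties.method = "first") > nt / 2)
  batch_taxa <- integer()
  if (config$n_batch_effect_taxa) {
    batch_taxa <- sort(sample(upper, min(config$n_batch_effect_taxa, length(upper))))
  }
  group_taxa <- integer()
  if (config$n_group_effect_taxa) {
    pool <- if (length(batch_taxa) >= config$n_group_effect_taxa) batch_taxa else upper
    group_taxa <- sort(sample(pool, min(config$n_group_effect_taxa, length(pool))))
  }

  bmult <- matrix(1, nt, config$n_batches,
                  dimnames = list(taxa, paste0("batch", seq_len(config$n_batches))))
  if (config$batch_effect_sd > 0) {
    bmult[] <- exp(matrix(rnorm(nt * config$n_batches, 0, config$batch_effect_sd),
                          nt))
  }
  if (length(batch_taxa) && config$n_batches >= 3L)
    bmult[batch_taxa, 3L] <- bmult[batch_taxa, 3L] * config$batch_effect_fold
  gmult <- matrix(1, nt, length(groups), dimnames = list(taxa, groups))
  if (length(group_taxa)) gmult[group_taxa, "CFS"] <- config$group_effect_fold

  depth <- md$filtered_read_count * (1 - config$host_fraction)
  mu <- matrix(0, nt, n_samp, dimnames = list(taxa, md$sample_id))
  for (s in seq_len(n_samp)) {
    a <- base
    if (md$control[s] == "negative") a <- base * contaminant
    mu[, s] <- depth[s] * a * bmult[, md$batch[s]] * gmult[, md$group[s]]
  }
  counts <- matrix(0L, nt, n_samp, dimnames = dimnames(mu))
  pos <- mu > 0
  if (config$dispersion > 0) {
    counts[pos] <- as.integer(rnbinom(sum(pos), mu = mu[pos],
                                      size = 1 / config$dispersion))
  } else {
    counts[pos] <- as.integer(stats::rpois(sum(pos), mu[pos]))
  }

  tm <- taxon_matrix(counts, md, rank = config$rank)
  truth <- list(base_abundance = base, contaminant = contaminant,
                batch_multipliers = bmult, group_multipliers = gmult,
                batch_effect_taxa = taxa[batch_taxa],
                group_effect_taxa = taxa[group_taxa],
                expected_library = depth, expected = mu,
                realized_library = colSums(counts))
  list(matrix = tm, metadata = tm$samples, truth = truth)
}
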