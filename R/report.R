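#' Hierarchically clustered abundance heatmap
#'
#' Clusters samples and taxa of a normalised abundance matrix
#' (Euclidean distance on `log1p` values, average linkage) and draws a
#' heatmap with group and batch annotation bars. The interesting failure mode
#' it visualises: samples organising by processing batch rather than by study
#' group.
#'
#' @param x A normalised [taxon_matrix()].
#' @param file Optional output file (pdf/png, by extension).
#' @return A list: `sample_order`, `taxon_order` (leaf orders), the two
#'   `hclust` objects (`NULL` when fewer than 3 items), and `file`.
#' @export
cluster_heatmap <- function(x, file = NULL) {
  stopifnot(inherits(x, "taxon_matrix"))
  if (!x$normalized) stop("heatmap expects normalised abundances")
  m <- log1p(x$counts)
  hc_samples <- if (ncol(m) >= 3L) hclust(dist(t(m)), method = "average") else NULL
  hc_taxa <- if (nrow(m) >= 3L) hclust(dist(m), method = "average") else NULL
  sample_order <- if (is.null(hc_samples)) seq_len(ncol(m)) else hc_samples$order
  taxon_order <- if (is.null(hc_taxa)) seq_len(nrow(m)) else hc_taxa$order
  if (!is.null(file) && nrow(m) >= 2L && ncol(m) >= 2L) {
    ann <- data.frame(group = x$samples$group,
                      batch = factor(x$samples$batch),
                      row.names = x$samples$sample_id)
    pheatmap::pheatmap(
      m,
      cluster_rows = if (is.null(hc_taxa)) FALSE else hc_taxa,
      cluster_cols = if (is.null(hc_samples)) FALSE else hc_samples,
      annotation_col = ann, show_colnames = ncol(m) <= 60,
      show_rownames = nrow(m) <= 60, filename = file, silent = TRUE)
  }
  list(sample_order = colnames(m)[sample_order],
       taxon_order = rownames(m)[taxon_order],
       hclust_samples = hc_samples, hclust_taxa = hc_taxa, file = file)
}

#' PCA of normalised abundances with batch/group annotation
#'
#' Principal component analysis of samples on `log1p` normalised abundances,
#' each taxon centred and unit-scaled (zero-variance taxa dropped). Component
#' signs are fixed so that each component's largest-magnitude taxon loading
#' is positive, making coordinates reproducible. The plot colours samples by
#' batch, shapes them by study group, and joins re-sequenced pairs with
#' dashed lines.
#'
#' @param x A normalised [taxon_matrix()] with at least 3 samples.
#' @param file Optional output figure path.
#' @param n_components Components to return (>= 2).
#' @return A list: `coordinates` (data frame of sample scores + metadata),
#'   `variance_explained`, `file`.
#' @export
pca_plot <- function(x, file = NULL, n_components = 2L) {
  stopifnot(inherits(x, "taxon_matrix"), ncol(x$counts) >= 3L)
  if (!x$normalized) stop("PCA expects normalised abundances")
  m <- log1p(x$counts)
  keep <- apply(m, 1L, stats::sd) > 0
  coords <- NULL
  varex <- numeric()
  if (sum(keep) >= 1L) {
    pc <- prcomp(t(m[keep, , drop = FALSE]), center = TRUE, scale. = TRUE)
    k <- min(n_components, ncol(pc$x))
    flip <- vapply(seq_len(k), function(j) {
      load <- pc$rotation[, j]
      sign(load[which.max(abs(load))])
    }, numeric(1))
    scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
    varex <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
    coords <- as.data.frame(scores)
  } else {
    # all-constant matrix: defined zero-variance handling
    coords <- data.frame(PC1 = rep(0, ncol(m)), PC2 = rep(0, ncol(m)))
    varex <- c(0, 0)
  }
  coords$sample_id <- x$samples$sample_id
  coords$group <- x$samples$group
  coords$batch <- factor(x$samples$batch)
  coords$replicate_of <- x$samples$replicate_of
  if (!is.null(file)) .pca_figure(coords, varex, file)
  list(coordinates = coords, variance_explained = varex, file = file)
}

.pca_figure <- function(coords, varex, file) {
  seg <- coords[!is.na(coords$replicate_of), , drop = FALSE]
  if (nrow(seg)) {
    i <- match(seg$replicate_of, coords$sample_id)
    ok <- !is.na(i)
    seg <- cbind(seg[ok, , drop = FALSE],
                 xend = coords$PC1[i[ok]], yend = coords$PC2[i[ok]])
  }
  g <- ggplot2::ggplot(coords, ggplot2::aes(x = PC1, y = PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = batch, shape = group),
                        size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * varex[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * varex[2]),
      colour = "batch", shape = "group") +
    ggplot2::theme_bw()
  if (nrow(seg)) {
    g <- g + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(xend = xend, yend = yend),
      linetype = "dashed", linewidth = 0.3, colour = "grey40")
  }
  ggplot2::ggsave(file, g, width = 7, height = 5)
  invisible(file)
}

#' Pipeline configuration
#'
#' @param out_dir Output directory for reports and figures.
#' @param seed Master seed, propagated to every stochastic step.
#' @param sim A [sim_config()] describing the synthetic inputs (its own seed
#'   is overridden by `seed`).
#' @param filter A [filter_config()].
#' @param glm A [glm_config()].
#' @param presence_threshold Presence cut-off for the contamination screen.
#' @param audit_taxon Taxon for the paired-read audit stage.
#' @param qc_sample_pairs Read pairs simulated for the QC stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("plasmascreen_"), seed = 1L,
                            sim = sim_config(seed = seed),
                            filter = filter_config(), glm = glm_config(),
                            presence_threshold = 1L,
                            audit_taxon = "Borrelia",
                            qc_sample_pairs = 2000L) {
  sim$seed <- as.integer(seed)
  sim$n_read_pairs <- as.integer(qc_sample_pairs)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 filter = filter, glm = glm,
                 presence_threshold = as.integer(presence_threshold),
                 audit_taxon = audit_taxon),
            class = "pipeline_config")
}

#' Run the full screening pipeline on synthetic data
#'
#' Executes every stage in order — read QC on simulated tagged reads, count
#' simulation and rollup through per-read assignments, normalisation,
#' negative-control overlap screening, duplicate-sample removal, group/batch
#' regression with classification, a paired-read audit of a planted
#' low-abundance taxon call, and the clustering/PCA figures — and writes a
#' single JSON summary plus per-stage outputs under `config$out_dir`. The
#' summary is fully deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also written to `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    message(msg)
    cat(msg, "\n", file = log_file, append = TRUE)
  }

  logf("read QC: simulating %d pairs", config$sim$n_read_pairs)
  sim_r <- simulate_reads(config$sim, sample_ids = "QC1")
  qc <- run_qc(sim_r$reads, config$filter)
  write_qc_report(qc$report,
                  tsv = file.path(config$out_dir, "qc_attrition.tsv"),
                  json = file.path(config$out_dir, "qc_attrition.json"))

  logf("profiling: simulating counts (%d taxa, %d samples)",
       config$sim$n_taxa, sum(config$sim$n_per_group) + sum(config$sim$n_resequenced))
  sim_c <- simulate_counts(config$sim)
  asg <- simulate_assignments(sim_c, config$sim, n_host_reads = 50L)
  tm <- build_count_matrix(subtract_host(asg$assignments), sim_c$metadata,
                           rank = config$sim$rank)
  norm <- normalize_counts(tm)
  write_taxon_matrix(tm, file.path(config$out_dir, "counts_raw.tsv"))

  logf("contamination screen (presence >= %d)", config$presence_threshold)
  ov <- negcontrol_overlap(tm, config$presence_threshold)
  flags <- flag_contaminants(ov)
  write.table(flags, file.path(config$out_dir, "contaminant_flags.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  logf("group/batch regression")
  dedup <- drop_duplicate_samples(tm, seed = config$seed)
  fit <- fit_taxon_glm(dedup, config$glm)
  fit <- classify_taxa(fit, flags, config$glm)
  write.table(as.data.frame(fit), file.path(config$out_dir, "regression_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  logf("paired-read audit of %s", config$audit_taxon)
  fx <- plant_audit_fixture(config$audit_taxon, seed = config$seed)
  cs <- pair_concordance(fx$assignments, config$audit_taxon, fx$confirm)
  verdict <- concordance_report(cs, n_samples_total = ncol(tm$counts))

  logf("figures")
  hm <- cluster_heatmap(norm, file.path(config$out_dir, "heatmap.pdf"))
  pca <- pca_plot(norm, file.path(config$out_dir, "pca.pdf"))

  cls <- table(factor(fit$classification,
                      levels = c("group_only", "batch_only", "both", "neither")))
  summary <- list(
    seed = config$seed,
    qc = list(input_pairs = qc$report$input_pairs,
              surviving_pairs = qc$report$surviving_pairs,
              filtered_read_count = qc$report$filtered_read_count,
              removed = as.list(qc$report$removed)),
    profile = list(rank = tm$rank, n_taxa = nrow(tm$counts),
                   n_samples = ncol(tm$counts)),
    contamination = list(n_total = ov$n_total, n_negctrl = ov$n_negctrl,
                         overlap_pct = ov$pct),
    inference = list(m_tested = attr(fit, "m_tested"),
                     classification = as.list(cls)),
    audit = list(taxon = cs$taxon, total_reads = cs$total_reads,
                 concordant_pairs = cs$concordant_pairs,
                 confirmed_reads = cs$confirmed_reads,
                 verdict = verdict$verdict),
    pca_variance = pca$variance_explained
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
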