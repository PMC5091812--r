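test_that("identical samples end up as adjacent leaves in the heatmap clustering", {
  md <- data.frame(sample_id = c("A", "B", "C", "D"),
                   group = c("CFS", "CFS", "Healthy", "Healthy"),
                   batch = c(1L, 1L, 2L, 2L), filtered_read_count = 1e6,
                   control = "none", replicate_of = NA_character_,
                   stringsAsFactors = FALSE)
  set.seed(1)
  m <- matrix(rpois(4 * 4, 40), 4, 4,
              dimnames = list(sprintf("t%d", 1:4), md$sample_id))
  m[, "B"] <- m[, "A"]
  hm <- cluster_heatmap(normalize_counts(taxon_matrix(m, md)))
  pos <- match(c("A", "B"), hm$sample_order)
  expect_identical(abs(diff(pos)), 1L)
})

test_that("planted batch structure separates batch 3 into a coherent subtree", {
  cfg <- sim_config(seed = 71, n_taxa = 60, n_batch_effect_taxa = 30,
                    batch_effect_fold = 10, batch_effect_sd = 0.2)
  sim <- simulate_counts(cfg)
  norm <- normalize_counts(sim$matrix)
  f <- file.path(tempdir(), "hm.pdf")
  hm <- cluster_heatmap(norm, file = f)
  expect_true(file.exists(f))
  # cut the sample dendrogram in two; batch-3 study samples should
  # concentrate in one branch
  cl <- stats::cutree(hm$hclust_samples, k = 2)
  b3 <- sim$metadata$sample_id[sim$metadata$batch == 3 &
                                 sim$metadata$control == "none"]
  major <- names(which.max(table(cl[b3])))
  purity <- mean(cl[b3] == as.integer(major))
  expect_gte(purity, 0.9)
})

test_that("a single-sample matrix does not crash the clustering stage", {
  md <- data.frame(sample_id = "solo", group = "CFS", batch = 1L,
                   filtered_read_count = 1e6, control = "none",
                   replicate_of = NA_character_, stringsAsFactors = FALSE)
  m <- matrix(1:3, 3, 1, dimnames = list(c("a", "b", "c"), "solo"))
  hm <- cluster_heatmap(normalize_counts(taxon_matrix(m, md)))
  expect_identical(hm$sample_order, "solo")
})

test_that("PCA coordinates are reproducible and batch beats group when batch dominates", {
  cfg <- sim_config(seed = 81, n_taxa = 60, n_batch_effect_taxa = 30,
                    batch_effect_fold = 10, batch_effect_sd = 0.3)
  sim <- simulate_counts(cfg)
  norm <- normalize_counts(sim$matrix)
  p1 <- pca_plot(norm)
  p2 <- pca_plot(norm)
  expect_equal(p1$coordinates$PC1, p2$coordinates$PC1, tolerance = 1e-9)
  expect_equal(p1$coordinates$PC2, p2$coordinates$PC2, tolerance = 1e-9)

  sil <- function(lab, xy) {
    # mean silhouette width on PC1-2
    d <- as.matrix(dist(xy))
    vapply(seq_len(nrow(xy)), function(i) {
      own <- mean(d[i, lab == lab[i] & seq_len(nrow(xy)) != i])
      oth <- min(vapply(setdiff(unique(lab), lab[i]),
                        function(l) mean(d[i, lab == l]), numeric(1)))
      (oth - own) / max(own, oth)
    }, numeric(1))
  }
  study <- sim$metadata$control == "none"
  xy <- as.matrix(p1$coordinates[study, c("PC1", "PC2")])
  expect_gt(mean(sil(sim$metadata$batch[study], xy)),
            mean(sil(sim$metadata$group[study], xy)))
})

test_that("a constant matrix yields defined zero-variance PCA output", {
  md <- data.frame(sample_id = c("A", "B", "C"), group = "CFS", batch = 1L,
                   filtered_read_count = 1e6, control = "none",
                   replicate_of = NA_character_, stringsAsFactors = FALSE)
  m <- matrix(5L, 2, 3, dimnames = list(c("x", "y"), md$sample_id))
  p <- pca_plot(normalize_counts(taxon_matrix(m, md)))
  expect_identical(p$coordinates$PC1, rep(0, 3))
})

test_that("the end-to-end pipeline is deterministic and complete", {
  cfg_small <- sim_config(seed = 5, n_taxa = 30, n_contaminant_taxa = 12,
                          n_batch_effect_taxa = 4,
                          n_per_group = c(CFS = 8, Healthy = 8, ADCLS = 5,
                                          SLE = 5, NegControl = 3, PosControl = 1),
                          n_resequenced = c(CFS = 2, Healthy = 2, ADCLS = 0, SLE = 0))
  d1 <- file.path(tempdir(), "pipe1"); d2 <- file.path(tempdir(), "pipe2")
  s1 <- suppressMessages(run_pipeline(pipeline_config(
    out_dir = d1, seed = 5, sim = cfg_small, qc_sample_pairs = 400)))
  s2 <- suppressMessages(run_pipeline(pipeline_config(
    out_dir = d2, seed = 5, sim = cfg_small, qc_sample_pairs = 400)))
  expect_identical(s1, s2)
  expect_identical(jsonlite::read_json(file.path(d1, "summary.json")),
                   jsonlite::read_json(file.path(d2, "summary.json")))
  expect_true(s1$qc$surviving_pairs > 0)
  expect_true(s1$contamination$n_total > 0)
  expect_identical(s1$audit$verdict, "unsupported")
  expect_true(file.exists(file.path(d1, "heatmap.pdf")))
  expect_true(file.exists(file.path(d1, "pca.pdf")))
  expect_true(file.exists(file.path(d1, "regression_results.tsv")))
})

test_that("the command-line wrapper answers a cohort-test query", {
  cli <- system.file("scripts", "plasmascreen-cli.R", package = "plasmascreen")
  expect_true(nzchar(cli))
  tab <- tempfile(fileext = ".tsv")
  writeLines(c("group\tMale\tFemale", "Healthy\t4\t21", "SLE\t0\t11"), tab)
  out <- suppressWarnings(system2("Rscript", c(cli, "cohort-test", "--table", tab),
                                  stdout = TRUE, stderr = TRUE))
  expect_match(paste(out, collapse = ""), "0.290", fixed = TRUE)
})

test_that("the pipeline fails early and clearly on an invalid configuration", {
  cfg <- pipeline_config(seed = 1)
  cfg$sim <- "not a config"
  expect_error(suppressMessages(run_pipeline(cfg)))
})
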