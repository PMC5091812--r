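study_layout <- function() {
  data.frame(
    sample_id = sprintf("S%02d", 1:74),
    group = rep(c("CFS", "Healthy", "ADCLS", "SLE"), c(25, 25, 13, 11)),
    batch = rep_len(1:3, 74), filtered_read_count = 1e6,
    control = "none", replicate_of = NA_character_, stringsAsFactors = FALSE)
}

test_that("constant counts with equal offsets show no group or batch signal", {
  md <- study_layout()
  m <- matrix(7L, 3, 74, dimnames = list(c("t1", "t2", "t3"), md$sample_id))
  fit <- fit_taxon_glm(taxon_matrix(m, md))
  expect_true(all(fit$group_p > 0.99))
  expect_true(all(fit$batch_p > 0.99))
  fit <- classify_taxa(fit)
  expect_true(all(fit$classification == "neither"))
})

test_that("bonferroni flags implement p < alpha/m and ignore input order", {
  expect_true(bonferroni_flags(1e-4, m = 10, alpha = 0.05))
  expect_false(bonferroni_flags(0.006, m = 10, alpha = 0.05))
  p <- c(1e-5, 0.2, 0.004, NA, 0.049)
  perm <- c(3, 1, 5, 2, 4)
  expect_identical(bonferroni_flags(p, m = 4, alpha = 0.05)[perm],
                   bonferroni_flags(p[perm], m = 4, alpha = 0.05))
})

test_that("a planted batch-3 effect is detected as batch-only, on the batch-3 contrast", {
  cfg <- sim_config(seed = 41, n_taxa = 100, n_batch_effect_taxa = 8,
                    batch_effect_fold = 10, batch_effect_sd = 0,
                    n_group_effect_taxa = 0)
  sim <- simulate_counts(cfg)
  tm <- drop_duplicate_samples(sim$matrix, seed = 41)
  fit <- classify_taxa(fit_taxon_glm(tm))
  planted <- sim$truth$batch_effect_taxa
  got <- fit[match(planted, fit$taxon), ]
  expect_true(all(got$batch_sig))
  expect_false(any(got$group_sig))
  expect_true(all(got$classification == "batch_only"))
  # the signal localises on the batch-3 Wald contrast
  w <- wald_level_contrasts(fit)
  w3 <- w[w$taxon %in% planted & w$level == "3", ]
  w2 <- w[w$taxon %in% planted & w$level == "2", ]
  expect_true(all(w3$significant))
  expect_true(all(w3$estimate > 0))
  expect_gt(mean(!w2$significant), 0.8)
})

test_that("a diffuse group shift can be jointly significant with no single contrast", {
  # all three comparison groups elevated ~1.3x vs reference: each Wald
  # contrast is unconvincing alone but the 3-df joint test sees the pattern
  # opposite modest shifts in two case groups: the pairwise difference doubles
  # inside the joint quadratic form while each contrast against the reference
  # stays unconvincing on its own
  md <- study_layout()
  found <- FALSE
  for (seed in 1:30) {
    for (d in c(0.2, 0.25, 0.3)) {
      set.seed(seed)
      delta <- ifelse(md$group == "CFS", d,
                      ifelse(md$group == "ADCLS", -d, 0))
      y <- rnbinom(74, mu = 50 * exp(delta), size = 1 / 0.1)
      m <- matrix(as.integer(y), 1, 74, dimnames = list("tx", md$sample_id))
      fit <- fit_taxon_glm(taxon_matrix(m, md))
      w <- wald_level_contrasts(fit)
      wg <- w[w$factor == "group", ]
      if (!is.na(fit$group_p) && fit$group_p < 0.05 && all(wg$p > 0.05)) {
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
})

test_that("zero coefficients give Wald p of 1", {
  md <- study_layout()[1:8, ]
  md$group <- rep(c("Healthy", "CFS"), 4)
  md$batch <- rep(1:2, each = 4)
  # both groups see the same values {4, 6}, so the group effect is exactly 0
  # while residual variation keeps the dispersion positive
  m <- matrix(c(4L, 4L, 6L, 6L, 4L, 4L, 6L, 6L), 1, 8,
              dimnames = list("tx", md$sample_id))
  fit <- fit_taxon_glm(taxon_matrix(m, md), glm_config(min_samples_present = 1))
  w <- wald_level_contrasts(fit)
  cfsp <- w$p[w$factor == "group" & w$level == "CFS"]
  expect_equal(w$estimate[w$factor == "group" & w$level == "CFS"], 0,
               tolerance = 1e-8)
  expect_equal(cfsp, 1, tolerance = 1e-6)
})

test_that("p-values are invariant to jointly rescaling a sample's counts and denominator", {
  cfg <- sim_config(seed = 3, n_taxa = 60, n_batch_effect_taxa = 5,
                    batch_effect_fold = 10, batch_effect_sd = 0)
  sim <- simulate_counts(cfg)
  tm <- drop_duplicate_samples(sim$matrix, seed = 3)
  fit1 <- fit_taxon_glm(tm)
  cts <- tm$counts; md <- tm$samples
  cts[, 5] <- cts[, 5] * 10L
  md$filtered_read_count[5] <- md$filtered_read_count[5] * 10L
  fit2 <- fit_taxon_glm(taxon_matrix(cts, md, rank = "genus"))
  expect_lt(max(abs(fit2$group_p - fit1$group_p), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(fit2$batch_p - fit1$batch_p), na.rm = TRUE), 1e-6)
  pcols <- grep("_p$", names(fit1), value = TRUE)
  for (pc in pcols) expect_lt(max(abs(fit2[[pc]] - fit1[[pc]]), na.rm = TRUE), 1e-6)
})

test_that("under a deeply sequenced global null, group p-values are near-uniform", {
  cfg <- sim_config(seed = 77, n_taxa = 500, n_contaminant_taxa = 0,
                    n_batch_effect_taxa = 0, batch_effect_sd = 0,
                    n_group_effect_taxa = 0, library_size_mean = 1.7e7,
                    n_per_group = c(CFS = 25, Healthy = 25, ADCLS = 13, SLE = 11),
                    n_resequenced = c(CFS = 0, Healthy = 0, ADCLS = 0, SLE = 0))
  sim <- simulate_counts(cfg)
  fit <- fit_taxon_glm(sim$matrix)
  p <- fit$group_p[!is.na(fit$group_p)]
  expect_gt(length(p), 450)
  ks <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  expect_lt(unname(ks), 0.1)
})

test_that("single-level factors are dropped with a warning, not an error", {
  md <- study_layout()
  md$batch <- 1L
  m <- matrix(rpois(74 * 2, 20), 2, 74,
              dimnames = list(c("t1", "t2"), md$sample_id))
  expect_warning(fit <- fit_taxon_glm(taxon_matrix(m, md)), "single level")
  expect_true(all(is.na(fit$batch_p)))
  expect_true(all(!is.na(fit$group_p)))
})

test_that("planted both/batch-only structure is classified exactly at generous folds", {
  cfg <- sim_config(seed = 55, n_taxa = 100, n_contaminant_taxa = 0,
                    n_batch_effect_taxa = 42, n_group_effect_taxa = 6,
                    batch_effect_fold = 10, group_effect_fold = 10,
                    batch_effect_sd = 0)
  sim <- simulate_counts(cfg)
  tm <- drop_duplicate_samples(sim$matrix, seed = 55)
  fit <- classify_taxa(fit_taxon_glm(tm))
  both <- fit$taxon[which(fit$classification == "both")]
  batch_only <- fit$taxon[which(fit$classification == "batch_only")]
  expect_setequal(both, sim$truth$group_effect_taxa)
  expect_setequal(batch_only,
                  setdiff(sim$truth$batch_effect_taxa, sim$truth$group_effect_taxa))
  expect_length(both, 6L)
  expect_length(batch_only, 36L)
  expect_true(all(fit$classification[!fit$taxon %in% sim$truth$batch_effect_taxa]
                  %in% c("neither", NA)))
})

test_that("contaminant-flagged group hits are annotated as likely artefacts", {
  cfg <- sim_config(seed = 61, n_taxa = 40, n_contaminant_taxa = 40,
                    n_batch_effect_taxa = 6, n_group_effect_taxa = 3,
                    batch_effect_fold = 10, group_effect_fold = 10,
                    batch_effect_sd = 0)
  sim <- simulate_counts(cfg)
  flags <- flag_contaminants(negcontrol_overlap(sim$matrix))
  tm <- drop_duplicate_samples(sim$matrix, seed = 61)
  fit <- classify_taxa(fit_taxon_glm(tm), flags)
  hits <- fit[fit$classification %in% c("both", "group_only") &
                fit$contaminant_flag %in% c("negctrl", "known", "both"), ]
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$annotation == "likely contamination/batch artifact"))
})
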