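#' Configuration for per-taxon group/batch regression
#'
#' @param alpha Family-wise significance level (Bonferroni-corrected across
#'   tested taxa).
#' @param family Working count family. `"quasi-quadratic"` (default) is a
#'   quasi-likelihood family with log link and variance proportional to
#'   `mu^2` (constant coefficient of variation). Its estimating equations are
#'   invariant to rescaling a sample's counts together with its exposure
#'   denominator — the property one wants when counts are compared across
#'   libraries of very different depth — and its F-tests are well calibrated
#'   on negative-binomially overdispersed counts of moderate abundance.
#'   `"quasi-poisson"` (variance proportional to `mu`) is available for
#'   comparison but is anticonservative under strong overdispersion.
#' @param min_samples_present Test a taxon only if it has a non-zero count in
#'   at least this many samples (default 5). Taxa seen in only a handful of
#'   samples cannot support a six-parameter model: their fits are
#'   quasi-separated and produce spurious significance, so they are screened
#'   out the way differential-abundance tools filter low-count features.
#' @param reference_group,reference_batch Reference levels for contrasts.
#' @return An object of class `glm_config`.
#' @export
glm_config <- function(alpha = 0.05,
                       family = c("quasi-quadratic", "quasi-poisson"),
                       min_samples_present = 5L,
                       reference_group = "Healthy", reference_batch = "1") {
  family <- match.arg(family)
  stopifnot(alpha > 0, alpha < 1, min_samples_present >= 1L)
  structure(list(alpha = alpha, family = family,
                 min_samples_present = as.integer(min_samples_present),
                 reference_group = reference_group,
                 reference_batch = as.character(reference_batch)),
            class = "glm_config")
}

.glm_family <- function(config) {
  switch(config$family,
         "quasi-quadratic" = {
           fam <- quasi(link = "log", variance = "mu^2")
           # ratio-form unit deviance: depends on y/mu only, so deviances (and
           # hence F tests) are invariant to joint rescaling of a sample's
           # count and exposure; zero counts contribute zero deviance (the
           # gamma-type deviance is undefined at y = 0, and stats::quasi's
           # log(1/mu) patch would reintroduce scale dependence)
           fam$dev.resids <- function(y, mu, wt) {
             pmax(-2 * wt * (log(ifelse(y == 0, 1, y / mu)) - (y - mu) / mu), 0)
           }
           fam
         },
         "quasi-poisson" = quasipoisson())
}

#' Per-taxon multivariable regression on study group and sequencing batch
#'
#' For every eligible taxon fits the count model
#' `count ~ group + batch + offset(log(filtered_read_count))`
#' on the raw counts of the study samples (negative and positive controls are
#' excluded automatically; re-sequenced duplicates should have been removed
#' first with [drop_duplicate_samples()]). Joint significance of each factor
#' comes from a quasi-likelihood F-test comparing nested fits (3 df for four
#' study groups, `n_batches - 1` df for batch), with the dispersion estimated
#' from Pearson residuals of the full model. Per-level Wald contrasts against
#' the reference level use t statistics on the same dispersion.
#'
#' A factor with a single observed level is dropped with a warning (its joint
#' p-value is `NA`); a taxon whose fit fails to converge is reported with
#' `NA` p-values rather than raising an error.
#'
#' @param x A raw [taxon_matrix()].
#' @param config A [glm_config()].
#' @return A data frame of class `taxon_glm` with one row per tested taxon:
#'   `taxon`, `n_present`, `group_p`, `batch_p`, and per-level Wald columns
#'   `<factor>_<level>_est` / `_se` / `_p` (log-scale estimates vs the
#'   reference level). Attributes: `m_tested`, `alpha`, `family`,
#'   `residual_df`.
#' @export
fit_taxon_glm <- function(x, config = glm_config()) {
  stopifnot(inherits(x, "taxon_matrix"))
  if (x$normalized)
    stop("regression runs on raw counts with the filtered-read offset")
  md <- x$samples
  study <- md$control == "none"
  md <- md[study, , drop = FALSE]
  counts <- x$counts[, study, drop = FALSE]
  if (any(!is.na(md$replicate_of)))
    warning("re-sequenced duplicates are still present; ",
            "consider drop_duplicate_samples() first")

  grp <- factor(md$group)
  if (config$reference_group %in% levels(grp))
    grp <- stats::relevel(grp, config$reference_group)
  bat <- factor(as.character(md$batch))
  if (config$reference_batch %in% levels(bat))
    bat <- stats::relevel(bat, config$reference_batch)

  use_group <- nlevels(grp) > 1L
  use_batch <- nlevels(bat) > 1L
  if (!use_group) warning("study group has a single level and was dropped")
  if (!use_batch) warning("sequencing batch has a single level and was dropped")

  terms <- c(if (use_group) "grp", if (use_batch) "bat")
  X_full <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c("1", terms), collapse = "+"))),
    data = data.frame(grp = grp, bat = bat))
  X_nogrp <- if (use_group && use_batch) stats::model.matrix(~bat) else NULL
  X_nobat <- if (use_group && use_batch) stats::model.matrix(~grp) else NULL
  X_null <- stats::model.matrix(~1, data.frame(row.names = seq_len(nrow(md))))

  off <- log(md$filtered_read_count)
  fam <- .glm_family(config)
  n <- nrow(md)
  p_full <- ncol(X_full)
  df_res <- n - p_full
  grp_cols <- grep("^grp", colnames(X_full))
  bat_cols <- grep("^bat", colnames(X_full))

  eligible <- rowSums(counts > 0) >= config$min_samples_present
  taxa <- rownames(counts)[eligible]

  fit_one <- function(y) {
    # tight IRLS tolerance: p-values must be exactly invariant to rescaling a
    # sample's counts together with its denominator, so fits are converged to
    # machine precision rather than the looser default
    ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 200L)
    full <- glm.fit(X_full, y, family = fam, offset = off, control = ctrl)
    if (!full$converged || full$rank < p_full) return(NULL)
    pearson <- sum((y - full$fitted.values)^2 / fam$variance(full$fitted.values))
    phi <- pearson / df_res
    ftest <- function(X_red) {
      red <- glm.fit(X_red, y, family = fam, offset = off, control = ctrl)
      q <- p_full - ncol(X_red)
      ddev <- max(red$deviance - full$deviance, 0)
      # an (almost) perfectly fitted taxon carries no evidence; phi is a
      # squared coefficient of variation, so values below 1e-10 are numerical
      # residue of the IRLS, not dispersion
      if (!is.finite(phi) || phi < 1e-10) return(if (ddev < 1e-6) 1 else 0)
      pf(ddev / q / phi, q, df_res, lower.tail = FALSE)
    }
    group_p <- if (use_group && use_batch) ftest(X_nogrp)
               else if (use_group) ftest(X_null) else NA_real_
    batch_p <- if (use_group && use_batch) ftest(X_nobat)
               else if (use_batch) ftest(X_null) else NA_real_
    Rmat <- full$qr$qr[seq_len(p_full), seq_len(p_full), drop = FALSE]
    Rmat[lower.tri(Rmat)] <- 0
    cov_unscaled <- chol2inv(Rmat)
    se <- sqrt(diag(cov_unscaled) * phi)
    tval <- full$coefficients / se
    wald_p <- 2 * pt(-abs(tval), df_res)
    wald_p[!is.finite(tval)] <- 1        # 0/0: no estimate, no evidence
    if (is.finite(phi) && phi < 1e-10) wald_p[] <- 1
    list(group_p = group_p, batch_p = batch_p,
         est = full$coefficients, se = se, wald_p = wald_p)
  }

  lvl_cols <- c(
    if (use_group) paste0("group_", levels(grp)[-1L]),
    if (use_batch) paste0("batch_", levels(bat)[-1L])
  )
  coef_names <- c(if (use_group) paste0("grp", levels(grp)[-1L]),
                  if (use_batch) paste0("bat", levels(bat)[-1L]))

  out <- data.frame(taxon = taxa, n_present = rowSums(counts[taxa, , drop = FALSE] > 0),
                    group_p = NA_real_, batch_p = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (nm in lvl_cols) {
    out[[paste0(nm, "_est")]] <- NA_real_
    out[[paste0(nm, "_se")]] <- NA_real_
    out[[paste0(nm, "_p")]] <- NA_real_
  }
  for (i in seq_along(taxa)) {
    y <- counts[taxa[i], ]
    f <- tryCatch(suppressWarnings(fit_one(y)), error = function(e) NULL)
    if (is.null(f)) next
    out$group_p[i] <- f$group_p
    out$batch_p[i] <- f$batch_p
    idx <- match(coef_names, names(f$est))
    for (j in seq_along(lvl_cols)) {
      if (is.na(idx[j])) next
      out[[paste0(lvl_cols[j], "_est")]][i] <- f$est[idx[j]]
      out[[paste0(lvl_cols[j], "_se")]][i] <- f$se[idx[j]]
      out[[paste0(lvl_cols[j], "_p")]][i] <- f$wald_p[idx[j]]
    }
  }
  structure(out, m_tested = sum(!is.na(out$group_p) | !is.na(out$batch_p)),
            alpha = config$alpha, family = config$family, residual_df = df_res,
            class = c("taxon_glm", "data.frame"))
}

#' Bonferroni significance flags
#'
#' A p-value is flagged significant when `p < alpha / m`, the Bonferroni
#' family-wise criterion over the `m` tests actually performed.
#'
#' @param p Numeric vector of p-values.
#' @param m Number of tests in the family (default: non-`NA` entries of `p`).
#' @param alpha Family-wise level.
#' @return Logical vector (`NA` where `p` is `NA`).
#' @export
bonferroni_flags <- function(p, m = sum(!is.na(p)), alpha = 0.05) {
  stopifnot(m >= 1L, alpha > 0, alpha < 1)
  p < alpha / m
}

#' Per-level Wald contrasts in long format
#'
#' Unpacks the per-level Wald columns of a [fit_taxon_glm()] result into one
#' row per taxon and non-reference level, with a significance call at
#' `config$alpha` (unadjusted — these contrasts probe *which* level drives a
#' factor already declared significant jointly). The diagnostic pattern worth
#' watching for is a jointly significant factor none of whose single-level
#' contrasts is: the signal then lives in a combination of levels, a typical
#' signature of diffuse batch/contamination structure rather than one
#' biological group.
#'
#' @param results A `taxon_glm` data frame.
#' @param config The [glm_config()] used.
#' @return Data frame: `taxon`, `factor`, `level`, `estimate`, `se`, `p`,
#'   `significant`.
#' @export
wald_level_contrasts <- function(results, config = glm_config()) {
  stopifnot(inherits(results, "taxon_glm"))
  pcols <- grep("_(p)$", names(results), value = TRUE)
  pcols <- setdiff(pcols, c("group_p", "batch_p"))
  out <- do.call(rbind, lapply(pcols, function(pc) {
    base <- sub("_p$", "", pc)
    data.frame(taxon = results$taxon,
               factor = sub("_.*$", "", base),
               level = sub("^[a-z]+_", "", base),
               estimate = results[[paste0(base, "_est")]],
               se = results[[paste0(base, "_se")]],
               p = results[[pc]], stringsAsFactors = FALSE)
  }))
  out$significant <- !is.na(out$p) & out$p < config$alpha
  out[order(out$taxon, out$factor, out$level), , drop = FALSE]
}

#' Classify taxa as group-driven, batch-driven, both, or neither
#'
#' Applies Bonferroni flags (with `m` = taxa tested) to the joint group and
#' batch p-values and combines them into a four-way classification. When
#' contaminant flags from [flag_contaminants()] are supplied, taxa that are
#' group-significant *and* contaminant-flagged are annotated as likely
#' contamination/batch artefacts — the study-design warning this package
#' exists to make easy.
#'
#' @param results A `taxon_glm` data frame.
#' @param contaminants Optional data frame from [flag_contaminants()] (or any
#'   with `taxon` and `flag` columns).
#' @param config The [glm_config()] used.
#' @return `results` with columns `group_sig`, `batch_sig`, `classification`
#'   and (if contaminant flags given) `contaminant_flag`, `annotation`.
#' @export
classify_taxa <- function(results, contaminants = NULL, config = glm_config()) {
  stopifnot(inherits(results, "taxon_glm"))
  m <- attr(results, "m_tested")
  results$group_sig <- bonferroni_flags(results$group_p, m, config$alpha)
  results$batch_sig <- bonferroni_flags(results$batch_p, m, config$alpha)
  g <- !is.na(results$group_sig) & results$group_sig
  b <- !is.na(results$batch_sig) & results$batch_sig
  results$classification <- ifelse(g & b, "both",
                                   ifelse(g, "group_only",
                                          ifelse(b, "batch_only", "neither")))
  results$classification[is.na(results$group_p) & is.na(results$batch_p)] <- NA
  if (!is.null(contaminants)) {
    results$contaminant_flag <-
      contaminants$flag[match(results$taxon, contaminants$taxon)]
    suspect <- results$classification %in% c("both", "group_only") &
      results$contaminant_flag %in% c("negctrl", "known", "both")
    results$annotation <- ifelse(suspect, "likely contamination/batch artifact", "")
  }
  results
}
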