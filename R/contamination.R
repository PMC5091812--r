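#' Overlap between study-sample taxa and negative-control taxa
#'
#' The central sanity check for low-biomass metagenomics: how much of what
#' was detected anywhere is also present in the plasma-free negative
#' extraction controls, and is therefore suspect as reagent or handling
#' contamination? A taxon is "present" in a sample when its raw count is at
#' least `presence_threshold`.
#'
#' @param x A raw [taxon_matrix()] whose metadata marks negative controls
#'   (`control == "negative"`).
#' @param presence_threshold Minimum raw count for presence (default 1).
#' @return An object of class `overlap_stats`: `rank`, `n_total` (taxa
#'   present in at least one sample), `n_negctrl` (of those, present in at
#'   least one negative control), `pct` (percentage, 1 decimal), and `taxa`
#'   (per-taxon data frame with `observed` and `in_negctrl`).
#' @examples
#' sim <- simulate_counts(sim_config(seed = 5, n_taxa = 28,
#'                                   n_contaminant_taxa = 20))
#' negcontrol_overlap(sim$matrix)
#' @export
negcontrol_overlap <- function(x, presence_threshold = 1L) {
  stopifnot(inherits(x, "taxon_matrix"), presence_threshold >= 1)
  if (x$normalized) stop("overlap screen runs on raw counts")
  neg <- x$samples$control == "negative"
  if (!any(neg))
    stop("no negative-control samples in metadata: contamination cannot be ",
         "assessed without plasma-free negative controls")
  present <- x$counts >= presence_threshold
  observed <- rowSums(present) > 0
  in_neg <- rowSums(present[, neg, drop = FALSE]) > 0
  n_total <- sum(observed)
  n_overlap <- sum(observed & in_neg)
  structure(list(
    rank = x$rank, presence_threshold = presence_threshold,
    n_total = n_total, n_negctrl = n_overlap,
    pct = if (n_total) round(100 * n_overlap / n_total, 1) else 0,
    taxa = data.frame(taxon = rownames(x$counts), observed = observed,
                      in_negctrl = in_neg, row.names = NULL,
                      stringsAsFactors = FALSE)
  ), class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("Negative-control overlap (%s level, presence >= %d read%s):\n",
              x$rank, x$presence_threshold,
              if (x$presence_threshold > 1) "s" else ""))
  cat(sprintf("  %d of %d taxa (%.1f%%) present in >= 1 plasma-free negative control\n",
              x$n_negctrl, x$n_total, x$pct))
  invisible(x)
}

#' The shipped catalog of commonly reported reagent contaminants
#'
#' Genera repeatedly reported in kit/reagent contamination surveys of
#' low-biomass sequencing. The catalog is a plain text file
#' (`extdata/known_contaminants.txt`, one genus per line, `#` comments) that
#' users can edit or replace; it is data, not hard-coded science.
#'
#' @param file Path to a catalog file; defaults to the shipped one.
#' @return Character vector of taxon names.
#' @export
known_contaminants <- function(file = system.file("extdata", "known_contaminants.txt",
                                                  package = "plasmascreen")) {
  x <- readLines(file, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Flag putative contaminant taxa
#'
#' Combines the negative-control evidence with a catalog of known reagent
#' contaminants: each observed taxon is flagged `"negctrl"` (present in a
#' negative control), `"known"` (in the catalog), `"both"`, or `"clean"`.
#'
#' @param stats An `overlap_stats` object from [negcontrol_overlap()].
#' @param known Character vector of catalog taxa (default the shipped
#'   [known_contaminants()] list).
#' @return The per-taxon data frame from `stats` with a `flag` column.
#' @export
flag_contaminants <- function(stats, known = known_contaminants()) {
  stopifnot(inherits(stats, "overlap_stats"))
  df <- stats$taxa
  in_cat <- df$taxon %in% known
  df$flag <- ifelse(df$in_negctrl & in_cat, "both",
                    ifelse(df$in_negctrl, "negctrl",
                           ifelse(in_cat, "known", "clean")))
  df
}
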