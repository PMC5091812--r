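#' Construct a taxon count matrix object
#'
#' The profiling container: a taxa x samples matrix of read counts at one
#' taxonomic rank, together with the sample metadata that downstream
#' statistics need (study group, batch, control role, the filtered-read
#' denominator, optional replicate links). Raw matrices hold non-negative
#' integers; [normalize_counts()] converts to reads-per-`scale` filtered
#' reads and flips the `normalized` flag.
#'
#' @param counts Numeric matrix, taxa in rows, samples in columns; column
#'   names must match `metadata$sample_id` (order is aligned automatically).
#' @param metadata Data frame with columns `sample_id`, `group`, `batch`,
#'   `filtered_read_count`, and optionally `control`
#'   ("none"/"negative"/"positive") and `replicate_of`.
#' @param rank "phylum" or "genus".
#' @param normalized,scale Normalisation state (set by [normalize_counts()]).
#' @return An object of class `taxon_matrix`.
#' @export
taxon_matrix <- function(counts, metadata, rank = c("genus", "phylum"),
                         normalized = FALSE, scale = NA_real_) {
  rank <- match.arg(rank)
  stopifnot(is.matrix(counts), is.data.frame(metadata),
            all(c("sample_id", "group", "batch", "filtered_read_count") %in%
                  names(metadata)))
  if (is.null(colnames(counts)) || (nrow(counts) > 0L && is.null(rownames(counts))))
    stop("counts must carry taxon row names and sample column names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (!setequal(colnames(counts), metadata$sample_id))
    stop("counts columns and metadata sample_id do not match")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (any(is.na(metadata$group)) || any(is.na(metadata$batch)))
    stop("group and batch must be non-missing for every sample")
  if (!"control" %in% names(metadata)) metadata$control <- "none"
  if (!"replicate_of" %in% names(metadata)) metadata$replicate_of <- NA_character_
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, samples = metadata, rank = rank,
                 normalized = normalized, scale = scale),
            class = "taxon_matrix")
}

#' @export
print.taxon_matrix <- function(x, ...) {
  cat("taxon_matrix: ", nrow(x$counts), " ", x$rank, "-level taxa x ",
      ncol(x$counts), " samples (",
      if (x$normalized) paste0("normalized, scale ", format(x$scale)) else "raw",
      ")\n", sep = "")
  grp <- table(x$samples$group)
  cat("  groups: ", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.taxon_matrix <- function(x) dim(x$counts)

#' Build a count matrix from a per-read assignment table
#'
#' Rolls read-level taxon assignments up to a sample x taxon count matrix at
#' the requested rank. Each assigned read contributes one count to its
#' sample/taxon cell. Reads assigned to the reserved `HOST` taxon and rows at
#' other ranks are excluded (see [subtract_host()]).
#'
#' @param assignments Data frame with columns `read_id`, `sample_id`, `mate`,
#'   `taxon`, `rank`.
#' @param metadata Sample metadata (see [taxon_matrix()]); every sample in
#'   `assignments` must appear here. Samples with no assigned reads get
#'   all-zero columns.
#' @param rank The rank to roll up ("phylum" or "genus").
#' @return A raw [taxon_matrix()].
#' @export
build_count_matrix <- function(assignments, metadata, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  stopifnot(is.data.frame(assignments),
            all(c("sample_id", "taxon", "rank") %in% names(assignments)))
  unknown <- setdiff(unique(assignments$sample_id), metadata$sample_id)
  if (length(unknown))
    stop("assignments reference sample id(s) absent from metadata: ",
         paste(head(unknown, 5L), collapse = ", "))
  a <- assignments[assignments$rank == rank & !is.na(assignments$taxon) &
                     assignments$taxon != "HOST", , drop = FALSE]
  taxa <- sort(unique(a$taxon))
  counts <- matrix(0L, nrow = length(taxa), ncol = nrow(metadata),
                   dimnames = list(taxa, metadata$sample_id))
  if (nrow(a)) {
    tab <- table(factor(a$taxon, levels = taxa),
                 factor(a$sample_id, levels = metadata$sample_id))
    counts[] <- as.integer(tab)
  }
  taxon_matrix(counts, metadata, rank = rank)
}

#' Drop host-assigned reads from an assignment table
#'
#' Stand-in for alignment-based host subtraction: real pipelines remove
#' host reads by mapping against the host genome; here host reads are
#' represented by the reserved taxon label `HOST` and simply dropped.
#'
#' @param assignments A per-read assignment table.
#' @return The table without `HOST` rows.
#' @export
subtract_host <- function(assignments) {
  assignments[is.na(assignments$taxon) | assignments$taxon != "HOST", ,
              drop = FALSE]
}

#' Normalise counts by the filtered-read denominator
#'
#' Divides each sample's counts by its `filtered_read_count` (the number of
#' quality-filtered reads before host subtraction) and multiplies by `scale`;
#' the default `1e6` yields counts per million filtered reads. Normalising an
#' already-normalised matrix is an error, as is a zero denominator.
#'
#' @param x A raw [taxon_matrix()].
#' @param scale Scale factor (default counts per million).
#' @return A normalised `taxon_matrix`.
#' @export
normalize_counts <- function(x, scale = 1e6) {
  stopifnot(inherits(x, "taxon_matrix"))
  if (x$normalized) stop("matrix is already normalized")
  den <- x$samples$filtered_read_count
  if (any(is.na(den) | den <= 0))
    stop("non-positive filtered_read_count for sample(s): ",
         paste(x$samples$sample_id[is.na(den) | den <= 0], collapse = ", "))
  x$counts <- sweep(x$counts, 2L, den, "/") * scale
  x$normalized <- TRUE
  x$scale <- scale
  x
}

#' Randomly drop re-sequenced duplicates
#'
#' Samples sequenced more than once are linked by `replicate_of` in the
#' metadata (child points at parent). For every replicate set exactly one
#' member is retained, chosen by a seeded uniform draw, so the choice is
#' reproducible.
#'
#' @param x A [taxon_matrix()].
#' @param seed Integer seed for the draw.
#' @return `x` restricted to the retained samples.
#' @export
drop_duplicate_samples <- function(x, seed = 1L) {
  stopifnot(inherits(x, "taxon_matrix"))
  md <- x$samples
  parent <- ifelse(is.na(md$replicate_of), md$sample_id, md$replicate_of)
  keep <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(md$sample_id, parent), function(set) {
      if (length(set) == 1L) set else sample(set, 1L)
    }), use.names = FALSE)
  })
  sel <- md$sample_id %in% keep
  x$counts <- x$counts[, sel, drop = FALSE]
  x$samples <- md[sel, , drop = FALSE]
  x$samples$replicate_of <- NA_character_   # links are resolved now
  rownames(x$samples) <- NULL
  x
}

#' Write / read a taxon matrix as TSV (taxa rows x sample columns)
#'
#' @param x A `taxon_matrix`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_taxon_matrix <- function(x, file) {
  stopifnot(inherits(x, "taxon_matrix"))
  df <- data.frame(taxon = rownames(x$counts), x$counts, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
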