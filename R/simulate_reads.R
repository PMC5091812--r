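#' Simulate paired-end reads with planted, truth-labelled defects
#'
#' Generates Illumina-style 100 bp read pairs for one or more samples. Each
#' pair is either clean or carries exactly one planted defect drawn from
#' `config$defect_rates`:
#'
#' \describe{
#'   \item{chastity_fail}{header comment carries the CASAVA `Y` (failed) flag
#'     on one mate}
#'   \item{homopolymer}{a single-base run of 21-26 bases spliced into one mate}
#'   \item{contains_n}{1-3 `N` calls}
#'   \item{lowq_half}{first-half qualities degraded so that fewer than 2/3 of
#'     the first `floor(L/2)` bases reach Q30}
#'   \item{solb_full}{the full 18-mer Sol-B primer spliced in at offset >= 20}
#'   \item{solb_tail}{the read begins with a proper suffix (1-17 nt) of the
#'     Sol-B primer, emulating an undigested B-tail}
#'   \item{short}{one mate truncated below 70 bp}
#'   \item{duplicate_pair}{an exact sequence copy of an earlier clean pair}
#'   \item{revcomp_duplicate}{reverse complement of an earlier clean pair with
#'     mates swapped}
#'   \item{low_complexity}{a 40-60 bp dinucleotide repeat spliced into one
#'     mate (DUST score far above threshold)}
#' }
#'
#' Clean reads violate no filter rule: uniform random sequence (homopolymer
#' runs of >20 or chance primer hits are vanishingly rare at 100 bp), all
#' base qualities Q35-40, full length, chastity pass. Reads that only carry a
#' B-tail are trimmed by QC, not removed, so truth marks them as expected to
#' survive.
#'
#' @param config A [sim_config()]; `n_read_pairs`, `read_length`,
#'   `defect_rates` and `seed` are used.
#' @param sample_ids Character vector of sample names; each gets its own pair
#'   of mate files (when writing) and its own reads.
#' @param out_dir Optional directory; when given, `<sample>_R1.fastq[.gz]` /
#'   `_R2` files are written there.
#' @param gzip Write gzip-compressed FASTQ (only with `out_dir`).
#' @return A list with `reads` (the read table, see [read_fastq_pair()]),
#'   `truth` (one row per pair: `id`, `sample`, `defect`, `defect_mate`,
#'   `detail` = planted run/tail/length parameter, `source_id` for duplicates,
#'   `expected_kept`), and `files` (named paths or `NULL`).
#' @examples
#' sim <- simulate_reads(sim_config(seed = 3, n_read_pairs = 50))
#' table(sim$truth$defect)
#' @export
simulate_reads <- function(config, sample_ids = "S1", out_dir = NULL, gzip = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    per_sample <- lapply(sample_ids, function(s) .sim_reads_one(config, s))
  })
  reads <- do.call(rbind, lapply(per_sample, `[[`, "reads"))
  truth <- do.call(rbind, lapply(per_sample, `[[`, "truth"))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    files <- lapply(sample_ids, function(s) {
      f1 <- file.path(out_dir, paste0(s, "_R1", ext))
      f2 <- file.path(out_dir, paste0(s, "_R2", ext))
      write_fastq_pair(reads[reads$sample == s, , drop = FALSE], f1, f2)
      c(f1, f2)
    })
    names(files) <- sample_ids
  }
  list(reads = reads, truth = truth, files = files)
}

# Generate all pairs for one sample. Assumes the RNG is already seeded.
.sim_reads_one <- function(config, sample) {
  n <- config$n_read_pairs
  L <- config$read_length
  prim <- SOLB_PRIMER
  ids <- sprintf("%s_%06d", sample, seq_len(n))
  if (n == 0L) {
    empty <- data.frame(id = character(), comment = character(), mate = integer(),
                        sequence = character(), quality = character(),
                        chastity_pass = logical(), sample = character(),
                        stringsAsFactors = FALSE)
    truth <- data.frame(id = character(), sample = character(), defect = character(),
                        defect_mate = integer(), detail = integer(),
                        source_id = character(), expected_kept = logical(),
                        stringsAsFactors = FALSE)
    return(list(reads = empty, truth = truth))
  }

  rates <- config$defect_rates
  defect <- sample(c(names(rates), "clean"), n, replace = TRUE,
                   prob = c(rates, 1 - sum(rates)))

  rand_seqs <- function(k, len) {
    if (k == 0L) return(character())
    m <- matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE), nrow = len)
    apply(m, 2, paste, collapse = "")
  }
  rand_quals <- function(k, len, lo = 35L, hi = 40L) {
    if (k == 0L) return(character())
    m <- matrix(as.raw(sample(lo:hi, k * len, replace = TRUE) + 33L), nrow = len)
    apply(m, 2, rawToChar)
  }
  seq1 <- rand_seqs(n, L); seq2 <- rand_seqs(n, L)
  qual1 <- rand_quals(n, L); qual2 <- rand_quals(n, L)
  chastity1 <- rep(TRUE, n); chastity2 <- rep(TRUE, n)
  defect_mate <- ifelse(defect == "clean", NA_integer_,
                        sample(1:2, n, replace = TRUE))
  detail <- rep(NA_integer_, n)
  source_id <- rep(NA_character_, n)

  splice <- function(s, pos, insert) {
    # replace bases [pos, pos+nchar(insert)-1] keeping total length
    paste0(substr(s, 1L, pos - 1L), insert,
           substr(s, pos + nchar(insert), nchar(s)))
  }
  get_seq <- function(i, m) if (m == 1L) seq1[i] else seq2[i]
  set_seq <- function(i, m, v) {
    if (m == 1L) seq1[i] <<- v else seq2[i] <<- v
  }

  half <- L %/% 2L
  for (i in which(!defect %in% c("clean", "duplicate_pair", "revcomp_duplicate"))) {
    m <- defect_mate[i]
    switch(defect[i],
      chastity_fail = {
        if (m == 1L) chastity1[i] <- FALSE else chastity2[i] <- FALSE
      },
      homopolymer = {
        run <- sample(21:26, 1L)
        pos <- sample.int(L - run + 1L, 1L)
        set_seq(i, m, splice(get_seq(i, m), pos, strrep(sample(c("A","C","G","T"), 1L), run)))
        detail[i] <- run
      },
      contains_n = {
        k <- sample(1:3, 1L)
        s <- get_seq(i, m)
        for (p in sample.int(L, k)) substr(s, p, p) <- "N"
        set_seq(i, m, s)
        detail[i] <- k
      },
      lowq_half = {
        # fewer than 2/3 of the first floor(L/2) bases at Q>=30
        limit <- ceiling(2 / 3 * half) - 1L
        k_high <- sample.int(limit + 1L, 1L) - 1L   # 0..limit bases at high Q
        hi_pos <- sample.int(half, k_high)
        q <- sample(2:29, half, replace = TRUE)
        q[hi_pos] <- sample(35:40, k_high, replace = TRUE)
        qfull <- if (m == 1L) qual1[i] else qual2[i]
        qfull <- paste0(rawToChar(as.raw(q + 33L)), substr(qfull, half + 1L, L))
        if (m == 1L) qual1[i] <- qfull else qual2[i] <- qfull
        # the verdict depends on the first-half window, so the read must not
        # start with a short primer suffix that B-tail trimming would shave
        # off ('C' begins no suffix under 10 bases)
        s <- get_seq(i, m)
        substr(s, 1L, 1L) <- "C"
        set_seq(i, m, s)
        detail[i] <- k_high
      },
      solb_full = {
        pos <- sample(20:(L - nchar(prim) + 1L), 1L)
        set_seq(i, m, splice(get_seq(i, m), pos, prim))
        detail[i] <- pos
      },
      solb_tail = {
        k <- sample.int(nchar(prim) - 1L, 1L)             # proper suffix, 1..17
        tail <- substr(prim, nchar(prim) - k + 1L, nchar(prim))
        set_seq(i, m, splice(get_seq(i, m), 1L, tail))
        detail[i] <- k
      },
      short = {
        len <- sample(30:69, 1L)
        set_seq(i, m, substr(get_seq(i, m), 1L, len))
        if (m == 1L) qual1[i] <- substr(qual1[i], 1L, len)
        else qual2[i] <- substr(qual2[i], 1L, len)
        detail[i] <- len
      },
      low_complexity = {
        len <- sample(seq(40L, 60L, 2L), 1L)
        di <- paste(sample(c("A","C","G","T"), 2L), collapse = "")
        pos <- sample.int(L - len + 1L, 1L)
        set_seq(i, m, splice(get_seq(i, m), pos, strrep(di, len %/% 2L)))
        detail[i] <- len
      }
    )
  }

  # duplicates copy an earlier clean pair so "first occurrence kept" matches truth
  clean_idx <- which(defect == "clean")
  for (i in which(defect %in% c("duplicate_pair", "revcomp_duplicate"))) {
    src_pool <- clean_idx[clean_idx < i]
    if (!length(src_pool)) {          # no earlier clean source: demote to clean
      defect[i] <- "clean"; defect_mate[i] <- NA_integer_
      clean_idx <- sort(c(clean_idx, i))
      next
    }
    src <- if (length(src_pool) == 1L) src_pool else sample(src_pool, 1L)
    if (defect[i] == "duplicate_pair") {
      seq1[i] <- seq1[src]; seq2[i] <- seq2[src]
    } else {
      seq1[i] <- revcomp(seq2[src]); seq2[i] <- revcomp(seq1[src])
    }
    source_id[i] <- ids[src]
    defect_mate[i] <- NA_integer_
  }

  comment1 <- paste0("1:", ifelse(chastity1, "N", "Y"), ":0:SIM")
  comment2 <- paste0("2:", ifelse(chastity2, "N", "Y"), ":0:SIM")
  reads <- data.frame(
    id = c(ids, ids), comment = c(comment1, comment2),
    mate = rep(1:2, each = n), sequence = c(seq1, seq2),
    quality = c(qual1, qual2), chastity_pass = c(chastity1, chastity2),
    sample = sample, stringsAsFactors = FALSE
  )
  truth <- data.frame(
    id = ids, sample = sample, defect = defect, defect_mate = defect_mate,
    detail = detail, source_id = source_id,
    expected_kept = defect %in% c("clean", "solb_tail"),
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth)
}
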