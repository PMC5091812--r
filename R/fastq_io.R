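#' Read a pair of FASTQ files into a read table
#'
#' Parses mate-1 and mate-2 FASTQ files (optionally gzipped) into the flat
#' read table used by the QC stack: one row per read with columns `id`
#' (identifier without the header comment), `comment` (everything after the
#' first space, e.g. the CASAVA `1:N:0:INDEX` field), `mate`, `sequence`,
#' `quality` (Phred+33 string) and `chastity_pass`. Per the CASAVA >= 1.8
#' convention the second `:`-separated field of the comment is `Y` when the
#' read *failed* the chastity filter; a missing comment counts as a pass.
#'
#' @param file1,file2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A `data.frame` of reads, mate 1 rows followed by mate 2 rows.
#' @seealso [write_fastq_pair()], [run_qc()]
#' @export
read_fastq_pair <- function(file1, file2) {
  one <- function(f, mate) {
    parsed <- tryCatch({
      x <- Biostrings::readDNAStringSet(f, format = "fastq", with.qualities = TRUE)
      seqs <- as.character(x)
      quals <- as.character(S4Vectors::mcols(x)$qualities)
      bad <- which(nchar(seqs) != nchar(quals))
      if (length(bad))
        stop("record ", bad[1], " has mismatched sequence/quality lengths")
      list(hdr = names(x), seqs = seqs, quals = quals)
    }, error = function(e) {
      stop("malformed FASTQ in ", f, ": ", conditionMessage(e), call. = FALSE)
    })
    hdr <- parsed$hdr
    sp <- regexpr(" ", hdr, fixed = TRUE)
    id <- ifelse(sp > 0, substr(hdr, 1, sp - 1), hdr)
    comment <- ifelse(sp > 0, substr(hdr, sp + 1, nchar(hdr)), "")
    data.frame(
      id = as.character(id), comment = as.character(comment),
      mate = rep(mate, length(hdr)),
      sequence = parsed$seqs, quality = parsed$quals,
      chastity_pass = !chastity_failed(as.character(comment)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  r1 <- one(file1, 1L)
  r2 <- one(file2, 2L)
  if (nrow(r1) != nrow(r2) || (nrow(r1) && any(r1$id != r2$id)))
    stop("mate files do not carry matching read ids in matching order")
  rbind(r1, r2)
}

#' Write a read table back to paired FASTQ files
#'
#' @param reads A read table as produced by [read_fastq_pair()] or
#'   [simulate_reads()].
#' @param file1,file2 Output paths; a `.gz` suffix triggers gzip compression.
#' @return Invisibly, `c(file1, file2)`.
#' @export
write_fastq_pair <- function(reads, file1, file2) {
  stopifnot(is.data.frame(reads), all(reads$mate %in% 1:2))
  one <- function(r, f) {
    s <- Biostrings::DNAStringSet(r$sequence)
    names(s) <- ifelse(nzchar(r$comment), paste(r$id, r$comment), r$id)
    q <- Biostrings::BStringSet(r$quality)
    Biostrings::writeXStringSet(s, f, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", f))
  }
  ord1 <- reads[reads$mate == 1L, , drop = FALSE]
  ord2 <- reads[reads$mate == 2L, , drop = FALSE]
  if (nrow(ord1) != nrow(ord2) || (nrow(ord1) && any(ord1$id != ord2$id)))
    stop("reads table does not contain matched mates in matching order")
  one(ord1, file1)
  one(ord2, file2)
  invisible(c(file1, file2))
}

#' Did a CASAVA-style header comment flag a chastity failure?
#' @param comment Character vector of header comments ("1:N:0:INDEX").
#' @return Logical vector; `TRUE` = failed. Absent/malformed comments pass.
#' @keywords internal
chastity_failed <- function(comment) {
  flag <- sub("^[0-9]+:([YN]):.*$", "\\1", comment)
  !is.na(flag) & flag == "Y"
}

# Phred+33 decode of one quality string to integer scores.
phred_decode <- function(q) utf8ToInt(q) - 33L

# reverse complement of a character vector of sequences
revcomp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
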