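#' DUST low-complexity score
#'
#' Scores sequence complexity from overlapping 3-mer repetition, in the
#' windowed, 0-100 rescaled convention used by read-QC tools. Each window of
#' up to `window` bases contributes
#' \deqn{S_w = \frac{\sum_t c_t (c_t - 1)/2}{w - 3}}
#' where \eqn{c_t} counts occurrences of ACGT 3-mer \eqn{t} among the
#' \eqn{w-2} overlapping triplets of the window. \eqn{S_w} is rescaled so that
#' a mononucleotide run attains 100 (its maximum is \eqn{(w-2)/2}), and the
#' read score is the maximum over windows. Windows start every `step` bases
#' and the final window is anchored at the 3' end so every base is covered.
#' Triplets containing non-ACGT calls are ignored.
#'
#' Reads scoring above the configured threshold (default 7) are removed as
#' low-complexity by [run_qc()]. Note this windowed 0-100 convention differs
#' from the unscaled score of the original DUST publication; window size and
#' step are arguments.
#'
#' @param sequences Character vector of sequences.
#' @param window Window size in bases (default 64).
#' @param step Window step (default 32).
#' @return Numeric scores in \[0, 100\]; sequences shorter than 4 bases
#'   score 0.
#' @examples
#' dust_score(strrep("A", 64))       # 100
#' dust_score("ACGTACGTACGT")        # highly repetitive
#' @export
dust_score <- function(sequences, window = 64L, step = 32L) {
  stopifnot(window >= 4L, step >= 1L)
  n <- length(sequences)
  if (!n) return(numeric())
  scores <- numeric(n)
  lens <- nchar(sequences)
  for (L in unique(lens)) {
    sel <- which(lens == L)
    if (L < 4L) { scores[sel] <- 0; next }
    w <- min(window, L)
    offs <- seq.int(1L, L - w + 1L, by = step)
    if (offs[length(offs)] != L - w + 1L) offs <- c(offs, L - w + 1L)
    best <- numeric(length(sel))
    for (o in offs) {
      sub <- substr(sequences[sel], o, o + w - 1L)
      cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(sub), 3L)
      raw <- rowSums(cnt * (cnt - 1) / 2) / (w - 3)
      best <- pmax(best, raw / ((w - 2) / 2) * 100)
    }
    scores[sel] <- best
  }
  scores
}
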