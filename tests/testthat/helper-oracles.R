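# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# --- DUST: plain-loop scorer over the same windowed 3-mer formula ------------
brute_dust <- function(seq, window = 64L, step = 32L) {
  L <- nchar(seq)
  if (L < 4L) return(0)
  w <- min(window, L)
  offs <- seq(1L, L - w + 1L, by = step)
  if (offs[length(offs)] != L - w + 1L) offs <- c(offs, L - w + 1L)
  best <- 0
  for (o in offs) {
    win <- substr(seq, o, o + w - 1L)
    trips <- character(0)
    for (j in 1:(w - 2L)) {
      t3 <- substr(win, j, j + 2L)
      if (!grepl("[^ACGT]", t3)) trips <- c(trips, t3)
    }
    cnt <- table(trips)
    raw <- sum(cnt * (cnt - 1) / 2) / (w - 3)
    best <- max(best, raw / ((w - 2) / 2) * 100)
  }
  best
}

# a 64-mer whose 62 overlapping 3-mers are all distinct: depth-first search
# over the 3-mer graph, verified on construction
distinct_triplet_64mer <- function() {
  bases <- c("A", "C", "G", "T")
  walk <- function(s, seen) {
    if (nchar(s) == 64L) return(s)
    for (b in bases) {
      t3 <- paste0(substr(s, nchar(s) - 1L, nchar(s)), b)
      if (!t3 %in% seen) {
        res <- walk(paste0(s, b), c(seen, t3))
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  s <- walk("AAT", "AAT")
  stopifnot(!is.null(s), nchar(s) == 64L,
            !anyDuplicated(substring(s, 1:62, 3:64)))
  s
}

# --- Freeman-Halton exact test: enumerate all tables with fixed margins ------
brute_fisher <- function(tab) {
  rm <- rowSums(tab); cm <- colSums(tab); N <- sum(tab)
  logfact <- lgamma(seq_len(N + 1))  # lgamma(k+1) = log(k!)
  lf <- function(k) lgamma(k + 1)
  log_p <- function(m) sum(lf(rm)) + sum(lf(cm)) - lf(N) - sum(lf(m))
  p_obs <- log_p(tab)
  total <- 0
  r <- nrow(tab); cc <- ncol(tab)
  # recursively fill rows; last row determined by column margins
  fill <- function(row_idx, col_left, acc) {
    if (row_idx == r) {
      if (any(col_left < 0)) return()
      m <- rbind_acc(acc, col_left)
      lp <- log_p(m)
      if (lp <= p_obs + log(1 + 1e-7)) total <<- total + exp(lp)
      return()
    }
    cells <- enumerate_row(rm[row_idx], pmin(col_left, rm[row_idx]))
    for (i in seq_len(nrow(cells))) {
      fill(row_idx + 1L, col_left - cells[i, ], c(acc, list(cells[i, ])))
    }
  }
  rbind_acc <- function(acc, last) do.call(rbind, c(acc, list(last)))
  enumerate_row <- function(s, caps) {
    # all non-negative integer vectors summing to s with per-cell caps
    if (length(caps) == 1L) {
      if (s <= caps) return(matrix(s, 1)) else return(matrix(numeric(0), 0, 1))
    }
    out <- NULL
    for (v in 0:min(s, caps[1])) {
      sub <- enumerate_row(s - v, caps[-1])
      if (nrow(sub)) out <- rbind(out, cbind(v, sub))
    }
    if (is.null(out)) matrix(numeric(0), 0, length(caps)) else out
  }
  fill(1L, cm, list())
  min(total, 1)
}

# --- Wilcoxon rank-sum: exact two-sided p by counting rank-sum outcomes -----
# dynamic programme over which ranks fall in the x sample (no ties assumed);
# two-sided p = P(|W - E W| >= |w_obs - E W|) under the uniform null
brute_wilcoxon <- function(x, y) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  w_obs <- sum(rank(c(x, y))[seq_len(nx)])
  smax <- sum((N - nx + 1):N)
  ways <- matrix(0, nx + 1L, smax + 1L)  # ways[k+1, s+1]
  ways[1, 1] <- 1
  for (r in seq_len(N)) {
    for (k in rev(seq_len(min(r, nx)))) {
      srange <- seq_len(smax - r + 1L)
      ways[k + 1L, srange + r] <- ways[k + 1L, srange + r] + ways[k, srange]
    }
  }
  counts <- ways[nx + 1L, ]
  sums <- 0:smax
  m <- nx * (N + 1) / 2
  sum(counts[abs(sums - m) >= abs(w_obs - m) - 1e-9]) / choose(N, nx)
}

# --- Pair concordance: naive loop over read ids ------------------------------
brute_concordance <- function(assignments, taxon) {
  a <- assignments[assignments$taxon == taxon, , drop = FALSE]
  total <- nrow(a)
  pairs <- 0L
  for (id in unique(a$read_id)) {
    m <- a$mate[a$read_id == id]
    if (any(m == 1) && any(m == 2)) pairs <- pairs + 1L
  }
  c(total = total, pairs = pairs)
}

# --- shared tiny configs -----------------------------------------------------
small_counts_config <- function(seed, ...) {
  sim_config(seed = seed,
             n_per_group = c(CFS = 6L, Healthy = 6L, ADCLS = 4L, SLE = 4L,
                             NegControl = 3L, PosControl = 1L),
             n_resequenced = c(CFS = 1L, Healthy = 1L, ADCLS = 0L, SLE = 0L),
             n_taxa = 25L, n_contaminant_taxa = 10L, n_batch_effect_taxa = 0L,
             batch_effect_sd = 0, ...)
}

random_assignment_fixture <- function(n_pairs = 30L, n_taxa = 3L) {
  ids <- sprintf("R%04d", seq_len(n_pairs))
  taxa <- c(sprintf("T%d", seq_len(n_taxa)), NA)
  rows <- data.frame(
    read_id = rep(ids, each = 2L), mate = rep(1:2, n_pairs),
    sample_id = sample(c("A", "B", "C"), 2L * n_pairs, replace = TRUE),
    taxon = sample(taxa, 2L * n_pairs, replace = TRUE),
    rank = "genus", stringsAsFactors = FALSE)
  rows[!is.na(rows$taxon), , drop = FALSE]
}
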