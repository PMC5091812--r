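mk_pair <- function(id, seq1, seq2, q1 = NULL, q2 = NULL,
                    chast1 = TRUE, chast2 = TRUE) {
  q <- function(s, q0) if (is.null(q0)) strrep("I", nchar(s)) else q0  # I = Q40
  data.frame(id = id, comment = "", mate = 1:2,
             sequence = c(seq1, seq2), quality = c(q(seq1, q1), q(seq2, q2)),
             chastity_pass = c(chast1, chast2), sample = "T",
             stringsAsFactors = FALSE)
}
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("pair dereplication removes exact and reverse-complement duplicates", {
  a <- mk_pair("a", rand_seq(100, 1), rand_seq(100, 2))
  b <- mk_pair("b", rand_seq(100, 1), rand_seq(100, 2))           # exact copy
  rc <- mk_pair("c", plasmascreen:::revcomp(a$sequence[2]),        # strand flip
                plasmascreen:::revcomp(a$sequence[1]))
  d <- mk_pair("d", rand_seq(100, 3), rand_seq(100, 4))
  res <- dereplicate_pairs(rbind(a, b, rc, d))
  expect_identical(sort(unique(res$reads$id)), c("a", "d"))
  expect_identical(res$removed, 2L)
})

test_that("unmatched mates raise a structural error naming the read", {
  a <- mk_pair("lonely", rand_seq(50, 1), rand_seq(50, 2))[1, ]
  expect_error(dereplicate_pairs(a), "lonely")
})

test_that("single-read dereplication pools mates and keeps first occurrences", {
  a <- mk_pair("a", rand_seq(80, 1), rand_seq(80, 2))
  b <- mk_pair("b", rand_seq(80, 5), rand_seq(80, 1))  # mate2 duplicates a's mate1
  pooled <- rbind(a, b)
  kept <- dereplicate_single(pooled)
  expect_identical(nrow(kept), 3L)
  expect_identical(dereplicate_single(kept), kept)
  expect_identical(nrow(dereplicate_single(pooled[0, ])), 0L)
})

test_that("B-tail trimming removes exactly the planted primer suffix", {
  cfg <- filter_config()
  r <- mk_pair("t", paste0("GGATA", rand_seq(95, 7)), rand_seq(100, 8))
  tr <- trim_b_tail(r, cfg)
  expect_identical(tr$sequence[1], substr(r$sequence[1], 6, 100))
  expect_identical(tr$quality[1], substr(r$quality[1], 6, 100))
  # a read with no primer-derived prefix is untouched
  r2 <- mk_pair("u", paste0("CCCC", rand_seq(96, 9)), rand_seq(100, 10))
  expect_identical(trim_b_tail(r2, cfg)$sequence[1], r2$sequence[1])
  # one mismatch tolerated for tails of 10+
  tail12 <- substr(SOLB_PRIMER, 7, 18)
  substr(tail12, 3, 3) <- "A"
  r3 <- mk_pair("v", paste0(tail12, rand_seq(88, 11)), rand_seq(100, 12))
  expect_identical(nchar(trim_b_tail(r3, cfg)$sequence[1]), 88L)
})

test_that("trimmed lengths match planted tail lengths in nearly all reads", {
  cfg <- sim_config(seed = 31, n_read_pairs = 2000,
                    defect_rates = c(solb_tail = 1))
  sim <- simulate_reads(cfg)
  trimmed <- trim_b_tail(sim$reads)
  tl <- sim$truth
  i <- match(paste(tl$id, tl$defect_mate), paste(trimmed$id, trimmed$mate))
  got_len <- nchar(trimmed$sequence[i])
  expect_gte(mean(got_len == cfg$read_length - tl$detail), 0.99)
})

test_that("bespoke rules respect their boundaries and attribution order", {
  cfg <- filter_config()
  clean <- rand_seq(100, 20)
  ok <- mk_pair("k", clean, rand_seq(100, 21))
  expect_true(apply_bespoke_filter(ok, cfg)$keep)

  # flank the runs with explicit non-A bases so the run length is exact
  run21 <- paste0(substr(clean, 1, 39), "C", strrep("A", 21), "C",
                  substr(clean, 63, 100))
  run20 <- paste0(substr(clean, 1, 39), "C", strrep("A", 20), "C",
                  substr(clean, 62, 100))
  expect_identical(apply_bespoke_filter(mk_pair("h", run21, clean), cfg)$rule,
                   "homopolymer")
  expect_true(apply_bespoke_filter(mk_pair("h2", run20, clean), cfg)$keep)

  # 2/3 of the first 50 bases: 33 high-quality bases fail, 34 keep
  ql <- function(k) paste0(strrep("I", k), strrep("#", 50 - k), strrep("I", 50))
  expect_identical(
    apply_bespoke_filter(mk_pair("q1", clean, clean, q1 = ql(33)), cfg)$rule,
    "lowq_half")
  expect_true(apply_bespoke_filter(mk_pair("q2", clean, clean, q1 = ql(34)), cfg)$keep)

  withp <- paste0(substr(clean, 1, 30), SOLB_PRIMER, substr(clean, 49, 100))
  expect_identical(apply_bespoke_filter(mk_pair("p", clean, withp), cfg)$rule,
                   "solb_contained")
  expect_identical(apply_bespoke_filter(mk_pair("c", clean, clean,
                                                chast2 = FALSE), cfg)$rule,
                   "chastity")
  expect_identical(
    apply_bespoke_filter(mk_pair("s", substr(clean, 1, 69), clean), cfg)$rule,
    "too_short")
  empty <- mk_pair("e", "", clean); empty$quality[1] <- ""
  expect_identical(apply_bespoke_filter(empty, cfg)$rule, "too_short")

  # chastity outranks an N on the other mate
  withn <- paste0("N", substr(clean, 2, 100))
  expect_identical(apply_bespoke_filter(mk_pair("o", withn, clean,
                                                chast2 = FALSE), cfg)$rule,
                   "chastity")
})

test_that("run_qc keeps exactly the truth-clean set and is idempotent", {
  cfg <- sim_config(seed = 13, n_read_pairs = 3000)
  sim <- simulate_reads(cfg)
  res <- run_qc(sim$reads)
  rep <- res$report

  expect_setequal(unique(res$reads$id), sim$truth$id[sim$truth$expected_kept])
  # conservation: every input pair accounted once
  expect_identical(rep$input_pairs, cfg$n_read_pairs)
  expect_identical(rep$input_pairs, rep$surviving_pairs + sum(rep$removed))
  expect_identical(rep$filtered_read_count, 2L * rep$surviving_pairs)

  # per-rule attrition equals truth for rule-unambiguous defects; planted
  # homopolymers score above the DUST threshold so they pool with
  # low-complexity removals
  tab <- table(factor(sim$truth$defect, levels = c(names(cfg$defect_rates), "clean")))
  expect_identical(unname(rep$removed[["chastity"]]), unname(tab[["chastity_fail"]]))
  expect_identical(unname(rep$removed[["n_content"]]), unname(tab[["contains_n"]]))
  expect_identical(unname(rep$removed[["lowq_half"]]), unname(tab[["lowq_half"]]))
  expect_identical(unname(rep$removed[["solb_contained"]]), unname(tab[["solb_full"]]))
  expect_identical(unname(rep$removed[["too_short"]]), unname(tab[["short"]]))
  expect_identical(unname(rep$removed[["duplicate_pair"]]),
                   unname(tab[["duplicate_pair"]] + tab[["revcomp_duplicate"]]))
  expect_identical(unname(rep$removed[["homopolymer"]] + rep$removed[["low_complexity"]]),
                   unname(tab[["homopolymer"]] + tab[["low_complexity"]]))

  # fixed point: a second pass removes nothing
  res2 <- run_qc(res$reads)
  expect_identical(sum(res2$report$removed), 0L)
  expect_setequal(unique(res2$reads$id), unique(res$reads$id))
})

test_that("all-clean input passes untouched", {
  cfg <- sim_config(seed = 17, n_read_pairs = 150, defect_rates = c())
  sim <- simulate_reads(cfg)
  res <- run_qc(sim$reads)
  expect_identical(res$report$surviving_pairs, 150L)
  expect_true(all(res$report$removed == 0L))
})

test_that("malformed FASTQ input fails with a clear parse error", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II"), bad)  # quality length mismatch
  good <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), good)
  expect_error(read_fastq_pair(bad, good), "malformed FASTQ")
})
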