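#' Fisher's exact test for r x c contingency tables
#'
#' Exact two-sided test in the Freeman-Halton sense: the p-value sums the
#' probabilities of every table with the observed margins whose multivariate
#' hypergeometric probability does not exceed that of the observed table
#' (with a small relative tolerance for floating-point ties). All-zero rows
#' and columns are dropped first; 2 x 2 tables are the k = 2 special case.
#' Enumeration is guarded to tables with at most 200 observations — cohort
#' demographic tables are far below this; larger tables would need a
#' Monte-Carlo approximation, which this package does not provide.
#'
#' @param table Matrix of non-negative integer counts.
#' @return A list of class `cohort_test`: `p_value`, `method`, `table` (after
#'   dropping empty rows/columns).
#' @examples
#' fisher_exact(rbind(Healthy = c(4, 21), SLE = c(0, 11)))
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold non-negative integer counts")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must have at least 2 non-empty rows and 2 non-empty columns")
  if (sum(tab) > 200L)
    stop("table total exceeds the exact-enumeration guard (200); ",
         "a Monte-Carlo approximation would be needed, which is not provided")
  p <- fisher.test(tab)$p.value
  structure(list(p_value = min(p, 1), method = "fisher_exact", table = tab),
            class = "cohort_test")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided comparison of two continuous samples. Uses the exact rank-sum
#' distribution when the smaller sample has at most 25 observations and there
#' are no ties; otherwise a tie-corrected normal approximation with
#' continuity correction. Identical constant samples give p = 1.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact distribution;
#'   the default `NULL` selects it automatically as described above. Exact
#'   computation with ties is not available.
#' @return A list of class `cohort_test`: `p_value`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1L, length(y) >= 1L, is.numeric(x), is.numeric(y))
  if (length(unique(c(x, y))) == 1L) {
    return(structure(list(p_value = 1, method = "degenerate_identical"),
                     class = "cohort_test"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- min(length(x), length(y)) <= 25L && !ties
  if (exact && ties) stop("exact rank-sum p-values are unavailable with ties")
  p <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))$p.value
  structure(list(p_value = min(p, 1),
                 method = if (exact) "exact" else "normal_approx_tie_corrected"),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("%s: p = %.4g\n", x$method, x$p_value))
  invisible(x)
}

#' Cohort demographic counts shipped with the package
#'
#' Categorical demographic counts of the four-group study cohort (25 healthy,
#' 11 SLE, 25 CFS, 13 ADCLS): sex and ethnicity per group, as a long-format
#' data frame read from `extdata/table1_demographics.tsv`.
#'
#' @param file Path to the TSV (defaults to the shipped fixture).
#' @return Data frame with columns `variable`, `category`, and one count
#'   column per group.
#' @export
table1_demographics <- function(file = system.file("extdata",
                                                   "table1_demographics.tsv",
                                                   package = "plasmascreen")) {
  read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Exact tests on a cohort demographics table
#'
#' For every categorical variable in a [table1_demographics()]-shaped table,
#' tests each comparison group against the reference group with
#' [fisher_exact()] on the group x category counts.
#'
#' @param demographics Long-format counts (columns `variable`, `category`,
#'   one column per group).
#' @param reference Reference group column (default "Healthy").
#' @param comparisons Groups to compare against the reference; default all
#'   other count columns.
#' @return Data frame: `variable`, `comparison`, `p_value`.
#' @examples
#' cohort_table_tests(table1_demographics())
#' @export
cohort_table_tests <- function(demographics, reference = "Healthy",
                               comparisons = NULL) {
  stopifnot(all(c("variable", "category", reference) %in% names(demographics)))
  if (is.null(comparisons))
    comparisons <- setdiff(names(demographics), c("variable", "category", reference))
  out <- do.call(rbind, lapply(unique(demographics$variable), function(v) {
    sub <- demographics[demographics$variable == v, , drop = FALSE]
    do.call(rbind, lapply(comparisons, function(g) {
      tab <- rbind(sub[[reference]], sub[[g]])
      dimnames(tab) <- list(c(reference, g), sub$category)
      data.frame(variable = v, comparison = g,
                 p_value = fisher_exact(tab)$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
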