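#' Exact and rank-based tests
#'
#' Thin, validated wrappers around the standard tests the pipeline uses, so
#' that every stage calls one audited surface: Fisher's exact test (2x2 by
#' hypergeometric tail summation, r x c by the Freeman-Halton network
#' algorithm), Pearson chi-square, Wilcoxon rank-sum, Benjamini-Hochberg
#' adjustment, and tie-aware Spearman correlation.
#'
#' @param tab non-negative integer matrix (at least 2x2).
#' @param enumeration_max maximum table total for r x c exact enumeration.
#' @return `fisher_exact`: the two-sided p-value (sum of the probabilities of
#'   tables with fixed margins no more probable than the observed one).
#' @name stat-tests
NULL

check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative entries in contingency table", call. = FALSE)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (any(tab != round(tab))) stop("non-integer counts", call. = FALSE)
  storage.mode(tab) <- "integer"
  tab
}

#' @rdname stat-tests
#' @export
fisher_exact <- function(tab, enumeration_max = 500L) {
  tab <- check_table(tab)
  if (!(nrow(tab) == 2L && ncol(tab) == 2L) && sum(tab) > enumeration_max) {
    stop("table total ", sum(tab), " exceeds exact enumeration bound ",
         enumeration_max, "; consider chi_square()", call. = FALSE)
  }
  stats::fisher.test(tab, workspace = 2e7)$p.value
}

#' @rdname stat-tests
#' @param correct apply Yates continuity correction for 2x2 tables
#'   (default `FALSE`: plain Pearson statistic).
#' @return `chi_square`: a list with `statistic`, `df`, `p`, and the
#'   `expected` counts (so sparse cells are visible to the caller).
#' @export
chi_square <- function(tab, correct = FALSE) {
  tab <- check_table(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' @rdname stat-tests
#' @param x,y numeric value vectors.
#' @param mode `"auto"` picks the exact distribution when the pooled size is
#'   at most 20 and there are no ties, otherwise the tie- and
#'   continuity-corrected normal approximation.
#' @return `wilcoxon_rank_sum`: the two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- switch(mode,
    auto = (length(x) + length(y) <= 20L) && !ties,
    exact = TRUE,
    normal_approx = FALSE)
  if (use_exact && ties) {
    stop("exact mode is not defined in the presence of ties", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  res$p.value
}

#' @rdname stat-tests
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return `bh_adjust`: the step-up adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' @rdname stat-tests
#' @return `spearman_cor`: the tie-aware Spearman rank correlation
#'   (Pearson correlation of mid-ranks).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Collapse a TC-score contingency table to negative vs expressing
#'
#' Immunohistochemistry membrane scores `TC1`-`TC3` all denote
#' CTLA-4-expressing cases; association tests compare them pooled against
#' the negative `TC0` column.
#'
#' @param tab matrix with columns `TC0`, `TC1`, `TC2`, `TC3`.
#' @return Two-column matrix (`TC0`, `expressing`) with the same rows.
#' @export
collapse_tc_table <- function(tab) {
  tab <- check_table(tab)
  stopifnot(all(c("TC0", "TC1", "TC2", "TC3") %in% colnames(tab)))
  out <- cbind(TC0 = tab[, "TC0"],
               expressing = rowSums(tab[, c("TC1", "TC2", "TC3"), drop = FALSE]))
  rownames(out) <- rownames(tab)
  out
}

#' Read a labeled contingency table from CSV
#'
#' First column holds row labels; remaining columns are counts.
#'
#' @param path CSV file path.
#' @return Integer matrix with dimnames.
#' @export
read_contingency <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  check_table(m)
}
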