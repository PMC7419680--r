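#' Single-sample gene set enrichment (ssGSEA)
#'
#' Rank-based per-sample enrichment in the running-sum style of ssGSEA. For
#' each sample, genes are ranked by expression in decreasing order (ties
#' broken by gene identifier, so scores are deterministic); the gene at
#' descending position `i` of `N` carries rank value `r = N - i + 1`. The
#' score of a set is the integrated difference between the weighted in-set
#' ECDF (weights `r^alpha` over set members) and the uniform ECDF of
#' non-members:
#' \deqn{ES = \sum_i [P_{in}(i) - P_{out}(i)].}
#' Scores depend only on within-sample ranks, so they are invariant under any
#' strictly monotone transform of a sample's values.
#'
#' @param x an [expr_matrix()].
#' @param genes character vector of set gene symbols.
#' @param alpha rank-weight exponent (default 0.25).
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(x, genes, alpha = 0.25) {
  stopifnot(alpha >= 0)
  vals <- as_expr_values(x)
  genes <- unique(clean_symbols(genes))
  present <- intersect(genes, rownames(vals))
  if (length(present) == 0L) {
    stop("no set genes present in the matrix", call. = FALSE)
  }
  n <- nrow(vals)
  in_set <- rownames(vals) %in% present
  n_out <- n - sum(in_set)
  if (n_out == 0L) stop("gene set covers the whole matrix", call. = FALSE)
  apply_cols(vals, function(v) {
    ord <- order(-v, rownames(vals))
    hit <- in_set[ord]
    r <- (n:1)^alpha
    w <- ifelse(hit, r, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!hit) / n_out
    sum(p_in - p_out)
  })
}

apply_cols <- function(vals, f) {
  out <- vapply(seq_len(ncol(vals)), function(j) f(vals[, j]), numeric(1L))
  names(out) <- colnames(vals)
  out
}

#' Score every set of a collection by ssGSEA
#'
#' @param x an [expr_matrix()].
#' @param sets a [gene_set_collection()].
#' @param alpha rank-weight exponent (default 0.25).
#' @return A tibble with columns `sample`, `set`, `score`.
#' @export
ssgsea <- function(x, sets, alpha = 0.25) {
  stopifnot(inherits(sets, "gene_set_collection"), length(sets) >= 1L)
  purrr::map_dfr(names(sets), function(nm) {
    sc <- ssgsea_score(x, sets[[nm]], alpha = alpha)
    tibble::tibble(sample = names(sc), set = nm, score = unname(sc))
  })
}

#' Combine several gene set scores into one axis score
#'
#' Each set's per-sample score vector is standardized to zero mean and unit
#' variance across samples, then the standardized vectors are averaged. Sets
#' with zero variance carry no ranking information and are excluded with a
#' warning.
#'
#' @param scores tibble with columns `sample`, `set`, `score` (as returned by
#'   [ssgsea()]), or a samples-by-sets numeric matrix.
#' @return Named numeric vector: one combined score per sample.
#' @export
combine_axis_scores <- function(scores) {
  if (is.data.frame(scores)) {
    wide <- tidyr::pivot_wider(scores, id_cols = "sample",
                               names_from = "set", values_from = "score")
    m <- as.matrix(wide[, -1L, drop = FALSE])
    rownames(m) <- wide$sample
  } else {
    m <- as.matrix(scores)
  }
  stopifnot(ncol(m) >= 1L)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance set score(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) == 0L) stop("no set with positive variance", call. = FALSE)
  }
  z <- scale(m)
  stats::setNames(rowMeans(z), rownames(m))
}
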