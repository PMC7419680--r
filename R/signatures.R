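#' Cytolytic activity score (CYT)
#'
#' The per-sample arithmetic mean of normalized GZMA and PRF1 expression.
#'
#' @param x an [expr_matrix()].
#' @return Named numeric vector of per-sample scores.
#' @export
cytolytic_score <- function(x) {
  mean_signature_score(x, c("GZMA", "PRF1"), require_all = TRUE)
}

#' Mean-expression signature score
#'
#' Multi-gene signatures such as the Tumor Inflammation Signature (TIS),
#' proliferation clusters, tissue-resident memory (TRM) and the anti-CTLA-4
#' immune score are scored as the per-sample mean of the signature genes'
#' normalized expression. Genes absent from the matrix are skipped (with a
#' message) unless `require_all` is set.
#'
#' @param x an [expr_matrix()].
#' @param genes character vector of signature gene symbols.
#' @param require_all error when any signature gene is missing (used by
#'   fixed-length signatures such as CYT).
#' @return Named numeric vector of per-sample scores.
#' @export
mean_signature_score <- function(x, genes, require_all = FALSE) {
  vals <- as_expr_values(x)
  genes <- unique(clean_symbols(genes))
  present <- intersect(genes, rownames(vals))
  missing <- setdiff(genes, present)
  if (require_all && length(missing)) {
    stop("signature gene(s) missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(present) == 0L) {
    stop("no signature gene present in the matrix", call. = FALSE)
  }
  if (length(missing)) {
    message(length(missing), " signature gene(s) not measured: ",
            paste(missing, collapse = ", "))
  }
  colMeans(vals[present, , drop = FALSE])
}

#' Immune cell-type enrichment panel
#'
#' ssGSEA scores for a panel of immune cell-type signatures (for example the
#' Charoentong-style adaptive/innate panels), one score per cell type per
#' sample.
#'
#' @param x an [expr_matrix()].
#' @param sets a [gene_set_collection()]; only sets tagged
#'   `immune_celltype` are used when such sets are present, otherwise all.
#' @param alpha ssGSEA rank-weight exponent.
#' @param min_size minimum surviving set size after universe restriction.
#' @return A tibble with columns `sample`, `set`, `score`.
#' @export
celltype_enrichment_panel <- function(x, sets, alpha = 0.25, min_size = 5L) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (any(attr(sets, "roles") == "immune_celltype")) {
    sets <- sets_with_role(sets, "immune_celltype")
  }
  sets <- restrict_to_universe(sets, rownames(x), min_size = min_size)
  if (length(sets) == 0L) {
    stop("no cell-type set survives universe restriction", call. = FALSE)
  }
  ssgsea(x, sets, alpha = alpha)
}

#' Compare score distributions across clusters against a reference
#'
#' For each non-reference cluster on the chosen axis, a two-sided Wilcoxon
#' rank-sum test against the reference cluster (HH by default), with group
#' medians and Benjamini-Hochberg adjustment across the compared clusters.
#'
#' @param scores named numeric vector of per-sample scores (names are sample
#'   identifiers).
#' @param clusters a [assign_clusters()] result.
#' @param axis `"erk"` or `"akt"`.
#' @param reference reference cluster label (default `"HH"`).
#' @return A tibble (`cluster`, `n`, `median`, `reference_median`, `p`, `q`).
#' @export
compare_groups <- function(scores, clusters, axis = c("erk", "akt"),
                           reference = "HH") {
  axis <- match.arg(axis)
  col <- paste0(axis, "_cluster")
  stopifnot(col %in% names(clusters))
  grp <- as.character(clusters[[col]])
  names(grp) <- clusters$sample
  common <- intersect(names(scores), names(grp))
  scores <- scores[common]; grp <- grp[common]
  ref_vals <- scores[grp == reference]
  if (length(ref_vals) == 0L) stop("reference group is empty", call. = FALSE)
  others <- setdiff(unique(grp), reference)
  rows <- purrr::map_dfr(others, function(cl) {
    v <- scores[grp == cl]
    if (length(v) == 0L) {
      warning("cluster ", cl, " is empty; comparison skipped", call. = FALSE)
      return(tibble::tibble())
    }
    tibble::tibble(
      cluster = cl, n = length(v),
      median = stats::median(v),
      reference_median = stats::median(ref_vals),
      p = wilcoxon_rank_sum(v, ref_vals)
    )
  })
  if (nrow(rows)) rows$q <- bh_adjust(rows$p)
  rows
}

#' Marker co-occurrence at the median
#'
#' Dichotomizes the anchor gene and each partner gene at their cohort
#' medians and reports, within the anchor-High and anchor-Low strata, the
#' proportion of samples that are partner-High (the donut-chart style
#' co-over-expression summary).
#'
#' @param x an [expr_matrix()].
#' @param anchor anchor gene symbol (e.g. `"CTLA4"`).
#' @param partners character vector of partner gene symbols.
#' @return A tibble (`partner`, `anchor_status`, `n`, `n_partner_high`,
#'   `prop_partner_high`).
#' @export
marker_cooccurrence <- function(x, anchor, partners) {
  vals <- as_expr_values(x)
  anchor <- clean_symbols(anchor); partners <- clean_symbols(partners)
  missing <- setdiff(c(anchor, partners), rownames(vals))
  if (length(missing)) {
    stop("gene(s) missing from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  a_status <- dichotomize(vals[anchor, ])
  purrr::map_dfr(partners, function(p) {
    p_status <- dichotomize(vals[p, ])
    purrr::map_dfr(c("High", "Low"), function(s) {
      sel <- a_status == s
      tibble::tibble(
        partner = p, anchor_status = s, n = sum(sel),
        n_partner_high = sum(p_status[sel] == "High"),
        prop_partner_high = mean(p_status[sel] == "High")
      )
    })
  })
}
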