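#' Two-phenotype permutation GSEA
#'
#' Non-preranked gene set enrichment: genes are ranked by a two-group
#' differential metric, the weighted Kolmogorov-Smirnov running sum gives the
#' enrichment score (ES), and significance comes from phenotype permutations.
#' When the number of distinct label assignments `choose(n, n1)` does not
#' exceed `n_perm` the null is exhaustive (an exact permutation test);
#' otherwise `n_perm` assignments are sampled under `seed`.
#'
#' The default ranking metric is signal-to-noise,
#' `(mean1 - mean2) / (sd1 + sd2)`, with each group's sd floored at
#' `0.2 * |mean|` and at a small positive minimum; `t_like` uses
#' `(mean1 - mean2) / sqrt(s1^2/n1 + s2^2/n2)`. NES is ES divided by the
#' mean absolute value of same-sign null scores, the nominal p-value is the
#' fraction of null assignments whose |ES| reaches the observed |ES|, and FDR
#' is the standard same-sign normalized-null ratio, capped at 1.
#'
#' @param x an [expr_matrix()].
#' @param labels two-group factor or character vector, one entry per sample;
#'   the first level is the reference ("group 1") so positive ES means
#'   enrichment in that group.
#' @param sets a [gene_set_collection()].
#' @param n_perm number of phenotype permutations (default 1000).
#' @param weight_p enrichment weight on |metric| (default 1).
#' @param ranking_metric `"signal_to_noise"` or `"t_like"`.
#' @param seed integer seed for sampled permutations.
#' @return A tibble (`set`, `size`, `es`, `nes`, `p`, `fdr`) sorted by
#'   decreasing NES, with class `gsea_table`.
#' @export
gsea <- function(x, labels, sets, n_perm = 1000L, weight_p = 1,
                 ranking_metric = c("signal_to_noise", "t_like"), seed = 1L) {
  ranking_metric <- match.arg(ranking_metric)
  vals <- as_expr_values(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) {
    stop("labels must define exactly two groups", call. = FALSE)
  }
  if (length(labels) != ncol(vals)) {
    stop("one label per sample required", call. = FALSE)
  }
  g1 <- labels == levels(labels)[1L]
  if (sum(g1) < 2L || sum(!g1) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  sets <- restrict_to_universe(sets, rownames(vals), min_size = 1L)
  if (length(sets) == 0L) stop("no usable gene sets", call. = FALSE)

  idx_sets <- lapply(unclass(sets), function(g) which(rownames(vals) %in% g))
  es_all <- function(assign_g1) {
    met <- ranking_stat(vals, assign_g1, ranking_metric)
    ord <- order(-met, rownames(vals))
    met_o <- met[ord]
    pos <- integer(nrow(vals)); pos[ord] <- seq_along(ord)
    vapply(idx_sets, function(ix) es_stat(met_o, sort(pos[ix]), weight_p),
           numeric(1L))
  }

  obs <- es_all(g1)
  n <- length(labels); n1 <- sum(g1)
  n_distinct <- choose(n, n1)
  if (n_distinct <= n_perm) {
    assigns <- utils::combn(n, n1, simplify = FALSE)
  } else {
    set.seed(seed)
    assigns <- replicate(n_perm, sample.int(n, n1), simplify = FALSE)
  }
  null_es <- vapply(assigns, function(ix) {
    g <- logical(n); g[ix] <- TRUE
    es_all(g)
  }, numeric(length(obs)))
  null_es <- matrix(null_es, nrow = length(obs))

  nes <- numeric(length(obs)); null_nes <- null_es
  pvals <- numeric(length(obs))
  for (i in seq_along(obs)) {
    ne <- null_es[i, ]
    # mirror assignments give |ES| equal in exact arithmetic; count them with
    # a relative tolerance so summation order cannot drop them from the tail
    pvals[i] <- mean(abs(ne) >= abs(obs[i]) * (1 - 1e-9))
    pos_mean <- mean(ne[ne > 0]); neg_mean <- mean(abs(ne[ne < 0]))
    norm_for <- function(v) {
      ifelse(v >= 0,
             v / ifelse(is.finite(pos_mean) && pos_mean > 0, pos_mean, 1),
             v / ifelse(is.finite(neg_mean) && neg_mean > 0, neg_mean, 1))
    }
    nes[i] <- norm_for(obs[i])
    null_nes[i, ] <- norm_for(ne)
  }
  fdr <- vapply(seq_along(obs), function(i) {
    v <- nes[i]
    if (v >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= v)
      den <- mean(nes[nes >= 0] >= v)
    } else {
      num <- mean(null_nes[null_nes <= 0] <= v)
      den <- mean(nes[nes <= 0] <= v)
    }
    if (!is.finite(num)) num <- 1
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1L))

  out <- tibble::tibble(
    set = names(idx_sets),
    size = lengths(idx_sets),
    es = unname(obs),
    nes = nes,
    p = pvals,
    fdr = fdr
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$nes))
  class(out) <- c("gsea_table", class(out))
  attr(out, "n_perm") <- length(assigns)
  attr(out, "exhaustive") <- n_distinct <= n_perm
  out
}

# two-group ranking metric over all genes
ranking_stat <- function(vals, g1, metric) {
  a <- vals[, g1, drop = FALSE]
  b <- vals[, !g1, drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  s1 <- apply(a, 1L, stats::sd); s2 <- apply(b, 1L, stats::sd)
  if (metric == "signal_to_noise") {
    floor_sd <- function(s, m) pmax(s, 0.2 * abs(m), 1e-8)
    (m1 - m2) / (floor_sd(s1, m1) + floor_sd(s2, m2))
  } else {
    (m1 - m2) / sqrt(pmax(s1^2, 1e-16) / ncol(a) + pmax(s2^2, 1e-16) / ncol(b))
  }
}

# weighted KS enrichment score given metric sorted descending and the sorted
# positions of set members within that ordering
es_stat <- function(metric_sorted, hit_pos, weight_p) {
  n <- length(metric_sorted)
  nh <- length(hit_pos)
  w <- abs(metric_sorted[hit_pos])^weight_p
  sw <- sum(w)
  if (sw == 0) w <- rep(1 / nh, nh) else w <- w / sw
  run <- numeric(n)
  hit_inc <- numeric(n); hit_inc[hit_pos] <- w
  miss_inc <- rep(1 / (n - nh), n); miss_inc[hit_pos] <- 0
  run <- cumsum(hit_inc - miss_inc)
  run[which.max(abs(run))]
}

#' Filter a GSEA table at an FDR threshold
#'
#' @param x a `gsea_table`.
#' @param fdr_max maximum FDR to report (default 0.25).
#' @return The filtered tibble.
#' @export
significant_sets <- function(x, fdr_max = 0.25) {
  dplyr::filter(x, .data$fdr < fdr_max)
}
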