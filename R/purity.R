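#' Stromal/immune enrichment and tumor purity
#'
#' Stromal and immune scores are ssGSEA scores of the two signatures on the
#' supplied matrix (typically MAD-scaled; the scores are rank-based, so any
#' per-sample monotone normalization yields the same values). Purity is then
#' obtained from their sum via [purity_from_estimate()].
#'
#' @param x an [expr_matrix()].
#' @param stromal_set character vector of stromal signature genes.
#' @param immune_set character vector of immune signature genes.
#' @param alpha ssGSEA rank-weight exponent (default 0.25).
#' @return A tibble with columns `sample`, `stromal_score`, `immune_score`,
#'   `estimate_score`, `purity`, `purity_flag`.
#' @export
estimate_scores <- function(x, stromal_set, immune_set, alpha = 0.25) {
  stromal <- ssgsea_score(x, stromal_set, alpha = alpha)
  immune <- ssgsea_score(x, immune_set, alpha = alpha)
  est <- stromal + immune
  pur <- purity_from_estimate(est)
  tibble::tibble(
    sample = names(stromal),
    stromal_score = unname(stromal),
    immune_score = unname(immune),
    estimate_score = unname(est),
    purity = unname(pur$purity),
    purity_flag = unname(pur$flag)
  )
}

#' Cosine purity calibration
#'
#' Converts a combined stromal+immune enrichment score into a tumor purity
#' fraction with the published Affymetrix calibration
#' `purity = cos(0.6049872018 + 0.0001467884 * score)`. The cosine is only
#' meaningful while its argument stays in (0, pi): results falling outside
#' `[0, 1]` are clamped to the boundary and flagged, and arguments beyond pi
#' yield an undefined purity (`NA`) with flag `"out_of_domain"`.
#'
#' @param estimate_score numeric vector of combined scores.
#' @return A tibble with columns `estimate_score`, `purity`, `flag`
#'   (`"ok"`, `"clamped"`, or `"out_of_domain"`).
#' @export
purity_from_estimate <- function(estimate_score) {
  arg <- 0.6049872018 + 0.0001467884 * estimate_score
  purity <- cos(arg)
  flag <- rep("ok", length(arg))
  undef <- arg > pi
  clamp_hi <- !undef & purity > 1
  clamp_lo <- !undef & purity < 0
  purity[clamp_hi] <- 1
  purity[clamp_lo] <- 0
  purity[undef] <- NA_real_
  flag[clamp_hi | clamp_lo] <- "clamped"
  flag[undef] <- "out_of_domain"
  tibble::tibble(estimate_score = estimate_score, purity = purity, flag = flag)
}

#' Purity gate
#'
#' Retains samples whose inferred purity is strictly greater than the
#' threshold (the "over 60%" inclusion rule by default); samples with
#' undefined purity are excluded. Counts are reported via `message()`.
#'
#' @param purity_tbl tibble as returned by [estimate_scores()] with at least
#'   columns `sample` and `purity`.
#' @param threshold purity fraction (default 0.60).
#' @return Character vector of retained sample identifiers.
#' @export
filter_by_purity <- function(purity_tbl, threshold = 0.60) {
  stopifnot(all(c("sample", "purity") %in% names(purity_tbl)))
  keep <- !is.na(purity_tbl$purity) & purity_tbl$purity > threshold
  message(sum(keep), " of ", nrow(purity_tbl), " sample(s) pass purity > ",
          threshold, " (", sum(is.na(purity_tbl$purity)), " undefined)")
  purity_tbl$sample[keep]
}
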