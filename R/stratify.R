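#' CD4/CD8 lymphocyte infiltration scores
#'
#' ssGSEA scores of the CD4 and CD8 lymphocyte signatures plus a combined
#' lymphocyte score (the standardized average of the two), used both for
#' immune adjustment of CTLA-4 and for correlation with checkpoint
#' expression.
#'
#' @param x an [expr_matrix()].
#' @param cd4_set,cd8_set character vectors of signature genes.
#' @param alpha ssGSEA rank-weight exponent.
#' @return A tibble with columns `sample`, `cd4_score`, `cd8_score`,
#'   `lymphocyte_score`.
#' @export
infiltration_scores <- function(x, cd4_set, cd8_set, alpha = 0.25) {
  cd4 <- ssgsea_score(x, cd4_set, alpha = alpha)
  cd8 <- ssgsea_score(x, cd8_set, alpha = alpha)
  comb <- combine_axis_scores(cbind(cd4 = cd4, cd8 = cd8))
  tibble::tibble(
    sample = names(cd4),
    cd4_score = unname(cd4),
    cd8_score = unname(cd8),
    lymphocyte_score = unname(comb[names(cd4)])
  )
}

#' Immune adjustment of CTLA-4 expression
#'
#' Removes the contribution of residual immune infiltrate from measured
#' CTLA-4 by ordinary least squares of CTLA-4 on the combined stromal+immune
#' (ESTIMATE) score and the CD4/CD8 infiltration scores; the adjusted value
#' is the residual. `"interaction_expansion"` (the default) reads the model
#' as CD4 + CD8 + CD4:CD8 (R formula semantics of `CD4*CD8`);
#' `"product"` uses the single product covariate.
#'
#' @param data tibble with columns `sample`, `ctla4`, `estimate_score`,
#'   `cd4_score`, `cd8_score`.
#' @param mode `"interaction_expansion"` or `"product"`.
#' @param max_condition maximum allowed design-matrix condition number.
#' @return A `ctla4_adjustment` object; `tidy()` gives coefficients,
#'   `glance()` the fit summary, and `$data` the input with an `adjusted`
#'   column.
#' @export
adjust_ctla4 <- function(data, mode = c("interaction_expansion", "product"),
                         max_condition = 1e8) {
  mode <- match.arg(mode)
  need <- c("sample", "ctla4", "estimate_score", "cd4_score", "cd8_score")
  stopifnot(all(need %in% names(data)))
  form <- if (mode == "interaction_expansion") {
    ctla4 ~ estimate_score + cd4_score * cd8_score
  } else {
    ctla4 ~ estimate_score + I(cd4_score * cd8_score)
  }
  mm <- stats::model.matrix(form, data = data)
  if (nrow(mm) < ncol(mm) + 2L) {
    stop("need at least ", ncol(mm) + 2L, " samples for ", ncol(mm),
         " model terms", call. = FALSE)
  }
  sv <- svd(scale(mm[, -1L, drop = FALSE], scale = FALSE))$d
  if (min(sv) <= 0 || max(sv) / min(sv) > max_condition) {
    stop("collinear adjustment design (covariates: ",
         paste(colnames(mm)[-1L], collapse = ", "), ")", call. = FALSE)
  }
  fit <- stats::lm(form, data = data)
  out <- dplyr::mutate(data, adjusted = unname(stats::residuals(fit)))
  structure(list(fit = fit, mode = mode, data = out),
            class = "ctla4_adjustment")
}

#' @export
print.ctla4_adjustment <- function(x, ...) {
  cat("CTLA-4 immune adjustment (", x$mode, "), n = ",
      nrow(x$data), "\n", sep = "")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @method tidy ctla4_adjustment
#' @export
tidy.ctla4_adjustment <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, 1L],
    std.error = co[, 2L],
    statistic = co[, 3L],
    p.value = co[, 4L]
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @method glance ctla4_adjustment
#' @export
glance.ctla4_adjustment <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = nrow(x$data),
    mode = x$mode
  )
}

#' Median dichotomization
#'
#' Values strictly greater than the cohort median are `High`; values at or
#' below the median are `Low`.
#'
#' @param values numeric vector (length >= 2, not all equal).
#' @return Factor with levels `High`, `Low`, same length as `values`.
#' @export
dichotomize <- function(values) {
  stopifnot(length(values) >= 2L)
  if (length(unique(values)) == 1L) {
    stop("all values identical: no median split exists", call. = FALSE)
  }
  med <- stats::median(values)
  factor(ifelse(values > med, "High", "Low"), levels = c("High", "Low"))
}

#' Four-cluster assignment on the ERK1/2 and AKT axes
#'
#' The adjusted CTLA-4 value and each combined pathway score are dichotomized
#' at their within-cohort medians; a sample's cluster on an axis is the pair
#' (CTLA-4 status, pathway status), written `HH`, `HL`, `LH`, `LL`. The
#' "activated-like" phenotype is asymmetric between the axes: on ERK1/2 it is
#' `HH` (checkpoint high, cascade enriched), on AKT it is `HL` (checkpoint
#' high, pathway down-modulated).
#'
#' @param data tibble with columns `sample`, `adjusted_ctla4`, `erk_score`,
#'   `akt_score`.
#' @return A tibble adding `ctla4_status`, `erk_status`, `akt_status`,
#'   `erk_cluster`, `akt_cluster`, `activated_like_erk`, `activated_like_akt`.
#' @export
assign_clusters <- function(data) {
  need <- c("sample", "adjusted_ctla4", "erk_score", "akt_score")
  stopifnot(all(need %in% names(data)))
  lv <- c("HH", "HL", "LH", "LL")
  status_initial <- function(s) substr(as.character(s), 1L, 1L)
  out <- dplyr::mutate(
    data,
    ctla4_status = dichotomize(.data$adjusted_ctla4),
    erk_status = dichotomize(.data$erk_score),
    akt_status = dichotomize(.data$akt_score),
    erk_cluster = factor(paste0(status_initial(.data$ctla4_status),
                                status_initial(.data$erk_status)), levels = lv),
    akt_cluster = factor(paste0(status_initial(.data$ctla4_status),
                                status_initial(.data$akt_status)), levels = lv),
    activated_like_erk = .data$erk_cluster == "HH",
    activated_like_akt = .data$akt_cluster == "HL"
  )
  class(out) <- c("cluster_assignment", class(out))
  out
}
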