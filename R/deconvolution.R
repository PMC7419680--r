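#' Immune deconvolution by nu-support-vector regression
#'
#' Estimates relative immune cell-type proportions in bulk mixtures from a
#' gene-by-celltype signature matrix, in the CIBERSORT style: mixture and
#' reference are restricted to shared signature genes and z-scored over that
#' gene vector, a linear-kernel nu-SVR of the mixture on the reference
#' profiles is fitted for each value of the `nu` grid, negative coefficients
#' are truncated at zero and the rest renormalized to sum to one, and the
#' `nu` with the lowest root-mean-square error between the reconstructed and
#' observed mixture is kept. Significance comes from a shared permutation
#' null: the fit correlation of `n_perm` random permutations of mixture
#' values, with `p = fraction of null correlations >= observed`.
#'
#' @param x an [expr_matrix()] of bulk mixtures.
#' @param ref numeric gene-by-celltype signature matrix (row names are gene
#'   symbols, column names cell types).
#' @param nu_grid candidate nu values (default 0.25, 0.5, 0.75).
#' @param n_perm permutations for the null correlation (default 1000).
#' @param seed integer seed for the permutation null.
#' @param min_overlap minimum fraction of reference genes that must be
#'   present in the mixture matrix (default 0.5).
#' @return A `deconv_result`: list with `fractions` (samples x celltypes
#'   tibble) and `stats` (`sample`, `rmse`, `r`, `p`, `nu`).
#' @export
deconvolve <- function(x, ref, nu_grid = c(0.25, 0.5, 0.75), n_perm = 1000L,
                       seed = 1L, min_overlap = 0.5) {
  vals <- as_expr_values(x)
  ref <- as.matrix(ref)
  if (is.null(rownames(ref)) || is.null(colnames(ref))) {
    stop("signature matrix needs gene row names and celltype column names",
         call. = FALSE)
  }
  if (ncol(ref) < 2L) stop("need at least 2 cell types", call. = FALSE)
  rownames(ref) <- clean_symbols(rownames(ref))
  shared <- intersect(rownames(ref), rownames(vals))
  if (length(shared) < min_overlap * nrow(ref)) {
    stop("only ", length(shared), " of ", nrow(ref),
         " reference genes present in mixture (need >= ",
         ceiling(min_overlap * nrow(ref)), ")", call. = FALSE)
  }
  # global (whole-matrix) standardization preserves mixture weights exactly;
  # per-column scaling would re-weight cell types by their profile spread
  refs <- ref[shared, , drop = FALSE]
  refs <- (refs - mean(refs)) / stats::sd(refs)
  mix <- vals[shared, , drop = FALSE]

  fit_one <- function(y) {
    yz <- as.vector(scale(y))
    best <- NULL
    for (nu in nu_grid) {
      w <- svr_weights(refs, yz, nu)
      w[w < 0] <- 0
      if (sum(w) == 0) w <- rep(1 / ncol(refs), ncol(refs)) else w <- w / sum(w)
      fitted <- as.vector(refs %*% w)
      rmse <- sqrt(mean((fitted - yz)^2))
      if (is.null(best) || rmse < best$rmse) {
        best <- list(w = w, rmse = rmse, r = stats::cor(fitted, yz), nu = nu)
      }
    }
    best
  }

  fits <- lapply(seq_len(ncol(mix)), function(j) fit_one(mix[, j]))

  # shared null: correlations achieved by permuted mixtures drawn from the
  # pooled expression values, middle nu of the grid
  set.seed(seed)
  pool <- as.vector(mix)
  nu_null <- nu_grid[ceiling(length(nu_grid) / 2)]
  null_r <- vapply(seq_len(n_perm), function(b) {
    yz <- as.vector(scale(sample(pool, length(shared))))
    w <- svr_weights(refs, yz, nu_null)
    w[w < 0] <- 0
    if (sum(w) == 0) w <- rep(1 / ncol(refs), ncol(refs)) else w <- w / sum(w)
    stats::cor(as.vector(refs %*% w), yz)
  }, numeric(1L))

  frac <- do.call(rbind, lapply(fits, `[[`, "w"))
  colnames(frac) <- colnames(ref)
  fractions <- tibble::as_tibble(frac)
  fractions <- dplyr::bind_cols(tibble::tibble(sample = colnames(mix)), fractions)
  stats_tbl <- tibble::tibble(
    sample = colnames(mix),
    rmse = vapply(fits, `[[`, numeric(1L), "rmse"),
    r = vapply(fits, `[[`, numeric(1L), "r"),
    p = vapply(fits, function(f) mean(null_r >= f$r), numeric(1L)),
    nu = vapply(fits, `[[`, numeric(1L), "nu")
  )
  structure(list(fractions = fractions, stats = stats_tbl,
                 n_genes = length(shared), n_perm = n_perm),
            class = "deconv_result")
}

# linear nu-SVR coefficient vector over reference columns
svr_weights <- function(refs, yz, nu) {
  fit <- e1071::svm(x = refs, y = yz, type = "nu-regression",
                    kernel = "linear", nu = nu, cost = 1, scale = FALSE)
  as.vector(t(fit$coefs) %*% fit$SV)
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("deconv_result: %d sample(s), %d cell type(s), %d shared genes\n",
              nrow(x$fractions), ncol(x$fractions) - 1L, x$n_genes))
  invisible(x)
}

#' @method tidy deconv_result
#' @export
tidy.deconv_result <- function(x, ...) {
  long <- tidyr::pivot_longer(x$fractions, -"sample",
                              names_to = "celltype", values_to = "fraction")
  dplyr::left_join(long, x$stats, by = "sample")
}

#' @method glance deconv_result
#' @export
glance.deconv_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$fractions),
    n_celltypes = ncol(x$fractions) - 1L,
    n_genes = x$n_genes,
    median_rmse = stats::median(x$stats$rmse),
    median_r = stats::median(x$stats$r)
  )
}
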