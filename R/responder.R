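#' Train an anti-CTLA-4 responder classifier
#'
#' Linear-kernel support vector machine (`C = 1`) on standardized immune
#' score features, with seeded 5-fold cross-validated accuracy reported.
#'
#' @param features tibble or data frame of numeric feature columns plus a
#'   `sample` identifier column.
#' @param labels factor/character vector with two classes
#'   (`responder` / `non_responder`), one per row of `features`.
#' @param cost SVM regularization constant (default 1).
#' @param folds cross-validation folds (default 5).
#' @param seed seed for the fold split.
#' @return A `responder_model`; `glance()` reports the CV accuracy.
#' @export
train_responder <- function(features, labels, cost = 1, folds = 5L, seed = 1L) {
  fm <- feature_matrix(features)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  if (nrow(fm) != length(labels)) stop("one label per row required", call. = FALSE)
  if (nrow(fm) < 10L) stop("need at least 10 training samples", call. = FALSE)
  center <- colMeans(fm)
  scl <- apply(fm, 2L, stats::sd)
  scl[scl == 0] <- 1
  fs <- scale(fm, center = center, scale = scl)
  fit <- e1071::svm(x = fs, y = labels, type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(fs)))
  cv_hits <- vapply(seq_len(folds), function(k) {
    tr <- fold_id != k
    if (nlevels(droplevels(labels[tr])) < 2L) return(NA_real_)
    f <- e1071::svm(x = fs[tr, , drop = FALSE], y = labels[tr],
                    type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE)
    mean(stats::predict(f, fs[!tr, , drop = FALSE]) == labels[!tr]) * sum(!tr)
  }, numeric(1L))
  cv_acc <- sum(cv_hits, na.rm = TRUE) / nrow(fs)
  structure(list(fit = fit, center = center, scale = scl,
                 feature_names = colnames(fm), levels = levels(labels),
                 n = nrow(fs), cv_accuracy = cv_acc, seed = seed),
            class = "responder_model")
}

feature_matrix <- function(features) {
  df <- as.data.frame(features)
  if ("sample" %in% names(df)) {
    rn <- as.character(df$sample)
    df <- df[, setdiff(names(df), "sample"), drop = FALSE]
  } else {
    rn <- rownames(df)
  }
  fm <- as.matrix(df)
  if (!is.numeric(fm)) stop("feature columns must be numeric", call. = FALSE)
  rownames(fm) <- rn
  fm
}

#' @export
print.responder_model <- function(x, ...) {
  cat(sprintf("responder_model: linear SVM, n = %d, %d feature(s)\n",
              x$n, length(x$feature_names)))
  cat(sprintf("5-fold CV accuracy: %.3f\n", x$cv_accuracy))
  invisible(x)
}

#' @method glance responder_model
#' @export
glance.responder_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$feature_names),
                 cv_accuracy = x$cv_accuracy, kernel = "linear")
}

#' Predict responder labels
#'
#' @param model a [train_responder()] result.
#' @param features feature table whose columns must cover the model's
#'   training features (extra columns are ignored).
#' @return Factor of predicted class labels, named by sample when available.
#' @export
predict_responders <- function(model, features) {
  fm <- feature_matrix(features)
  missing <- setdiff(model$feature_names, colnames(fm))
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  fm <- fm[, model$feature_names, drop = FALSE]
  fs <- scale(fm, center = model$center, scale = model$scale)
  stats::predict(model$fit, fs)
}

#' Responder enrichment across clusters
#'
#' Tests whether predicted responders concentrate in particular clusters:
#' for each contrasted pair of cluster labels a 2x2 responder-by-cluster
#' table with Fisher's exact p, Benjamini-Hochberg adjusted across
#' contrasts.
#'
#' @param labels responder labels (factor/character), named by sample.
#' @param clusters an [assign_clusters()] result.
#' @param axis `"erk"` or `"akt"`.
#' @param contrasts list of cluster-label pairs to compare (default the
#'   activated-like contrast `HH` vs `HL`).
#' @param positive label counted as responder (default the label containing
#'   `"responder"` that is not `"non_responder"`, else the first level).
#' @return A tibble (`group1`, `group2`, `n1`, `n2`, `responders1`,
#'   `responders2`, `prop1`, `prop2`, `p`, `q`).
#' @export
responder_enrichment <- function(labels, clusters, axis = c("erk", "akt"),
                                 contrasts = list(c("HH", "HL")),
                                 positive = NULL) {
  axis <- match.arg(axis)
  col <- paste0(axis, "_cluster")
  lab <- as.character(labels)
  nm <- names(labels)
  if (is.null(nm)) {
    stopifnot(length(lab) == nrow(clusters))
    nm <- clusters$sample
  }
  if (is.null(positive)) {
    cand <- setdiff(unique(lab), "non_responder")
    positive <- if ("responder" %in% cand) "responder" else sort(cand)[1L]
  }
  grp <- as.character(clusters[[col]])
  names(grp) <- clusters$sample
  common <- intersect(nm, names(grp))
  lab <- stats::setNames(lab, nm)[common]; grp <- grp[common]
  rows <- purrr::map_dfr(contrasts, function(pair) {
    s1 <- grp == pair[1L]; s2 <- grp == pair[2L]
    if (sum(s1) == 0L || sum(s2) == 0L) {
      warning("empty cluster in contrast ", paste(pair, collapse = " vs "),
              "; skipped", call. = FALSE)
      return(tibble::tibble())
    }
    r1 <- sum(lab[s1] == positive); r2 <- sum(lab[s2] == positive)
    tab <- matrix(c(r1, sum(s1) - r1, r2, sum(s2) - r2), 2L, 2L)
    tibble::tibble(
      group1 = pair[1L], group2 = pair[2L],
      n1 = sum(s1), n2 = sum(s2),
      responders1 = r1, responders2 = r2,
      prop1 = r1 / sum(s1), prop2 = r2 / sum(s2),
      p = fisher_exact(tab)
    )
  })
  if (nrow(rows)) rows$q <- bh_adjust(rows$p)
  rows
}
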