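#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric genes-by-samples matrix that records
#' which normalization steps have been applied (`provenance`) and how many
#' gene rows were dropped for missing values at ingestion (`n_dropped`).
#' Gene symbols are uppercased and whitespace-stripped so that matrices from
#' different platforms share one symbol space.
#'
#' @param values numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names.
#' @param provenance character vector of normalization flags; any of
#'   `"collapsed"`, `"mad_scaled"`, `"median_centered"`, `"logcpm"`.
#' @param n_dropped number of gene rows removed because they contained
#'   missing values.
#'
#' @return An `expr_matrix`: the matrix with class and provenance attributes.
#' @export
expr_matrix <- function(values, provenance = character(), n_dropped = 0L) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and sample column names", call. = FALSE)
  }
  rownames(values) <- clean_symbols(rownames(values))
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  }
  drop <- apply(values, 1L, anyNA)
  n_dropped <- n_dropped + sum(drop)
  values <- values[!drop, , drop = FALSE]
  structure(values,
            provenance = unique(provenance),
            n_dropped = as.integer(n_dropped),
            class = c("expr_matrix", "matrix", "array"))
}

clean_symbols <- function(x) toupper(trimws(x))

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  prov <- attr(x, "provenance")
  cat("provenance:", if (length(prov)) paste(prov, collapse = ", ") else "<raw>", "\n")
  if (attr(x, "n_dropped") > 0L) {
    cat("rows dropped for missing values:", attr(x, "n_dropped"), "\n")
  }
  invisible(x)
}

add_provenance <- function(x, flag) {
  attr(x, "provenance") <- unique(c(attr(x, "provenance"), flag))
  x
}

#' @export
#' @rdname expr_matrix
provenance <- function(x) attr(x, "provenance")

as_expr_values <- function(x) {
  # strip class so plain matrix ops do not dispatch back here
  unclass(x)[, , drop = FALSE]
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' Tab-delimited input has a header row of sample identifiers and the gene
#' identifier in the first column. GCT 1.2 input has a `#1.2` line, a
#' dimensions line, and `Name`/`Description` columns before the samples.
#' Gene rows containing missing values are dropped and counted.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @return An [expr_matrix()] with empty provenance.
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || !identical(trimws(header[1L]), "#1.2")) {
      stop("malformed GCT: first line must be '#1.2' in ", path, call. = FALSE)
    }
    dims <- suppressWarnings(as.integer(strsplit(header[2L], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2])) {
      stop("malformed GCT: second line must give dimensions in ", path, call. = FALSE)
    }
    tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(tab) != dims[1L] || ncol(tab) - 2L != dims[2L]) {
      stop("GCT dimensions line does not match table in ", path, call. = FALSE)
    }
    ids <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  expr_matrix(vals)
}

#' Write an expression matrix
#'
#' Emits the same dialects [read_expression()] accepts.
#'
#' @param x an [expr_matrix()].
#' @param path output file path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  vals <- as_expr_values(x)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(vals), ncol(vals), sep = "\t")), con)
    tab <- data.frame(Name = rownames(vals), Description = rownames(vals),
                      vals, check.names = FALSE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene = rownames(vals), vals, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Collapse duplicate probes to gene symbols by interquartile range
#'
#' When several probes map to one gene symbol, the probe with the largest
#' across-sample interquartile range is kept; ties are broken by file order
#' (first probe wins). Probes absent from the map are dropped with a warning.
#'
#' @param x an [expr_matrix()] whose rows are probe identifiers.
#' @param probe_map data frame with columns `probe_id` and `symbol`.
#' @return An [expr_matrix()] with one row per gene symbol and provenance
#'   flag `"collapsed"`.
#' @export
collapse_probes <- function(x, probe_map) {
  stopifnot(all(c("probe_id", "symbol") %in% names(probe_map)))
  map <- probe_map
  # row identifiers are uppercased at ingestion; normalize the map to match
  map$probe_id <- clean_symbols(map$probe_id)
  map$symbol <- clean_symbols(map$symbol)
  if (any(map$symbol == "")) stop("empty gene symbols in probe map", call. = FALSE)
  if (anyDuplicated(map$probe_id)) {
    stop("probe map assigns some probes more than one symbol", call. = FALSE)
  }
  vals <- as_expr_values(x)
  idx <- match(rownames(vals), map$probe_id)
  unmapped <- sum(is.na(idx))
  if (unmapped > 0L) {
    warning(unmapped, " probe(s) absent from map dropped", call. = FALSE)
    vals <- vals[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  sym <- map$symbol[idx]
  iqr <- apply(vals, 1L, stats::IQR)
  ord <- seq_len(nrow(vals))
  # per symbol keep the probe with max IQR, first-in-file on ties
  keep <- vapply(split(ord, sym), function(rows) {
    rows[which.max(iqr[rows])]
  }, integer(1L))
  out <- vals[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  expr_matrix(out, provenance = c(provenance(x), "collapsed"),
              n_dropped = attr(x, "n_dropped"))
}

#' Per-sample median-absolute-deviation scaling
#'
#' Each sample column is centered at its median and divided by its MAD with
#' the 1.4826 normal-consistency constant, i.e. `mad(x)` in base R. Scaled
#' columns therefore have median 0 and consistent MAD 1.
#'
#' @param x an [expr_matrix()].
#' @return An [expr_matrix()] with provenance flag `"mad_scaled"`.
#' @export
mad_scale <- function(x) {
  vals <- as_expr_values(x)
  med <- apply(vals, 2L, stats::median)
  s <- apply(vals, 2L, stats::mad)
  if (any(s == 0)) {
    stop("zero MAD in sample(s): ",
         paste(colnames(vals)[s == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(vals, 2L, med, "-"), 2L, s, "/")
  expr_matrix(out, provenance = c(provenance(x), "mad_scaled"),
              n_dropped = attr(x, "n_dropped"))
}

#' Per-gene median centering
#'
#' @param x an [expr_matrix()].
#' @return An [expr_matrix()] with provenance flag `"median_centered"`.
#' @export
median_center <- function(x) {
  vals <- as_expr_values(x)
  out <- sweep(vals, 1L, apply(vals, 1L, stats::median), "-")
  expr_matrix(out, provenance = c(provenance(x), "median_centered"),
              n_dropped = attr(x, "n_dropped"))
}

#' Restrict matrices to their common genes
#'
#' Cross-platform analyses use only genes measured on every platform. All
#' matrices are restricted to the sorted intersection of their gene sets, in
#' the same order.
#'
#' @param matrices list of [expr_matrix()] objects (at least two).
#' @return List of restricted matrices, same length and order as the input.
#' @export
intersect_genes <- function(matrices) {
  stopifnot(length(matrices) >= 2L)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0L) stop("empty gene intersection", call. = FALSE)
  common <- sort(common)
  lapply(matrices, function(m) {
    expr_matrix(as_expr_values(m)[common, , drop = FALSE],
                provenance = provenance(m), n_dropped = attr(m, "n_dropped"))
  })
}

#' Transform raw counts to log2 counts-per-million
#'
#' A light-weight stand-in for count normalization of RNA-seq input:
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)`.
#'
#' @param x an [expr_matrix()] of non-negative raw counts.
#' @param prior pseudo-count added to every count (default 0.5).
#' @return An [expr_matrix()] with provenance flag `"logcpm"`.
#' @export
counts_to_logcpm <- function(x, prior = 0.5) {
  vals <- as_expr_values(x)
  if (any(vals < 0)) stop("negative counts", call. = FALSE)
  lib <- colSums(vals)
  out <- log2(sweep(vals + prior, 2L, lib + 2 * prior, "/") * 1e6)
  expr_matrix(out, provenance = c(provenance(x), "logcpm"),
              n_dropped = attr(x, "n_dropped"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy an expression matrix into long form
#'
#' @param x an [expr_matrix()].
#' @param ... unused.
#' @return A tibble with columns `gene`, `sample`, `value`.
#' @method tidy expr_matrix
#' @export
tidy.expr_matrix <- function(x, ...) {
  vals <- as_expr_values(x)
  tibble::tibble(
    gene = rep(rownames(vals), times = ncol(vals)),
    sample = rep(colnames(vals), each = nrow(vals)),
    value = as.vector(vals)
  )
}
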