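#' Gene set collections
#'
#' Gene sets are named character vectors of uppercased gene symbols grouped in
#' a `gene_set_collection`: a named list with a parallel `roles` attribute
#' tagging each set as one of `"erk_axis"`, `"akt_axis"`, `"immune_celltype"`,
#' `"signature"`, or `"generic"`.
#'
#' @param sets named list of character vectors.
#' @param roles character vector of role tags, recycled to `length(sets)`.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, roles = "generic") {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("all gene sets must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  roles <- rep_len(roles, length(sets))
  bad <- setdiff(roles, c("erk_axis", "akt_axis", "immune_celltype",
                          "signature", "generic"))
  if (length(bad)) stop("unknown role tag(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  sets <- lapply(sets, function(g) {
    g <- unique(clean_symbols(g))
    g[g != ""]
  })
  if (any(lengths(sets) == 0L)) stop("empty gene set(s)", call. = FALSE)
  structure(sets, roles = stats::setNames(roles, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s)\n", length(x)))
  for (nm in utils::head(names(x), 10L)) {
    cat(sprintf("  %s [%s]: %d genes\n", nm, attr(x, "roles")[[nm]], length(x[[nm]])))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  sets <- unclass(x)[i]
  gene_set_collection(sets, roles = attr(x, "roles")[names(sets)])
}

#' @export
#' @rdname gene_set_collection
set_roles <- function(x) attr(x, "roles")

#' Select sets by role tag
#'
#' @param x a [gene_set_collection()].
#' @param role role tag to keep.
#' @return A [gene_set_collection()] with only the matching sets.
#' @export
sets_with_role <- function(x, role) {
  keep <- names(x)[attr(x, "roles") == role]
  if (length(keep) == 0L) stop("no sets with role '", role, "'", call. = FALSE)
  x[keep]
}

#' Read gene sets from a GMT file
#'
#' Each line holds a set name, a description, and one or more gene symbols,
#' tab-separated. Duplicate genes within a line are dropped.
#'
#' @param path file path.
#' @param role role tag applied to every set in the file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, role = "generic") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(list(), roles = stats::setNames(character(), character()),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields", call. = FALSE)
  }
  nms <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nms)
  gene_set_collection(sets, roles = role)
}

#' Write gene sets to a GMT file
#'
#' @param x a [gene_set_collection()].
#' @param path output file path.
#' @param descriptions optional per-set description column (defaults to "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(x))
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], descriptions[i], x[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene sets to a measured-gene universe
#'
#' Each set is intersected with the genes actually present in the data; sets
#' that fall below `min_size` surviving genes are dropped with a message.
#' The operation is idempotent.
#'
#' @param x a [gene_set_collection()].
#' @param universe character vector of measured gene symbols.
#' @param min_size minimum surviving set size (default 5).
#' @return A [gene_set_collection()] (possibly empty).
#' @export
restrict_to_universe <- function(x, universe, min_size = 5L) {
  universe <- clean_symbols(universe)
  trimmed <- lapply(unclass(x), function(g) intersect(g, universe))
  keep <- lengths(trimmed) >= min_size
  if (any(!keep)) {
    message("dropped ", sum(!keep), " set(s) below min size ", min_size, ": ",
            paste(names(trimmed)[!keep], collapse = ", "))
  }
  structure(trimmed[keep],
            roles = attr(x, "roles")[names(trimmed)[keep]],
            class = "gene_set_collection")
}

#' @method tidy gene_set_collection
#' @export
tidy.gene_set_collection <- function(x, ...) {
  tibble::tibble(
    set = rep(names(x), lengths(x)),
    role = rep(unname(attr(x, "roles")), lengths(x)),
    gene = unlist(unclass(x), use.names = FALSE)
  )
}
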