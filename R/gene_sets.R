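#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (pathway name -> member gene
#'   symbols). Empty sets are not allowed.
#' @param universe Character vector of gene symbols forming the annotation
#'   universe; defaults to the union of the sets.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a non-empty named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  structure(list(sets = sets, universe = unique(as.character(universe))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (sizes %d-%d), universe %d genes\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              length(x$universe)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": needs name, description, >=1 gene")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  gene_set_collection(sets)
}

#' Write gene sets in GMT format
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @return Invisibly, `gsc`.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, "na", gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(gsc)
}
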