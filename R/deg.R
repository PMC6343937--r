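#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided WMW test of a location difference between two samples. The
#' p-value is exact (full enumeration of the rank-sum null) when the
#' combined sample size is at most 12 and there are no ties, and otherwise
#' uses the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return List with `U` (the Mann-Whitney U statistic for `a` over `b`)
#'   and `p` (two-sided p-value).
#' @examples
#' wmw_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
wmw_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("groups must not contain NA")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= 12
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values: monotone in p-rank, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("'pvalues' must be numeric")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes between two phenotype classes
#'
#' Per-gene two-sided WMW test across the two classes, BH adjustment across
#' all tested genes, and the joint significance rule p < 0.05 AND q < 0.25.
#' Direction is the sign of the median difference (second class level minus
#' first; with a control/disease factor this is disease minus control).
#'
#' @param ds An `expr_dataset`.
#' @param labels Per-sample phenotypes; defaults to the dataset's own
#'   labels. May be a named vector over the dataset's sample IDs. Both
#'   classes must be present — a single-class labeling signals a degenerate
#'   translation and is an error (callers score such runs with an empty
#'   predicted DEG set).
#' @return A data.frame of class `deg_table`: `gene`, `U`, `p`, `q`,
#'   `direction` (-1/0/1), `is_significant`.
#' @export
call_degs <- function(ds, labels = ds$labels) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids(ds), names(labels))
    if (length(missing))
      stop("no label for sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[sample_ids(ds)]
  }
  labels <- droplevels(factor(as.character(labels),
                              levels = if (is.factor(labels)) levels(labels)))
  if (length(labels) != ncol(ds$values))
    stop("need one label per sample")
  if (nlevels(labels) < 2)
    stop("differential expression requires both phenotype classes; ",
         "got only '", levels(labels), "'")
  ia <- labels == levels(labels)[2]      # second level (disease) vs first
  res <- apply(ds$values, 1, function(row) {
    t <- wmw_test(row[ia], row[!ia])
    c(t$U, t$p, sign(stats::median(row[ia]) - stats::median(row[!ia])))
  })
  out <- data.frame(gene = gene_ids(ds), U = res[1, ], p = res[2, ],
                    q = bh_fdr(res[2, ]), direction = res[3, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$is_significant <- out$p < 0.05 & out$q < 0.25
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Significant genes of a DEG table
#' @param degs A `deg_table`.
#' @return Character vector of significant gene symbols.
#' @export
deg_genes <- function(degs) degs$gene[degs$is_significant]

#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric (Fisher) test of DEG over-representation in each
#' gene set, against the measured-gene universe, with BH adjustment across
#' sets. Sets are first restricted to measured genes; restricted sets with
#' fewer than 3 members are skipped. Enrichment is called at q < 0.05.
#' Under-representation is never flagged.
#'
#' @param degs Character vector of DEG symbols (subset of `measured`). An
#'   empty DEG set yields an empty table, not an error.
#' @param gsc A `gene_set_collection`.
#' @param measured Character vector of all measured gene symbols (the
#'   universe for the test).
#' @return A data.frame of class `enrichment_table`: `set`, `overlap`,
#'   `set_size`, `universe_size`, `n_deg`, `p`, `q`, `is_enriched`.
#' @export
enrich <- function(degs, gsc, measured) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  degs <- unique(as.character(degs))
  measured <- unique(as.character(measured))
  bad <- setdiff(degs, measured)
  if (length(bad))
    stop("DEG(s) not in the measured universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  empty <- data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), universe_size = integer(0),
                      n_deg = integer(0), p = numeric(0), q = numeric(0),
                      is_enriched = logical(0), stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_table", "data.frame")
  if (!length(degs)) return(empty)
  sets <- lapply(gsc$sets, intersect, measured)
  sets <- sets[lengths(sets) >= 3]
  if (!length(sets)) return(empty)
  N <- length(measured)
  k <- length(degs)
  overlap <- vapply(sets, function(s) length(intersect(s, degs)), integer(1))
  size <- lengths(sets)
  ## P(X >= overlap), X ~ Hypergeometric(white = DEGs, black = rest, draws = set)
  p <- stats::phyper(overlap - 1, k, N - k, size, lower.tail = FALSE)
  out <- data.frame(set = names(sets), overlap = unname(overlap),
                    set_size = unname(size), universe_size = N, n_deg = k,
                    p = unname(p), q = bh_fdr(unname(p)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$is_enriched <- out$q < 0.05
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Enriched set names of an enrichment table
#' @param et An `enrichment_table`.
#' @return Character vector of enriched set names.
#' @export
enriched_sets <- function(et) et$set[et$is_enriched]
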