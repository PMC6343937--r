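#' Construct an expression dataset
#'
#' Bundles a gene-by-sample expression matrix with per-sample binary
#' phenotype labels. This is the unit both species' cohorts share after
#' homolog harmonization: rows are gene symbols (unique after
#' [collapse_duplicates()]), columns are samples, and every sample carries a
#' label from a two-level phenotype factor (conventionally control/disease,
#' with the disease class as the second level).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene symbols; column names are sample identifiers.
#' @param labels Character or factor of per-sample phenotypes, either in
#'   column order or named by sample identifier. Must have at most two
#'   distinct values; training functions additionally require both.
#' @param species `"mouse"` or `"human"`.
#' @param name Cohort name used in printing and manifests.
#' @return An object of class `expr_dataset`: a list with elements `values`,
#'   `labels` (factor), `species` and `name`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("ARG1", "LCN2", "TP53"), paste0("s", 1:4)))
#' ds <- expression_dataset(m, c("control", "control", "disease", "disease"),
#'                          species = "human", name = "toy")
#' ds
#' @export
expression_dataset <- function(values, labels, species = c("mouse", "human"),
                               name = "dataset") {
  species <- match.arg(species)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene symbols as row names and sample IDs as column names")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
      stop("no phenotype label for sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[colnames(values)]
  }
  if (length(labels) != ncol(values))
    stop("need one label per sample: ", length(labels), " labels for ",
         ncol(values), " samples")
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) > 2)
    stop("phenotype must be binary; got levels: ",
         paste(levels(labels), collapse = ", "))
  if (anyNA(values) || anyNA(labels))
    stop("expression values and labels must not contain NA")
  names(labels) <- colnames(values)
  structure(list(values = values, labels = labels,
                 species = species, name = name),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %s (%s): %d genes x %d samples\n",
              x$name, x$species, nrow(x$values), ncol(x$values)))
  print(table(phenotype = x$labels))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Gene identifiers of a dataset
#' @param ds An `expr_dataset`.
#' @return Character vector of gene symbols in row order.
#' @export
gene_ids <- function(ds) rownames(ds$values)

#' Sample identifiers of a dataset
#' @param ds An `expr_dataset`.
#' @return Character vector of sample IDs in column order.
#' @export
sample_ids <- function(ds) colnames(ds$values)

## Column subset preserving labels; internal.
subset_samples <- function(ds, idx) {
  expression_dataset(ds$values[, idx, drop = FALSE], ds$labels[idx],
                     species = ds$species, name = ds$name)
}

#' Read an expression matrix with its phenotype table
#'
#' The matrix is tab-separated text with a header row of sample IDs and gene
#' symbols in the first column (conventionally headed `gene`). The phenotype
#' table is two-column TSV (`sample_id`, `label`) and must cover every sample
#' in the matrix. Values are returned raw: duplicate gene rows are retained
#' (collapse them with [collapse_duplicates()]) and no scaling is applied
#' (see [zscore_by_gene()]).
#'
#' @param matrix_path Path to the expression TSV.
#' @param phenotype_path Path to the phenotype TSV.
#' @param species `"mouse"` or `"human"`.
#' @param name Cohort name; defaults to the matrix file name.
#' @return An `expr_dataset`.
#' @export
read_expression <- function(matrix_path, phenotype_path,
                            species = c("mouse", "human"), name = NULL) {
  species <- match.arg(species)
  if (!file.exists(matrix_path)) stop("expression matrix not found: ", matrix_path)
  if (!file.exists(phenotype_path)) stop("phenotype table not found: ", phenotype_path)
  raw <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("expression matrix needs a gene column and >= 1 sample column")
  genes <- raw[[1]]
  num <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at gene '%s' (row %d), sample '%s'",
                 genes[bad[1]], bad[1], colnames(num)[bad[2]]))
  }
  rownames(num) <- genes
  pheno <- utils::read.delim(phenotype_path, header = TRUE, check.names = FALSE,
                             colClasses = "character")
  if (ncol(pheno) < 2) stop("phenotype table must have columns sample_id, label")
  labels <- stats::setNames(pheno[[2]], pheno[[1]])
  expression_dataset(num, labels, species = species,
                     name = if (is.null(name)) basename(matrix_path) else name)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]: values round-trip exactly at full double
#' precision.
#'
#' @param ds An `expr_dataset`.
#' @param matrix_path,phenotype_path Output paths.
#' @return Invisibly, `ds`.
#' @export
write_expression <- function(ds, matrix_path, phenotype_path) {
  df <- data.frame(gene = gene_ids(ds),
                   format(ds$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("gene", sample_ids(ds))
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = sample_ids(ds),
                                label = as.character(ds$labels)),
                     phenotype_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ds)
}

#' Collapse duplicated gene rows
#'
#' For each gene symbol appearing more than once, retains the single row with
#' the maximum mean expression across all samples; ties keep the first
#' occurrence. Row order of the retained representatives follows first
#' occurrence in the input. Idempotent.
#'
#' @param ds An `expr_dataset` (typically freshly read, before scaling).
#' @return An `expr_dataset` with unique gene symbols.
#' @export
collapse_duplicates <- function(ds) {
  genes <- gene_ids(ds)
  if (!anyDuplicated(genes)) return(ds)
  means <- rowMeans(ds$values)
  keep <- vapply(split(seq_along(genes), factor(genes, levels = unique(genes))),
                 function(idx) idx[which.max(means[idx])], integer(1))
  keep <- sort(unname(keep))
  expression_dataset(ds$values[keep, , drop = FALSE], ds$labels,
                     species = ds$species, name = ds$name)
}

#' Z-score a dataset by gene
#'
#' Centers and scales each gene row to mean 0 and sample standard deviation 1
#' (n - 1 denominator) across the dataset's own samples. Genes with zero
#' variance carry no class signal; their rows are set to zero and a warning
#' names them. Idempotent within numerical tolerance.
#'
#' @param ds An `expr_dataset`.
#' @return An `expr_dataset` of the same shape with standardized rows.
#' @export
zscore_by_gene <- function(ds) {
  v <- ds$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  zero <- sdv < .Machine$double.eps * 100
  if (any(zero)) {
    warning("zero-variance gene(s) set to all zeros: ",
            paste(utils::head(gene_ids(ds)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) sprintf(" (and %d more)", sum(zero) - 5) else "")
    sdv[zero] <- 1
  }
  z <- (v - mu) / sdv
  z[zero, ] <- 0
  expression_dataset(z, ds$labels, species = ds$species, name = ds$name)
}

#' Read a mouse-to-human homology map
#'
#' Two-column TSV (`mouse_symbol`, `human_symbol`), one pair per line, as
#' exported from a homology database.
#'
#' @param path Path to the TSV.
#' @return A `homology_map`: data.frame with columns `mouse_symbol`,
#'   `human_symbol`.
#' @export
read_homology_map <- function(path) {
  if (!file.exists(path)) stop("homology map not found: ", path)
  hm <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(hm) < 2) stop("homology map must have columns mouse_symbol, human_symbol")
  homology_map(hm[[1]], hm[[2]])
}

#' Construct a homology map
#' @param mouse_symbol,human_symbol Equal-length character vectors of paired
#'   gene symbols.
#' @return A `homology_map` data.frame.
#' @export
homology_map <- function(mouse_symbol, human_symbol) {
  mouse_symbol <- as.character(mouse_symbol)
  human_symbol <- as.character(human_symbol)
  if (length(mouse_symbol) != length(human_symbol))
    stop("mouse and human symbol vectors must have equal length")
  if (any(!nzchar(mouse_symbol)) || any(!nzchar(human_symbol)))
    stop("homology map contains empty symbols")
  structure(data.frame(mouse_symbol = mouse_symbol, human_symbol = human_symbol),
            class = c("homology_map", "data.frame"))
}

#' Harmonize a mouse/human dataset pair into a shared homolog space
#'
#' Restricts the homology map to pairs measured in both datasets, enforces a
#' 1:1 mapping (among conflicting pairs sharing a mouse or human symbol, the
#' first-listed pair wins, with a warning), renames mouse rows to their human
#' homolog symbols, and reorders both matrices to the identical gene list
#' (ordered as in the human dataset). Both datasets should already be
#' duplicate-collapsed; z-scoring is deliberately left to the caller so each
#' cohort is standardized on its own samples after restriction.
#'
#' @param mouse,human `expr_dataset` objects with the matching `species`.
#' @param hm A `homology_map`.
#' @param disease Disease label for the pairing.
#' @param identifier Case-study identifier.
#' @return A `case_study` object (see [case_study()]).
#' @export
map_homologs <- function(mouse, human, hm, disease = "disease",
                         identifier = paste(mouse$name, human$name, sep = "->")) {
  stopifnot(inherits(mouse, "expr_dataset"), inherits(human, "expr_dataset"),
            inherits(hm, "homology_map"))
  if (mouse$species != "mouse" || human$species != "human")
    stop("arguments must be a mouse dataset and a human dataset, in that order")
  keep <- hm$mouse_symbol %in% gene_ids(mouse) & hm$human_symbol %in% gene_ids(human)
  hm <- hm[keep, , drop = FALSE]
  dup <- duplicated(hm$mouse_symbol) | duplicated(hm$human_symbol)
  if (any(dup)) {
    warning(sum(dup), " conflicting homolog pair(s) dropped (first-listed pair kept)")
    hm <- hm[!dup, , drop = FALSE]
  }
  if (nrow(hm) == 0)
    stop("no shared homologous genes between '", mouse$name, "' and '", human$name, "'")
  ## order by the human dataset's gene order for determinism
  ord <- order(match(hm$human_symbol, gene_ids(human)))
  hm <- hm[ord, , drop = FALSE]
  mv <- mouse$values[hm$mouse_symbol, , drop = FALSE]
  rownames(mv) <- hm$human_symbol
  hv <- human$values[hm$human_symbol, , drop = FALSE]
  case_study(expression_dataset(mv, mouse$labels, "mouse", mouse$name),
             expression_dataset(hv, human$labels, "human", human$name),
             disease = disease, identifier = identifier)
}

#' Construct a case study
#'
#' One (mouse training cohort, human test cohort) pairing over an identical
#' ordered gene list, the unit at which translation is fitted and scored.
#'
#' @param mouse,human Harmonized `expr_dataset` objects sharing the same
#'   ordered gene IDs.
#' @param disease Disease label.
#' @param identifier Case-study identifier string.
#' @return An object of class `case_study`.
#' @export
case_study <- function(mouse, human, disease = "disease", identifier = "cs") {
  stopifnot(inherits(mouse, "expr_dataset"), inherits(human, "expr_dataset"))
  if (mouse$species != "mouse" || human$species != "human")
    stop("case study needs a mouse training dataset and a human test dataset")
  if (!identical(gene_ids(mouse), gene_ids(human)))
    stop("mouse and human datasets must share an identical ordered gene list; ",
         "run map_homologs() first")
  structure(list(mouse = mouse, human = human, disease = disease,
                 identifier = identifier),
            class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("<case_study> %s (%s): %d shared genes\n", x$identifier,
              x$disease, nrow(x$mouse$values)))
  cat(sprintf("  mouse '%s': %d samples (%s)\n", x$mouse$name,
              ncol(x$mouse$values),
              paste(sprintf("%s=%d", levels(x$mouse$labels),
                            tabulate(x$mouse$labels)), collapse = ", ")))
  cat(sprintf("  human '%s': %d samples\n", x$human$name, ncol(x$human$values)))
  invisible(x)
}
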