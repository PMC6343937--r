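## Stratified, seeded cross-validation fold assignment keyed to sample IDs
## (not column positions), so permuting the columns of a dataset does not
## change any sample's fold.
stratified_folds <- function(labels, ids, nfolds, seed) {
  fold <- integer(length(labels))
  names(fold) <- ids
  for (li in seq_along(levels(labels))) {
    cls_ids <- sort(ids[labels == levels(labels)[li]])
    set.seed((seed + 7919L * li) %% .Machine$integer.max)
    perm <- sample(cls_ids)
    fold[perm] <- rep_len(seq_len(nfolds), length(perm))
  }
  fold
}

#' Select discriminative genes by penalized logistic regression
#'
#' Fits an elastic-net-penalized binomial regression of the phenotype on the
#' expression matrix over a geometric penalty path, choosing the penalty
#' weight that minimizes mean cross-validated deviance, and returns the genes
#' with nonzero coefficients at that optimum. `alpha = 1` is the Lasso;
#' smaller values mix in a ridge penalty and typically keep more genes.
#'
#' Cross-validation is stratified by class and seeded through sample IDs, so
#' the selected set does not depend on column order. When the smaller class
#' has fewer samples than `cv_folds` (or `cv_folds = "loo"`), leave-one-out
#' cross-validation is used instead — the regime of very small model-organism
#' cohorts. If the optimum keeps no genes, the 10 genes with the largest
#' absolute class-mean difference are returned as a fallback, with a loud
#' warning, so downstream training always has features.
#'
#' @param ds An `expr_dataset` (z-scored) with both phenotype classes present.
#' @param alpha Elastic-net mixing parameter in (0, 1].
#' @param cv_folds Number of CV folds (default 10) or `"loo"`.
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `feature_set`: list with `genes` (character),
#'   `coefficients` (named numeric, logistic scale), `alpha`,
#'   `lambda_selected`, and `fallback` (logical).
#' @export
select_features <- function(ds, alpha = 1, cv_folds = 10, seed = 1) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must be in (0, 1]")
  if (nlevels(droplevels(ds$labels)) < 2)
    stop("feature selection requires both phenotype classes in '", ds$name, "'")
  y <- droplevels(ds$labels)
  x <- t(ds$values)                       # samples x genes for glmnet
  n_min <- min(table(y))
  if (n_min < 2) stop("need >= 2 samples per class for cross-validation")
  loo <- identical(cv_folds, "loo") || n_min < cv_folds
  if (loo) {
    ord <- order(colnames(ds$values))
    foldid <- integer(ncol(ds$values))
    foldid[ord] <- seq_along(ord)         # leave-one-out, ID-keyed
  } else {
    foldid <- stratified_folds(y, sample_ids(ds), cv_folds, seed)
    foldid <- unname(foldid[sample_ids(ds)])
  }
  set.seed(seed %% .Machine$integer.max)
  cv <- tryCatch(
    suppressWarnings(glmnet::cv.glmnet(
      x, y, family = "binomial", alpha = alpha, foldid = foldid,
      type.measure = "deviance", standardize = FALSE, grouped = !loo)),
    error = function(e) NULL)            # e.g. every predictor zero-variance
  if (is.null(cv)) {
    beta <- stats::setNames(numeric(ncol(x)), colnames(x))
    lambda_min <- NA_real_
  } else {
    beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
    lambda_min <- unname(cv$lambda.min)
  }
  genes <- names(beta)[beta != 0]
  fallback <- FALSE
  if (!length(genes)) {
    warning("penalized regression selected no genes at the CV optimum; ",
            "falling back to the 10 genes with largest |class-mean difference|")
    fallback <- TRUE
    diffs <- rowMeans(ds$values[, y == levels(y)[2], drop = FALSE]) -
      rowMeans(ds$values[, y == levels(y)[1], drop = FALSE])
    genes <- gene_ids(ds)[order(-abs(diffs))][seq_len(min(10, nrow(ds$values)))]
    beta <- stats::setNames(diffs[match(genes, gene_ids(ds))], genes)
  }
  structure(list(genes = genes,
                 coefficients = beta[genes],
                 alpha = alpha,
                 lambda_selected = lambda_min,
                 fallback = fallback),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d genes (alpha = %g, lambda = %.4g%s)\n",
              length(x$genes), x$alpha, x$lambda_selected,
              if (x$fallback) ", univariate fallback" else ""))
  invisible(x)
}
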