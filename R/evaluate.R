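#' Confusion sets between a predicted and a truth set
#'
#' A predicted DEG or pathway is a true positive if it also appears in the
#' truth-phenotype analysis; predicted-only items are false positives and
#' truth-only items false negatives.
#'
#' @param predicted,truth Character vectors (treated as sets).
#' @return List with `tp`, `fp`, `fn` character vectors.
#' @export
confusion_sets <- function(predicted, truth) {
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  list(tp = intersect(predicted, truth),
       fp = setdiff(predicted, truth),
       fn = setdiff(truth, predicted))
}

#' Precision, recall and F-score from confusion counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F-score the harmonic mean
#' 2PR/(P+R); each is 0 when its denominator is 0.
#'
#' @param tp,fp,fn Sets (character vectors) or non-negative counts.
#' @return List with `precision`, `recall`, `fscore`.
#' @examples
#' prf(tp = 72, fp = 28, fn = 3)  # precision 0.72
#' @export
prf <- function(tp, fp, fn) {
  n <- vapply(list(tp, fp, fn), function(x)
    if (is.numeric(x) && length(x) == 1) as.numeric(x) else length(unique(x)),
    numeric(1))
  if (any(n < 0)) stop("counts must be non-negative")
  precision <- if (n[1] + n[2] > 0) n[1] / (n[1] + n[2]) else 0
  recall <- if (n[1] + n[3] > 0) n[1] / (n[1] + n[3]) else 0
  fscore <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, fscore = fscore)
}

#' Rank-based area under the ROC curve
#'
#' AUC computed as the Mann-Whitney U statistic divided by the number of
#' positive-negative pairs, with midranks for ties (ties count one half).
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Logical (or coercible) positive-class indicator.
#' @return AUC in \[0, 1\]; `NA` (with a warning) if only one class is
#'   present.
#' @examples
#' auc_score(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))  # 0.75
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("'scores' and 'labels' must be equal-length and NA-free")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined with a single class; returning NA")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score a set prediction against the truth-phenotype set
#'
#' @param predicted,truth Character vectors of symbols or set names.
#' @param level `"deg"` or `"pathway"` (annotation only).
#' @return An `eval_report`: list with `level`, the confusion sets, and
#'   `precision`, `recall`, `fscore`.
#' @export
eval_sets <- function(predicted, truth, level = c("deg", "pathway")) {
  level <- match.arg(level)
  cs <- confusion_sets(predicted, truth)
  m <- prf(cs$tp, cs$fp, cs$fn)
  structure(c(list(level = level), cs, m), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: TP=%d FP=%d FN=%d | P=%.3f R=%.3f F=%.3f\n",
              x$level, length(x$tp), length(x$fp), length(x$fn),
              x$precision, x$recall, x$fscore))
  invisible(x)
}

#' Evaluate a fitted translation against the true human phenotypes
#'
#' Recomputes the human differential-expression and pathway analysis twice —
#' once with the model-predicted phenotypes and once with the true
#' phenotypes — and scores the predicted DEG and enriched-pathway sets
#' against the truth-derived ones, plus the phenotype-level accuracy and
#' AUC. A translation that predicted a single class for every human sample
#' is scored with an empty predicted DEG set.
#'
#' @param fit A `translation`.
#' @param truth Named vector/factor of true human phenotypes.
#' @param gsc Optional `gene_set_collection`; pathway-level scoring is
#'   skipped when absent.
#' @return List with `deg` and (optionally) `pathway` `eval_report`s,
#'   `accuracy`, `auc`, and the underlying `predicted_degs` / `truth_degs`
#'   tables.
#' @export
evaluate_translation <- function(fit, truth, gsc = NULL) {
  stopifnot(inherits(fit, "translation"))
  human <- fit$case_study$human
  truth <- stats::setNames(as.character(truth[sample_ids(human)]),
                           sample_ids(human))
  truth_f <- factor(truth, levels = levels(fit$predicted_labels))
  truth_tab <- call_degs(human, truth_f)
  pred_genes <- character(0)
  pred_tab <- NULL
  if (nlevels(droplevels(fit$predicted_labels)) == 2) {
    pred_tab <- call_degs(human, fit$predicted_labels)
    pred_genes <- deg_genes(pred_tab)
  }
  out <- list(deg = eval_sets(pred_genes, deg_genes(truth_tab), "deg"),
              accuracy = mean(fit$predicted_labels == truth_f),
              auc = auc_score(fit$scores,
                              truth_f == levels(truth_f)[2]),
              predicted_degs = pred_tab, truth_degs = truth_tab)
  if (!is.null(gsc)) {
    measured <- gene_ids(human)
    pred_path <- enriched_sets(enrich(pred_genes, gsc, measured))
    truth_path <- enriched_sets(enrich(deg_genes(truth_tab), gsc, measured))
    out$pathway <- eval_sets(pred_path, truth_path, "pathway")
  }
  out
}

#' Score the mouse cohort's own DEGs/pathways against the human truth
#'
#' The baseline modality: genes (and pathways) implicated by differential
#' expression in the mouse cohort, using the mouse's true phenotypes, scored
#' against the human truth-phenotype analysis.
#'
#' @param cs A `case_study`.
#' @param gsc Optional `gene_set_collection` for pathway-level scoring.
#' @return List with `deg` and (optionally) `pathway` `eval_report`s plus
#'   the underlying DEG tables.
#' @export
evaluate_mouse_direct <- function(cs, gsc = NULL) {
  stopifnot(inherits(cs, "case_study"))
  mouse_tab <- call_degs(cs$mouse)
  human_tab <- call_degs(cs$human)
  out <- list(deg = eval_sets(deg_genes(mouse_tab), deg_genes(human_tab), "deg"),
              mouse_degs = mouse_tab, truth_degs = human_tab)
  if (!is.null(gsc)) {
    measured <- gene_ids(cs$human)
    mouse_path <- enriched_sets(enrich(deg_genes(mouse_tab), gsc, measured))
    truth_path <- enriched_sets(enrich(deg_genes(human_tab), gsc, measured))
    out$pathway <- eval_sets(mouse_path, truth_path, "pathway")
  }
  out
}

#' Enumerate a benchmarking grid of classifier configurations
#'
#' Cartesian product of classifier family, training mode, elastic-net alpha
#' and case study, in stable row order (case study slowest, alpha fastest),
#' with a deterministic per-cell seed derived from the master seed.
#'
#' @param families Character vector of classifier families.
#' @param modes Character vector of training modes.
#' @param alphas Numeric vector of elastic-net mixing values.
#' @param case_studies Character vector of case-study identifiers (or a list
#'   of `case_study` objects, whose identifiers are used).
#' @param seed Master seed for per-cell seed derivation.
#' @return A data.frame with one row per configuration: `case_study`,
#'   `family`, `mode`, `alpha`, `cell`, `seed`.
#' @examples
#' nrow(grid_registry(c("knn", "svm", "rf", "nn"), c("supervised", "semi"),
#'                    c(1, 0.9, 0.7, 0.5, 0.3, 0.1),
#'                    paste0("cs", 1:36)))  # 1728
#' @export
grid_registry <- function(families, modes, alphas, case_studies, seed = 1) {
  if (is.list(case_studies))
    case_studies <- vapply(case_studies, function(cs) cs$identifier, character(1))
  for (ax in list(families, modes, alphas, case_studies))
    if (!length(ax)) stop("every grid axis must be non-empty")
  g <- expand.grid(alpha = alphas, mode = modes, family = families,
                   case_study = case_studies,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("case_study", "family", "mode", "alpha")]
  g$cell <- seq_len(nrow(g))
  g$seed <- derive_seed(seed, g$cell)
  g
}

## Deterministic per-cell seed stream: an affine map on the cell index,
## kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483647L)
}

#' Linear-model meta-analysis of grid performance
#'
#' Ordinary least squares of a performance response (e.g. DEG F-score or
#' AUC) on dummy-coded classifier family, numeric alpha, and any further
#' design covariates (e.g. training sample size, class imbalance), with
#' per-coefficient two-sided t-tests. A rank-deficient design is an error
#' naming the collinear columns.
#'
#' @param grid Data.frame with one row per configuration, containing the
#'   response and the covariates.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate column names; factors are
#'   dummy-coded. Each modeled factor must have at least 2 observed levels.
#' @return A data.frame with `term`, `estimate`, `std_error`, `t_value`,
#'   `p_value`, plus attribute `"model"` holding the `lm` fit.
#' @export
meta_analyze <- function(grid, response = "fscore",
                         covariates = c("family", "alpha")) {
  stopifnot(is.data.frame(grid))
  missing <- setdiff(c(response, covariates), names(grid))
  if (length(missing))
    stop("column(s) not in grid: ", paste(missing, collapse = ", "))
  for (cv in covariates) {
    v <- grid[[cv]]
    if (!is.numeric(v) && length(unique(v)) < 2)
      stop("covariate '", cv, "' has fewer than 2 levels")
  }
  fml <- stats::reformulate(covariates, response)
  fit <- stats::lm(fml, data = grid)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), estimate = cf[, 1],
                    std_error = cf[, 2], t_value = cf[, 3], p_value = cf[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "model") <- fit
  out
}

#' Percentile-bootstrap 95% confidence interval of a mean
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return List with `lo`, `hi`, `mean`.
#' @export
summarize_ci <- function(values, n_boot = 10000, seed = 1) {
  if (length(values) < 2) stop("need at least 2 values for a bootstrap CI")
  set.seed(seed %% .Machine$integer.max)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(sample(values, replace = TRUE)), numeric(1))
  qs <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  list(lo = qs[1], hi = qs[2], mean = mean(values))
}

#' Paired comparison of per-case-study F-scores between two families
#'
#' Two-sided Wilcoxon signed-rank test on per-case-study score differences,
#' the default test for claims that one family outperforms another across a
#' shared set of case studies.
#'
#' @param grid Data.frame with columns `case_study`, `family`, and the score.
#' @param family_a,family_b The two families to compare.
#' @param score Score column name.
#' @return List with `median_a`, `median_b`, `p`.
#' @export
compare_families <- function(grid, family_a, family_b, score = "fscore") {
  a <- grid[grid$family == family_a, c("case_study", score)]
  b <- grid[grid$family == family_b, c("case_study", score)]
  shared <- intersect(a$case_study, b$case_study)
  if (length(shared) < 2) stop("need >= 2 shared case studies")
  av <- a[[score]][match(shared, a$case_study)]
  bv <- b[[score]][match(shared, b$case_study)]
  ht <- suppressWarnings(stats::wilcox.test(av, bv, paired = TRUE))
  list(median_a = stats::median(av), median_b = stats::median(bv),
       p = ht$p.value)
}
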