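#' Translate mouse phenotype structure onto a human cohort
#'
#' The central fitting function. Given a harmonized case study (mouse
#' training cohort, human test cohort over the same ordered gene list), fits
#' either a supervised translation — feature selection and classifier
#' training on the mouse cohort alone, applied once to label every human
#' sample — or the transductive semi-supervised variant, in which the
#' unlabeled human cohort is folded into training under a descending
#' confidence-percentile schedule:
#'
#' 1. Select features and train on the mouse cohort alone; predict all human
#'    samples.
#' 2. Merge the human samples at or above the 90th percentile of prediction
#'    confidence into the training set, carrying their predicted
#'    (pseudo-)labels.
#' 3. Each subsequent iteration re-selects features on the augmented set,
#'    retrains, re-predicts *all* human samples, and recomputes the merged
#'    set at a threshold lowered by 10 percentile points (80th, 70th, ...).
#'    Merged membership and pseudo-labels are refreshed every iteration
#'    (mouse samples are never dropped), but the merged count never
#'    decreases: samples tied at the cutoff are all admitted, and if a
#'    fresh confidence distribution would admit fewer samples than are
#'    already merged, the highest-confidence samples top the set up to the
#'    previous count.
#' 4. The loop terminates at the iteration whose threshold admits every
#'    human sample (at most 10 iterations); the labels from that final
#'    prediction are the output.
#'
#' For the neural network family, the first iteration is guarded against
#' degenerate starts: training is restarted with fresh weight
#' initializations until more than one human sample is predicted into each
#' class, up to 50 attempts (see [nn_restart_guard()]).
#'
#' @param cs A `case_study` (see [map_homologs()] / [case_study()]). Both
#'   datasets should already be z-scored by gene.
#' @param family Classifier family: `"knn"`, `"svm"`, `"rf"` or `"nn"`.
#' @param mode `"semi"` (transductive self-training, the default) or
#'   `"supervised"`.
#' @param alpha Elastic-net mixing parameter for feature selection; 1 is the
#'   Lasso. The grid studied for benchmarking is
#'   `c(1, 0.9, 0.7, 0.5, 0.3, 0.1)`.
#' @param cv_folds CV folds for feature selection (default 10; `"loo"`
#'   forces leave-one-out, which is also used automatically when the smaller
#'   class is below `cv_folds`).
#' @param seed Integer seed; every stochastic step derives its own stream
#'   from it.
#' @return An object of class `translation`: list with `predicted_labels`
#'   (named factor over human samples), `scores` (continuous score toward
#'   the second class, for ROC analysis), `trace` (one row per iteration:
#'   `iteration`, `threshold_pct`, `n_merged`, `n_features`, plus
#'   list-columns `merged_ids`, `merged_labels`), `final_features`
#'   (`feature_set`), `classifier` (`phenofit`), `family`, `mode`, `alpha`,
#'   `seed`, `case_study` and `call`.
#' @seealso [evaluate_translation()] for DEG/pathway-level scoring,
#'   [predict.translation()], [summary.translation()].
#' @examples
#' sim <- generate_case_study(sim_config(n_genes = 80, n_shared_deg = 8,
#'                                       seed = 7))
#' fit <- translate(sim$case_study, family = "knn", mode = "semi", seed = 7)
#' fit
#' @export
translate <- function(cs, family = c("nn", "knn", "svm", "rf"),
                      mode = c("semi", "supervised"),
                      alpha = 1, cv_folds = 10, seed = 1) {
  stopifnot(inherits(cs, "case_study"))
  family <- match.arg(family)
  mode <- match.arg(mode)
  human <- cs$human
  n_human <- ncol(human$values)
  classes <- levels(droplevels(cs$mouse$labels))
  if (length(classes) < 2)
    stop("mouse training cohort must contain both phenotype classes")

  merged_ids <- character(0)
  merged_labels <- factor(character(0), levels = classes)
  trace <- list()
  fs <- NULL; clf <- NULL; pred <- NULL

  for (i in seq_len(10)) {
    iter_seed <- (seed + 101L * i) %% .Machine$integer.max
    train <- augment_training(cs$mouse, human, merged_ids, merged_labels)
    fs <- select_features(train, alpha = alpha, cv_folds = cv_folds,
                          seed = iter_seed)
    if (family == "nn" && i == 1L) {
      fitpred <- nn_guarded_first_fit(train, fs, human, iter_seed)
      clf <- fitpred$clf; pred <- fitpred$pred
    } else {
      clf <- train_classifier(train, fs, family, seed = iter_seed)
      pred <- stats::predict(clf, human)
    }
    if (mode == "supervised") {
      trace[[1]] <- iteration_record(1L, NA_real_, sample_ids(human),
                                     pred$label, fs)
      break
    }
    threshold_pct <- 100 - 10 * i
    cutoff <- stats::quantile(pred$confidence, threshold_pct / 100,
                              names = FALSE, type = 7)
    admit <- pred$confidence >= cutoff
    ## the merged set is refreshed each iteration, but never shrinks: if the
    ## new confidence distribution admits fewer samples than are already
    ## merged (possible when ties dominate one iteration), extend with the
    ## next-highest-confidence samples up to the previous count
    if (sum(admit) < length(merged_ids)) {
      ord <- order(-pred$confidence)
      admit <- seq_along(pred$confidence) %in% ord[seq_len(length(merged_ids))]
    }
    merged_ids <- pred$sample_id[admit]
    merged_labels <- factor(as.character(pred$label[admit]), levels = classes)
    trace[[i]] <- iteration_record(i, threshold_pct, merged_ids,
                                   merged_labels, fs)
    if (length(merged_ids) == n_human) break
  }

  structure(list(
    predicted_labels = stats::setNames(factor(as.character(pred$label),
                                              levels = classes),
                                       pred$sample_id),
    scores = stats::setNames(pred$score, pred$sample_id),
    confidence = stats::setNames(pred$confidence, pred$sample_id),
    trace = do.call(rbind, trace),
    final_features = fs,
    classifier = clf,
    family = family, mode = mode, alpha = alpha, seed = seed,
    case_study = cs,
    call = match.call()),
    class = "translation")
}

iteration_record <- function(i, threshold_pct, merged_ids, merged_labels, fs) {
  data.frame(iteration = i, threshold_pct = threshold_pct,
             n_merged = length(merged_ids), n_features = length(fs$genes),
             merged_ids = I(list(as.character(merged_ids))),
             merged_labels = I(list(as.character(merged_labels))))
}

## Mouse cohort plus currently merged human samples with their pseudo-labels.
augment_training <- function(mouse, human, merged_ids, merged_labels) {
  if (!length(merged_ids)) return(mouse)
  hv <- human$values[, merged_ids, drop = FALSE]
  ids <- merged_ids
  clash <- ids %in% sample_ids(mouse)
  if (any(clash)) {
    ids[clash] <- paste0("human:", ids[clash])
    colnames(hv) <- ids
  }
  expression_dataset(cbind(mouse$values, hv),
                     factor(c(as.character(mouse$labels),
                              as.character(merged_labels)),
                            levels = levels(mouse$labels)),
                     species = "mouse", name = paste0(mouse$name, "+human"))
}

#' First-iteration restart guard for the neural network
#'
#' Network training is stochastic in its weight initialization, and a bad
#' start can collapse the first round of human predictions onto (almost) a
#' single class, which would poison the self-training loop. The guard
#' decides whether a first-iteration prediction is usable: proceed if more
#' than one human sample is predicted into *each* class, otherwise retry
#' with a fresh initialization — up to 50 attempts, after which the last
#' model is used regardless.
#'
#' @param predictions Factor or character vector of predicted human labels.
#' @param attempt_count Number of training attempts made so far (>= 1).
#' @param classes The two class labels (defaults to the levels of
#'   `predictions`).
#' @return `"proceed"` or `"retry"`.
#' @examples
#' nn_restart_guard(rep(c("a", "b"), c(5, 5)), 1)   # "proceed"
#' nn_restart_guard(rep(c("a", "b"), c(9, 1)), 1)   # "retry"
#' nn_restart_guard(rep("a", 10), 50)               # "proceed" (attempts spent)
#' @export
nn_restart_guard <- function(predictions, attempt_count,
                             classes = levels(factor(predictions))) {
  counts <- table(factor(as.character(predictions), levels = classes))
  if (all(counts > 1) || attempt_count >= 50) "proceed" else "retry"
}

nn_guarded_first_fit <- function(train, fs, human, iter_seed) {
  classes <- levels(droplevels(train$labels))
  for (attempt in seq_len(50)) {
    clf <- train_nn(train, fs,
                    seed = (iter_seed + 1000L * attempt) %% .Machine$integer.max)
    pred <- stats::predict(clf, human)
    if (nn_restart_guard(pred$label, attempt, classes) == "proceed")
      return(list(clf = clf, pred = pred, attempts = attempt))
  }
}

#' @export
print.translation <- function(x, ...) {
  cat(sprintf("<translation> %s %s (alpha = %g) on case study '%s'\n",
              if (x$mode == "semi") "semi-supervised" else "supervised",
              toupper(x$family), x$alpha, x$case_study$identifier))
  cat(sprintf("  %d iteration(s); final feature set: %d genes\n",
              nrow(x$trace), length(x$final_features$genes)))
  print(table(predicted = x$predicted_labels))
  invisible(x)
}

#' Summarize a fitted translation
#'
#' @param object A `translation`.
#' @param truth Optional named vector/factor of true human phenotypes; when
#'   supplied, accuracy and AUC against the truth are reported.
#' @param ... Unused.
#' @return An object of class `summary.translation` printed as a compact
#'   report; invisibly a list with the iteration trace and, if `truth` was
#'   given, `accuracy` and `auc`.
#' @export
summary.translation <- function(object, truth = NULL, ...) {
  out <- list(fit = object,
              trace = object$trace[, c("iteration", "threshold_pct",
                                       "n_merged", "n_features")])
  if (!is.null(truth)) {
    truth <- factor(as.character(truth[names(object$predicted_labels)]),
                    levels = levels(object$predicted_labels))
    out$accuracy <- mean(object$predicted_labels == truth)
    out$auc <- auc_score(object$scores,
                         truth == levels(object$predicted_labels)[2])
  }
  class(out) <- "summary.translation"
  out
}

#' @export
print.summary.translation <- function(x, ...) {
  print(x$fit)
  cat("iteration trace:\n")
  print(x$trace, row.names = FALSE)
  if (!is.null(x$accuracy))
    cat(sprintf("vs truth phenotypes: accuracy = %.3f, AUC = %.3f\n",
                x$accuracy, x$auc))
  invisible(x)
}

#' Predicted human phenotypes (or predictions on new samples)
#'
#' @param object A `translation`.
#' @param newdata Optional `expr_dataset` or matrix over the case study's
#'   gene space; by default the human cohort's final predictions are
#'   returned.
#' @param ... Unused.
#' @return A data.frame with `sample_id`, `label`, `confidence`, `score`.
#' @export
predict.translation <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(data.frame(sample_id = names(object$predicted_labels),
                      label = unname(object$predicted_labels),
                      confidence = unname(object$confidence),
                      score = unname(object$scores),
                      stringsAsFactors = FALSE))
  stats::predict(object$classifier, newdata)
}

#' Final selected feature genes and their penalized-regression coefficients
#' @param object A `translation`.
#' @param ... Unused.
#' @return Named numeric vector of logistic-scale coefficients, one per
#'   selected gene, from the final iteration's feature selection.
#' @export
coef.translation <- function(object, ...) object$final_features$coefficients

#' Plot the self-training trajectory
#'
#' Merged human sample count and selected feature count per iteration.
#'
#' @param x A `translation`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.translation <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$iteration, cbind(tr$n_merged, tr$n_features),
                    type = "b", pch = c(16, 1), lty = 1,
                    xlab = "iteration", ylab = "count", ...)
  graphics::legend("topleft", legend = c("merged human samples",
                                         "selected features"),
                   pch = c(16, 1), bty = "n")
  invisible(x)
}
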