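#' Hidden-layer size for the feed-forward network
#'
#' One hidden layer sized as the average of the input and output node counts,
#' rounded up to the nearest integer; the output layer always has two nodes
#' (one per phenotype class).
#'
#' @param n_input Number of input features.
#' @param n_output Number of output nodes (default 2).
#' @return Integer hidden-layer size.
#' @examples
#' nn_hidden_size(5)  # 4
#' nn_hidden_size(2)  # 2
#' @export
nn_hidden_size <- function(n_input, n_output = 2) {
  stopifnot(n_input >= 1)
  as.integer(ceiling((n_input + n_output) / 2))
}

#' Train a phenotype classifier
#'
#' Fits one of the four classifier families on the selected feature genes of
#' a training dataset. All families share a prediction contract (see
#' [predict.phenofit()]): a hard label from the two training classes, a
#' confidence in \[0, 1\] used for ranking within a prediction batch, and a
#' continuous score oriented toward the second class level (used for ROC
#' analysis).
#'
#' Family-specific fixed hyperparameters:
#' \describe{
#'   \item{knn}{k = 3 nearest training samples by Euclidean distance;
#'     confidence is the fraction of the 3 neighbors voting the predicted
#'     label (2/3 or 1). Distance ties are broken by training sample order.}
#'   \item{svm}{linear-kernel maximum-margin classifier; confidence is the
#'     within-batch rank of |decision value| rescaled to \[0, 1\].}
#'   \item{rf}{bagged ensemble of 50 trees, sqrt(p) candidate features per
#'     split; confidence is the fraction of trees voting the predicted
#'     label.}
#'   \item{nn}{feed-forward network with one hidden layer of
#'     [nn_hidden_size()] units and 2 softmax output nodes, trained by
#'     batch quasi-Newton (BFGS) optimization of the cross-entropy loss,
#'     at most 500 iterations; confidence is the larger output.}
#' }
#'
#' @param ds Training `expr_dataset` with both classes present.
#' @param features A `feature_set` or character vector of gene symbols.
#' @param family One of `"knn"`, `"svm"`, `"rf"`, `"nn"`.
#' @param seed Integer seed (consumed by the stochastic families rf and nn).
#' @return An object of class `phenofit`.
#' @export
train_classifier <- function(ds, features, family = c("knn", "svm", "rf", "nn"),
                             seed = 1) {
  family <- match.arg(family)
  switch(family,
         knn = train_knn(ds, features),
         svm = train_svm(ds, features),
         rf  = train_rf(ds, features, seed),
         nn  = train_nn(ds, features, seed))
}

feature_genes <- function(features, ds) {
  genes <- if (inherits(features, "feature_set")) features$genes
           else as.character(features)
  missing <- setdiff(genes, gene_ids(ds))
  if (length(missing))
    stop("feature gene(s) not in dataset: ", paste(utils::head(missing, 5), collapse = ", "))
  genes
}

training_xy <- function(ds, features) {
  genes <- feature_genes(features, ds)
  y <- droplevels(ds$labels)
  if (nlevels(y) < 2)
    stop("training requires both phenotype classes in '", ds$name, "'")
  list(x = t(ds$values[genes, , drop = FALSE]), y = y, genes = genes)
}

new_phenofit <- function(family, genes, classes, state) {
  structure(list(family = family, feature_genes = genes,
                 classes = classes, state = state),
            class = "phenofit")
}

#' @rdname train_classifier
#' @export
train_knn <- function(ds, features) {
  d <- training_xy(ds, features)
  if (nrow(d$x) < 3) stop("KNN with k = 3 needs at least 3 training samples")
  new_phenofit("knn", d$genes, levels(d$y),
               list(train = d$x, labels = d$y, k = 3L))
}

#' @rdname train_classifier
#' @export
train_svm <- function(ds, features) {
  d <- training_xy(ds, features)
  fit <- e1071::svm(d$x, d$y, kernel = "linear", scale = FALSE)
  new_phenofit("svm", d$genes, levels(d$y), list(fit = fit))
}

#' @rdname train_classifier
#' @export
train_rf <- function(ds, features, seed = 1) {
  d <- training_xy(ds, features)
  set.seed(seed %% .Machine$integer.max)
  fit <- randomForest::randomForest(d$x, d$y, ntree = 50)
  new_phenofit("rf", d$genes, levels(d$y), list(fit = fit))
}

#' @rdname train_classifier
#' @export
train_nn <- function(ds, features, seed = 1) {
  d <- training_xy(ds, features)
  size <- nn_hidden_size(ncol(d$x))
  set.seed(seed %% .Machine$integer.max)
  fit <- nnet::nnet(d$x, nnet::class.ind(d$y), size = size, softmax = TRUE,
                    maxit = 500, abstol = 1e-6, trace = FALSE,
                    MaxNWts = 1e5)
  if (!is.null(fit$convergence) && fit$convergence == 1)
    warning("network training hit the 500-iteration cap; using best-so-far weights")
  new_phenofit("nn", d$genes, levels(d$y), list(fit = fit))
}

#' @export
print.phenofit <- function(x, ...) {
  cat(sprintf("<phenofit> %s on %d feature genes; classes: %s\n",
              toupper(x$family), length(x$feature_genes),
              paste(x$classes, collapse = " / ")))
  invisible(x)
}

#' Predict phenotypes with a trained classifier
#'
#' @param object A `phenofit`.
#' @param newdata An `expr_dataset`, or a numeric matrix with either genes in
#'   rows (gene symbols as row names) or samples in rows matching the feature
#'   genes.
#' @param ... Unused.
#' @return A data.frame with one row per sample: `sample_id`, `label`
#'   (predicted class), `confidence` in \[0, 1\] (comparable within this
#'   batch; used for ranking), and `score` (continuous score toward the
#'   second class level, for ROC analysis).
#' @export
predict.phenofit <- function(object, newdata, ...) {
  x <- prediction_matrix(object, newdata)
  out <- switch(object$family,
                knn = predict_knn(object, x),
                svm = predict_svm(object, x),
                rf  = predict_rf(object, x),
                nn  = predict_nn(object, x))
  data.frame(sample_id = rownames(x),
             label = factor(out$label, levels = object$classes),
             confidence = out$confidence,
             score = out$score,
             row.names = NULL, stringsAsFactors = FALSE)
}

prediction_matrix <- function(object, newdata) {
  if (inherits(newdata, "expr_dataset")) {
    x <- t(newdata$values[object$feature_genes, , drop = FALSE])
  } else if (is.matrix(newdata)) {
    if (all(object$feature_genes %in% rownames(newdata)))
      x <- t(newdata[object$feature_genes, , drop = FALSE])
    else if (all(object$feature_genes %in% colnames(newdata)))
      x <- newdata[, object$feature_genes, drop = FALSE]
    else stop("newdata does not contain all feature genes")
  } else stop("newdata must be an expr_dataset or a matrix")
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  x
}

predict_knn <- function(object, x) {
  tr <- object$state$train
  lab <- object$state$labels
  k <- object$state$k
  cls <- object$classes
  n <- nrow(x)
  label <- character(n); confidence <- numeric(n); score <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(tr) - x[i, ])^2)
    nb <- lab[order(d2)[seq_len(k)]]      # order() breaks ties by sample order
    votes <- table(factor(nb, levels = cls))
    label[i] <- cls[which.max(votes)]
    confidence[i] <- max(votes) / k
    score[i] <- votes[[cls[2]]] / k
  }
  list(label = label, confidence = confidence, score = score)
}

predict_svm <- function(object, x) {
  pred <- stats::predict(object$state$fit, x, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  ## decision-value column is named "first/second"; positive means the class
  ## left of the slash, so orient the score toward classes[2]
  dv_name <- colnames(attr(pred, "decision.values"))[1]
  toward_first <- identical(strsplit(dv_name, "/", fixed = TRUE)[[1]][1],
                            object$classes[1])
  score <- if (toward_first) -dv else dv
  n <- length(dv)
  confidence <- if (n == 1) 1 else (rank(abs(dv), ties.method = "average") - 1) / (n - 1)
  list(label = as.character(pred), confidence = confidence, score = score)
}

predict_rf <- function(object, x) {
  votes <- stats::predict(object$state$fit, x, type = "vote", norm.votes = TRUE)
  votes <- votes[, object$classes, drop = FALSE]
  idx <- max.col(votes, ties.method = "first")
  list(label = object$classes[idx],
       confidence = votes[cbind(seq_len(nrow(votes)), idx)],
       score = votes[, object$classes[2]])
}

predict_nn <- function(object, x) {
  p <- stats::predict(object$state$fit, x, type = "raw")
  p <- p / rowSums(p)                     # softmax outputs; renormalize defensively
  colnames(p) <- object$classes
  idx <- max.col(p, ties.method = "first")
  list(label = object$classes[idx],
       confidence = p[cbind(seq_len(nrow(p)), idx)],
       score = p[, object$classes[2]])
}
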