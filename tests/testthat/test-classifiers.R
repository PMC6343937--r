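## 1-D training geometry with known neighborhoods for the KNN contract.
knn_fixture <- function() {
  v <- matrix(c(0, 0.1, 0.2, 10, 10.1), 1, 5,
              dimnames = list("g1", paste0("s", 1:5)))
  make_dataset(v, c("A", "A", "A", "B", "B"))
}

test_that("KNN votes give the closed-form confidences", {
  ds <- knn_fixture()
  fit <- train_knn(ds, "g1")
  q <- matrix(c(0.05, 9.9), 1, 2, dimnames = list("g1", c("q1", "q2")))
  pred <- predict(fit, q)
  expect_identical(as.character(pred$label), c("A", "B"))
  expect_equal(pred$confidence, c(1, 2 / 3))      # (A,A,A) and (B,B,A)
  expect_true(all(pred$confidence %in% c(2 / 3, 1)))
})

test_that("KNN needs at least 3 training samples", {
  v <- matrix(c(0, 1), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_error(train_knn(make_dataset(v, c("A", "B")), "g1"), "at least 3")
})

test_that("linear SVM separates separable clusters and ranks confidence by margin", {
  set.seed(4)
  v <- rbind(g1 = c(rnorm(10, -3), rnorm(10, 3)),
             g2 = rnorm(20))
  colnames(v) <- sprintf("s%02d", 1:20)
  ds <- make_dataset(v, rep(c("A", "B"), each = 10))
  fit <- train_svm(ds, c("g1", "g2"))
  pred <- predict(fit, ds)
  expect_identical(as.character(pred$label), as.character(ds$labels))

  ## a boundary point cannot out-rank off-boundary points
  q <- matrix(c(0, 0, -3, 0, 3, 0), 2, 3,
              dimnames = list(c("g1", "g2"), c("onb", "offA", "offB")))
  pq <- predict(fit, q)
  expect_lte(pq$confidence[1], min(pq$confidence[2:3]))
  expect_true(all(pq$confidence >= 0 & pq$confidence <= 1))
})

test_that("SVM survives contradictory duplicated samples at chance accuracy", {
  v <- matrix(c(1, 1, -1, -1, 0.5, -0.5), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  ds <- make_dataset(v, c("A", "B", "A", "B", "A", "B"))
  fit <- train_svm(ds, "g1")
  pred <- predict(fit, ds)
  dup_acc <- mean(as.character(pred$label[1:4]) == c("A", "B", "A", "B"))
  expect_equal(dup_acc, 0.5)
})

test_that("random forest confidence is a 50-tree vote fraction in [0.5, 1]", {
  sim <- planted_dataset(n_genes = 50, n_info = 10, shift = 2,
                         n_per_class = c(15, 15), seed = 11)
  fit <- train_rf(sim$ds, sim$informative, seed = 11)
  pred <- predict(fit, sim$ds)
  expect_true(all(pred$confidence >= 0.5 & pred$confidence <= 1))
  expect_true(all(abs(pred$confidence * 50 - round(pred$confidence * 50)) < 1e-9))

  pred2 <- predict(train_rf(sim$ds, sim$informative, seed = 11), sim$ds)
  expect_identical(pred$label, pred2$label)       # seeded determinism
  expect_equal(pred$confidence, pred2$confidence)
})

test_that("random forest learns planted signal", {
  accs <- vapply(1:10, function(s) {
    sim <- planted_dataset(n_genes = 100, n_info = 20, shift = 2,
                           n_per_class = c(20, 20), seed = 300 + s)
    fit <- train_rf(sim$ds, sim$informative, seed = s)
    mean(as.character(predict(fit, sim$ds)$label) == as.character(sim$ds$labels))
  }, numeric(1))
  expect_gte(median(accs), 0.9)
})

test_that("network hidden layer is the rounded-up mean of input and output sizes", {
  expect_identical(nn_hidden_size(5), 4L)   # ceil(7/2)
  expect_identical(nn_hidden_size(2), 2L)   # ceil(4/2)
  expect_identical(nn_hidden_size(1), 2L)
  expect_identical(nn_hidden_size(100), 51L)
})

test_that("the network has capacity for an XOR arrangement", {
  set.seed(9)
  centers <- cbind(c(-2, -2), c(2, 2), c(-2, 2), c(2, -2))
  v <- do.call(cbind, lapply(1:4, function(k)
    centers[, k] + matrix(rnorm(2 * 8, sd = 0.3), 2)))
  dimnames(v) <- list(c("g1", "g2"), sprintf("s%02d", 1:32))
  ds <- make_dataset(v, rep(c("A", "A", "B", "B"), each = 8))
  best <- max(vapply(1:5, function(s) {
    fit <- train_nn(ds, c("g1", "g2"), seed = s)
    mean(as.character(predict(fit, ds)$label) == as.character(ds$labels))
  }, numeric(1)))
  expect_gte(best, 0.95)
})

test_that("all families predict only training classes with confidences in [0, 1]", {
  sim <- planted_dataset(n_genes = 40, n_info = 8, shift = 2,
                         n_per_class = c(10, 10), seed = 21)
  q <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(gene_ids(sim$ds), paste0("q", 1:6)))
  for (fam in c("knn", "svm", "rf", "nn")) {
    fit <- train_classifier(sim$ds, sim$informative, fam, seed = 2)
    pred <- predict(fit, q)
    expect_true(all(as.character(pred$label) %in% c("control", "disease")),
                info = fam)
    expect_true(all(pred$confidence >= 0 & pred$confidence <= 1), info = fam)
  }
})

test_that("single-class training data is rejected by every family", {
  v <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  ds <- make_dataset(v, rep("disease", 5))
  for (fam in c("knn", "svm", "rf", "nn"))
    expect_error(train_classifier(ds, paste0("g", 1:4), fam),
                 "both phenotype classes", info = fam)
})
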