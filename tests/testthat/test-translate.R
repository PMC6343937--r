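test_that("supervised translation recovers shared-signal human phenotypes", {
  accs <- vapply(1:10, function(s) {
    sim <- generate_case_study(sim_config(n_genes = 150, n_shared_deg = 15,
                                          effect_mouse = 2, effect_human = 2,
                                          n_mouse_per_class = c(20, 20),
                                          n_human_per_class = c(20, 20),
                                          seed = 400 + s))
    fit <- translate(sim$case_study, family = "rf", mode = "supervised",
                     alpha = 1, seed = s)
    expect_equal(nrow(fit$trace), 1L)
    mean(fit$predicted_labels == sim$case_study$human$labels)
  }, numeric(1))
  expect_gte(median(accs), 0.9)
})

test_that("self-translation is no worse than training accuracy", {
  sim <- planted_dataset(n_genes = 120, n_info = 15, shift = 2,
                         n_per_class = c(15, 15), seed = 33, species = "mouse")
  mouse <- sim$ds
  human_twin <- expression_dataset(mouse$values, mouse$labels,
                                   species = "human", name = "twin")
  cs <- case_study(mouse, human_twin, identifier = "self")
  fit <- translate(cs, family = "rf", mode = "supervised", seed = 3)
  train_pred <- predict(fit$classifier, mouse)
  train_acc <- mean(as.character(train_pred$label) == as.character(mouse$labels))
  human_acc <- mean(fit$predicted_labels == human_twin$labels)
  expect_gte(human_acc, train_acc - 0.05)
})

test_that("a single-class mouse cohort cannot train a translation", {
  sim <- generate_case_study(sim_config(n_genes = 60, n_shared_deg = 6, seed = 2))
  cs <- sim$case_study
  one_class <- expression_dataset(cs$mouse$values,
                                  rep("disease", ncol(cs$mouse$values)),
                                  species = "mouse")
  expect_error(translate(case_study(one_class, cs$human), family = "knn"),
               "both phenotype classes")
})

test_that("the confidence schedule descends by 10 points and merges monotonically", {
  sim <- generate_case_study(sim_config(n_genes = 100, n_shared_deg = 10,
                                        effect_mouse = 1.2, effect_human = 1.2,
                                        n_mouse_per_class = c(8, 8),
                                        n_human_per_class = c(5, 5), seed = 5))
  fit <- translate(sim$case_study, family = "svm", mode = "semi", seed = 5)
  tr <- fit$trace
  expect_lte(nrow(tr), 10)
  expect_identical(tr$threshold_pct, 90 - 10 * (tr$iteration - 1))
  expect_true(all(diff(tr$n_merged) >= 0))
  expect_equal(tr$n_merged[nrow(tr)], 10)
  expect_length(fit$predicted_labels, 10)
})

test_that("a one-sample human cohort merges immediately", {
  sim <- generate_case_study(sim_config(n_genes = 80, n_shared_deg = 8, seed = 8))
  cs <- sim$case_study
  human1 <- expression_dataset(cs$human$values[, 1, drop = FALSE],
                               cs$human$labels[1], species = "human")
  fit <- translate(case_study(cs$mouse, human1), family = "knn",
                   mode = "semi", seed = 8)
  expect_equal(nrow(fit$trace), 1L)
  expect_equal(fit$trace$n_merged, 1L)
})

test_that("self-training surfaces human-only signal genes in the final feature set", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_scenario("divergent", seed = 500 + s)
    fit <- translate(sim$case_study, family = "nn", mode = "semi",
                     alpha = 1, seed = s)
    length(intersect(fit$final_features$genes, sim$truth$human_only_degs)) >= 1
  }, logical(1))
  expect_gte(sum(hits), 7)
})

test_that("the network restart guard demands more than one sample per class", {
  expect_identical(nn_restart_guard(rep(c("A", "B"), c(5, 5)), 1), "proceed")
  expect_identical(nn_restart_guard(rep(c("A", "B"), c(9, 1)), 1,
                                    classes = c("A", "B")), "retry")
  expect_identical(nn_restart_guard(rep("A", 10), 1, classes = c("A", "B")),
                   "retry")
  expect_identical(nn_restart_guard(rep("A", 10), 50, classes = c("A", "B")),
                   "proceed")
})

test_that("translation objects expose methods for inspection and prediction", {
  sim <- generate_case_study(sim_config(n_genes = 80, n_shared_deg = 10,
                                        seed = 12))
  fit <- translate(sim$case_study, family = "rf", mode = "semi", seed = 12)
  expect_s3_class(fit, "translation")
  expect_output(print(fit), "semi-supervised RF")
  sm <- summary(fit, truth = sim$case_study$human$labels)
  expect_output(print(sm), "accuracy")
  expect_gte(sm$accuracy, 0)

  pred <- predict(fit)
  expect_identical(nrow(pred), ncol(sim$case_study$human$values))
  newpred <- predict(fit, sim$case_study$mouse)
  expect_true(all(as.character(newpred$label) %in% c("control", "disease")))

  cf <- coef(fit)
  expect_identical(names(cf), fit$final_features$genes)
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
})

test_that("translation is reproducible from its seed", {
  sim <- generate_case_study(sim_config(n_genes = 80, n_shared_deg = 8, seed = 6))
  f1 <- translate(sim$case_study, family = "nn", mode = "semi", seed = 99)
  f2 <- translate(sim$case_study, family = "nn", mode = "semi", seed = 99)
  expect_identical(f1$predicted_labels, f2$predicted_labels)
  expect_identical(f1$final_features$genes, f2$final_features$genes)
  expect_equal(f1$scores, f2$scores)
})
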