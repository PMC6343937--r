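test_that("confusion sets follow the TP/FP/FN definitions", {
  cs <- confusion_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(cs$tp, c("b", "c"))
  expect_identical(cs$fp, "a")
  expect_identical(cs$fn, "d")

  cs0 <- confusion_sets(character(0), c("x", "y"))
  expect_length(cs0$tp, 0); expect_length(cs0$fp, 0)
  expect_setequal(cs0$fn, c("x", "y"))

  eq <- confusion_sets(c("p", "q"), c("p", "q"))
  expect_length(eq$fp, 0); expect_length(eq$fn, 0)
})

test_that("precision/recall/F-score follow the harmonic-mean formulas", {
  ## the sepsis pathway operating point: P = 0.72, R = 0.96
  m <- prf(tp = 72, fp = 28, fn = 3)
  expect_equal(m$precision, 0.72)
  expect_equal(m$recall, 0.96)
  expect_equal(m$fscore, 2 * 0.72 * 0.96 / (0.72 + 0.96), tolerance = 1e-12)
  expect_equal(round(m$fscore, 4), 0.8229)

  z <- prf(0, 0, 0)
  expect_equal(unlist(z), c(precision = 0, recall = 0, fscore = 0))

  half <- prf(tp = 5, fp = 5, fn = 5)
  expect_equal(half$fscore, 0.5)        # harmonic-mean fixed point
})

test_that("AUC is the tie-corrected rank statistic", {
  expect_equal(auc_score(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_warning(a <- auc_score(1:4, rep(TRUE, 4)), "single class")
  expect_true(is.na(a))
})

test_that("AUC and F-score match brute-force reimplementations on random instances", {
  set.seed(16)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))   # both classes guaranteed
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)

    ntp <- sample(0:20, 1); nfp <- sample(0:20, 1); nfn <- sample(0:20, 1)
    m <- prf(ntp, nfp, nfn)
    expect_equal(c(m$precision, m$recall, m$fscore),
                 oracle_prf(ntp, nfp, nfn), tolerance = 1e-12)
  }
})

test_that("the grid registry enumerates the full configuration product", {
  reg <- grid_registry(c("knn", "svm", "rf", "nn"), c("supervised", "semi"),
                       c(1, 0.9, 0.7, 0.5, 0.3, 0.1), paste0("cs", 1:36))
  expect_identical(nrow(reg), 1728L)
  expect_identical(anyDuplicated(reg$seed), 0L)
  expect_true(all(reg$seed >= 0 & reg$seed < 2^31))

  expect_identical(nrow(grid_registry("nn", "semi", 1, "cs1")), 1L)
  expect_error(grid_registry(character(0), "semi", 1, "cs1"), "non-empty")

  set.seed(17)
  for (i in 1:10) {
    axes <- lapply(1:4, function(j) paste0("v", seq_len(sample(1:5, 1))))
    expect_identical(nrow(grid_registry(axes[[1]], axes[[2]],
                                        seq_along(axes[[3]]), axes[[4]])),
                     as.integer(prod(lengths(axes))))
  }
})

test_that("mouse-direct scoring agrees with an independently coded scoring path", {
  sim <- generate_case_study(sim_config(n_genes = 150, n_shared_deg = 15,
                                        n_mouse_only_deg = 10,
                                        effect_mouse = 2.5, effect_human = 2.5,
                                        n_mouse_per_class = c(15, 15),
                                        n_human_per_class = c(15, 15),
                                        seed = 23))
  ev <- evaluate_mouse_direct(sim$case_study, sim$gene_sets)

  ## second path: recompute both DEG sets and score with raw set algebra
  mouse_set <- with(call_degs(sim$case_study$mouse), gene[p < 0.05 & q < 0.25])
  human_set <- with(call_degs(sim$case_study$human), gene[p < 0.05 & q < 0.25])
  ntp <- length(intersect(mouse_set, human_set))
  nfp <- length(setdiff(mouse_set, human_set))
  nfn <- length(setdiff(human_set, mouse_set))
  expect_setequal(ev$deg$tp, intersect(mouse_set, human_set))
  expect_equal(c(ev$deg$precision, ev$deg$recall, ev$deg$fscore),
               oracle_prf(ntp, nfp, nfn), tolerance = 1e-12)
})

test_that("the grid meta-analysis detects a planted alpha effect", {
  detected <- vapply(1:20, function(s) {
    set.seed(800 + s)
    g <- expand.grid(family = c("knn", "svm", "rf", "nn"),
                     alpha = c(1, 0.9, 0.7, 0.5, 0.3, 0.1),
                     rep = 1:5, stringsAsFactors = FALSE)
    g$fscore <- 0.1 * g$alpha + rnorm(nrow(g), sd = 0.05)
    tab <- meta_analyze(g, "fscore", c("family", "alpha"))
    row <- tab[tab$term == "alpha", ]
    row$estimate > 0 && row$p_value < 0.05
  }, logical(1))
  expect_gte(sum(detected), 18)
})

test_that("meta-analysis rejects degenerate designs", {
  g <- data.frame(family = "nn", alpha = runif(20), fscore = runif(20))
  expect_error(meta_analyze(g, "fscore", c("family", "alpha")),
               "fewer than 2 levels")
  g2 <- data.frame(family = rep(c("a", "b"), 10), alpha = 0.5,
                   alpha2 = 0.5, fscore = runif(20))
  expect_error(meta_analyze(g2, "fscore", c("family", "alpha", "alpha2")),
               "collinear")
})

test_that("bootstrap confidence intervals behave on degenerate and Bernoulli input", {
  ci <- summarize_ci(rep(0.4, 10), n_boot = 200, seed = 1)
  expect_equal(ci$lo, 0.4); expect_equal(ci$hi, 0.4); expect_equal(ci$mean, 0.4)

  ci2 <- summarize_ci(rep(c(0, 1), 50), n_boot = 2000, seed = 2)
  expect_gt(ci2$lo, 0.3); expect_lt(ci2$hi, 0.7)
  expect_true(ci2$lo < 0.5 && ci2$hi > 0.5)

  expect_error(summarize_ci(1), "at least 2")
})

test_that("paired family comparison runs on a shared case-study panel", {
  set.seed(19)
  g <- data.frame(case_study = rep(paste0("cs", 1:8), 2),
                  family = rep(c("nn", "knn"), each = 8),
                  fscore = c(runif(8, 0.5, 0.9), runif(8, 0.1, 0.5)))
  cmp <- compare_families(g, "nn", "knn")
  expect_gt(cmp$median_a, cmp$median_b)
  expect_lt(cmp$p, 0.05)
})
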