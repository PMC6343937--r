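test_that("generation is fully reproducible from its seed", {
  cfg <- sim_config(n_genes = 100, n_shared_deg = 10, n_human_only_deg = 5,
                    seed = 31)
  s1 <- generate_case_study(cfg)
  s2 <- generate_case_study(cfg)
  expect_identical(s1$case_study$mouse$values, s2$case_study$mouse$values)
  expect_identical(s1$case_study$human$values, s2$case_study$human$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$gene_sets$sets, s2$gene_sets$sets)
})

test_that("truth sets are disjoint and human truth is shared plus human-only", {
  sim <- generate_case_study(sim_config(n_genes = 200, n_shared_deg = 12,
                                        n_mouse_only_deg = 8,
                                        n_human_only_deg = 15, seed = 32))
  tr <- sim$truth
  expect_length(intersect(tr$shared_degs, tr$mouse_only_degs), 0)
  expect_length(intersect(tr$shared_degs, tr$human_only_degs), 0)
  expect_length(intersect(tr$mouse_only_degs, tr$human_only_degs), 0)
  expect_setequal(tr$human_truth_degs, union(tr$shared_degs, tr$human_only_degs))
})

test_that("a null configuration produces calibrated false-positive rates", {
  sim <- generate_case_study(sim_config(n_genes = 200, n_shared_deg = 0,
                                        n_human_only_deg = 0,
                                        n_mouse_only_deg = 0, seed = 33))
  expect_length(sim$truth$human_truth_degs, 0)
  expect_length(sim$truth$true_pathways, 0)
  tab <- call_degs(sim$case_study$human)
  expect_lte(mean(tab$p < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("planted true pathways are genuinely enriched for human truth DEGs", {
  sim <- generate_case_study(sim_config(n_genes = 250, n_shared_deg = 15,
                                        n_human_only_deg = 20, seed = 34))
  et <- enrich(sim$truth$human_truth_degs, sim$gene_sets,
               gene_ids(sim$case_study$human))
  expect_true(all(sim$truth$true_pathways %in% enriched_sets(et)))
})

test_that("the easy-transfer regime gives high mouse-direct DEG F-scores", {
  fscores <- vapply(1:10, function(s) {
    sim <- generate_case_study(sim_config(n_genes = 200, n_shared_deg = 20,
                                          effect_mouse = 2.5, effect_human = 2.5,
                                          n_mouse_per_class = c(40, 40),
                                          n_human_per_class = c(40, 40),
                                          seed = 900 + s))
    evaluate_mouse_direct(sim$case_study)$deg$fscore
  }, numeric(1))
  expect_gte(median(fscores), 0.6)
})

test_that("the scenario library covers the four study regimes", {
  lib <- scenario_library()
  expect_setequal(names(lib), c("easy_transfer", "divergent",
                                "imbalanced_mouse", "heterogeneous_mouse"))
  expect_true(all(vapply(lib, inherits, logical(1), "sim_config")))

  het <- simulate_scenario("heterogeneous_mouse", seed = 3)
  ids <- sample_ids(het$case_study$mouse)
  expect_true(any(startsWith(ids, "m1_")) && any(startsWith(ids, "m2_")))

  imb <- scenario_library()$imbalanced_mouse
  expect_identical(imb$n_mouse_per_class, c(4L, 16L))

  expect_error(simulate_scenario("no_such"), "unknown scenario")
})

test_that("divergent mouse-direct analysis misses nearly all human truth DEGs", {
  recalls <- vapply(1:10, function(s) {
    sim <- simulate_scenario("divergent", seed = 1000 + s)
    evaluate_mouse_direct(sim$case_study)$deg$recall
  }, numeric(1))
  expect_lte(median(recalls), 0.15)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_genes = 10, n_shared_deg = 20), "exceed")
  expect_error(sim_config(n_mouse_per_class = c(0, 5)), ">= 1")
  expect_error(sim_config(noise_sd = 0), "positive")
  expect_error(sim_config(deg_pathway_purity = 1.5), "purity")
  expect_error(sim_config(pathway_size = 1000, n_genes = 100), "exceeds")
})

test_that("simulated case studies serialize to the package's file formats", {
  sim <- generate_case_study(sim_config(n_genes = 60, n_shared_deg = 6,
                                        n_human_only_deg = 4, seed = 35))
  dir <- withr::local_tempdir()
  paths <- write_case_study(sim, dir)
  expect_true(all(file.exists(paths)))

  mouse <- read_expression(paths["mouse_matrix"], paths["mouse_pheno"], "mouse")
  human <- read_expression(paths["human_matrix"], paths["human_pheno"], "human")
  expect_equal(mouse$values, sim$case_study$mouse$values, tolerance = 1e-12)
  expect_identical(gene_ids(human), gene_ids(sim$case_study$human))
  hm <- read_homology_map(paths["homology"])
  expect_identical(hm$mouse_symbol, hm$human_symbol)  # identity map by design
  gsc <- read_gmt(paths["gmt"])
  expect_identical(gsc$sets, sim$gene_sets$sets)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_setequal(truth$human_truth_degs, sim$truth$human_truth_degs)
})
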