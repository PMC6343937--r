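## FNV-1a hash of a deparsed R object; used to stamp manifests so a resumed
## run can detect a changed configuration.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the 'yaml' package; use JSON instead")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

load_case_study_from_config <- function(cfg) {
  if (!is.null(cfg$scenario)) {
    sim <- simulate_scenario(cfg$scenario, seed = cfg$seed %||% 1)
    return(list(cs = sim$case_study, gsc = sim$gene_sets,
                truth = sim$case_study$human$labels))
  }
  needed <- c("mouse_matrix", "mouse_phenotypes", "human_matrix",
              "human_phenotypes", "homology")
  for (f in c(needed, if (!is.null(cfg$gmt)) "gmt")) {
    if (is.null(cfg[[f]])) stop("config is missing required path '", f, "'")
    if (!file.exists(cfg[[f]]))
      stop("config path '", f, "' does not exist: ", cfg[[f]])
  }
  mouse <- collapse_duplicates(read_expression(cfg$mouse_matrix,
                                               cfg$mouse_phenotypes, "mouse"))
  human <- collapse_duplicates(read_expression(cfg$human_matrix,
                                               cfg$human_phenotypes, "human"))
  hm <- read_homology_map(cfg$homology)
  cs <- map_homologs(mouse, human, hm,
                     disease = cfg$disease %||% "disease",
                     identifier = cfg$identifier %||% "case_study")
  cs <- case_study(zscore_by_gene(cs$mouse), zscore_by_gene(cs$human),
                   disease = cs$disease, identifier = cs$identifier)
  list(cs = cs, gsc = if (!is.null(cfg$gmt)) read_gmt(cfg$gmt),
       truth = cs$human$labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one translation case study end to end, writing artifacts to disk
#'
#' Loads (or simulates) a case study, fits the translation, performs
#' differential-expression and pathway analysis under the predicted human
#' phenotypes, evaluates against the truth phenotypes when available, and
#' writes: an iteration trace (`trace.jsonl`, one JSON record per
#' iteration), `predicted_labels.tsv`, `deg_table.tsv`,
#' `enrichment_table.tsv` (when gene sets are supplied), `evaluation.json`
#' (when truth labels are available) and `manifest.json` (package version,
#' seed, configuration hash).
#'
#' @param config Path to a JSON/YAML config file, or an equivalent list.
#'   Either `scenario` (a [scenario_library()] name) or the five input
#'   paths `mouse_matrix`, `mouse_phenotypes`, `human_matrix`,
#'   `human_phenotypes`, `homology` (plus optional `gmt`); and `family`,
#'   `mode`, `alpha`, `seed`, `out`.
#' @return Invisibly, a list with the fitted `translation`, the evaluation
#'   (if computed) and the output directory.
#' @export
run_case_study <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out %||% stop("config must name an output directory 'out'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- withCallingHandlers(
    load_case_study_from_config(cfg),
    error = function(e) stop("stage 'load': ", conditionMessage(e), call. = FALSE))
  fit <- tryCatch(
    translate(inputs$cs, family = cfg$family %||% "nn",
              mode = cfg$mode %||% "semi", alpha = cfg$alpha %||% 1,
              seed = cfg$seed %||% 1),
    error = function(e) stop("stage 'translate': ", conditionMessage(e),
                             call. = FALSE))
  write_trace_jsonl(fit, file.path(out_dir, "trace.jsonl"))
  utils::write.table(predict(fit), file.path(out_dir, "predicted_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  evaluation <- NULL
  if (nlevels(droplevels(fit$predicted_labels)) == 2) {
    degs <- call_degs(inputs$cs$human, fit$predicted_labels)
    utils::write.table(degs, file.path(out_dir, "deg_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(inputs$gsc)) {
      et <- enrich(deg_genes(degs), inputs$gsc, gene_ids(inputs$cs$human))
      utils::write.table(et, file.path(out_dir, "enrichment_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(inputs$truth)) {
    evaluation <- evaluate_translation(fit, inputs$truth, inputs$gsc)
    jsonlite::write_json(evaluation_json(evaluation),
                         file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  manifest <- list(package = "phenotrans",
                   version = as.character(utils::packageVersion("phenotrans")),
                   seed = cfg$seed %||% 1,
                   family = cfg$family %||% "nn", mode = cfg$mode %||% "semi",
                   alpha = cfg$alpha %||% 1,
                   config_hash = config_hash(cfg[setdiff(names(cfg), "out")]),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fit = fit, evaluation = evaluation, out = out_dir))
}

write_trace_jsonl <- function(fit, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(fit$trace))) {
    rec <- list(iteration = fit$trace$iteration[i],
                threshold_pct = fit$trace$threshold_pct[i],
                n_merged = fit$trace$n_merged[i],
                n_features = fit$trace$n_features[i],
                merged_ids = fit$trace$merged_ids[[i]],
                merged_labels = fit$trace$merged_labels[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

evaluation_json <- function(ev) {
  strip <- function(r) list(tp = r$tp, fp = r$fp, fn = r$fn,
                            precision = r$precision, recall = r$recall,
                            fscore = r$fscore)
  out <- list(deg = strip(ev$deg), accuracy = ev$accuracy, auc = ev$auc)
  if (!is.null(ev$pathway)) out$pathway <- strip(ev$pathway)
  out
}

#' Run a benchmarking grid of translation configurations
#'
#' Enumerates [grid_registry()] over the requested axes, runs each cell on
#' freshly simulated case studies, and writes one TSV row per configuration
#' with DEG/pathway F-scores, accuracy and AUC. Completed cells are cached
#' as per-cell JSON files in `out`, so an interrupted run resumes without
#' recomputation and produces an identical final table.
#'
#' @param config List or JSON/YAML path with fields `scenarios` (names from
#'   [scenario_library()]), `families`, `modes`, `alphas`, `seed`, `out`.
#' @return The grid results data.frame (also written to
#'   `file.path(out, "grid_results.tsv")`).
#' @export
run_grid <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out %||% stop("config must name an output directory 'out'")
  dir.create(file.path(out_dir, "cells"), recursive = TRUE, showWarnings = FALSE)
  scenarios <- cfg$scenarios %||% "easy_transfer"
  reg <- grid_registry(cfg$families %||% c("knn", "svm", "rf", "nn"),
                       cfg$modes %||% c("supervised", "semi"),
                       cfg$alphas %||% c(1, 0.9, 0.7, 0.5, 0.3, 0.1),
                       scenarios, seed = cfg$seed %||% 1)
  rows <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    cell_file <- file.path(out_dir, "cells", sprintf("cell_%04d.json", i))
    if (file.exists(cell_file)) {
      rows[[i]] <- as.data.frame(jsonlite::read_json(cell_file,
                                                     simplifyVector = TRUE))
      next
    }
    sim <- simulate_scenario(reg$case_study[i], seed = reg$seed[i])
    t0 <- proc.time()[["elapsed"]]
    fit <- translate(sim$case_study, family = reg$family[i],
                     mode = reg$mode[i], alpha = reg$alpha[i],
                     seed = reg$seed[i])
    ev <- evaluate_translation(fit, sim$case_study$human$labels, sim$gene_sets)
    row <- data.frame(cell = i, case_study = reg$case_study[i],
                      family = reg$family[i], mode = reg$mode[i],
                      alpha = reg$alpha[i], seed = reg$seed[i],
                      accuracy = ev$accuracy, auc = ev$auc,
                      deg_fscore = ev$deg$fscore,
                      deg_precision = ev$deg$precision,
                      deg_recall = ev$deg$recall,
                      pathway_fscore = ev$pathway$fscore,
                      n_iterations = nrow(fit$trace),
                      n_features = length(fit$final_features$genes),
                      runtime_s = proc.time()[["elapsed"]] - t0)
    jsonlite::write_json(as.list(row), cell_file, auto_unbox = TRUE,
                         digits = NA)
    rows[[i]] <- row
  }
  grid <- do.call(rbind, rows)
  utils::write.table(grid, file.path(out_dir, "grid_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  grid
}
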