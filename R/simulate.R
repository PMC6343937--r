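#' Configuration for a synthetic paired mouse/human case study
#'
#' Describes a paired cohort with three planted gene classes: genes
#' differentially expressed in both species (`n_shared_deg`), in the mouse
#' only (`n_mouse_only_deg`), and in the human only (`n_human_only_deg`).
#' Expression is Gaussian noise per gene per sample; disease-class samples
#' are shifted additively by `effect_mouse` / `effect_human` (in noise-SD
#' units) on the respective species' DEG genes — the simplest generative
#' model consistent with z-scored intensities and a rank-test downstream.
#' Pathway gene sets are built so that a configurable fraction
#' (`prop_true_pathways`) are genuinely enriched for the human truth DEGs
#' (drawing a `deg_pathway_purity` fraction of their members from them),
#' while the remainder draw uniformly from non-DEG genes.
#'
#' @param n_genes Total gene count.
#' @param n_shared_deg,n_mouse_only_deg,n_human_only_deg Planted gene-class
#'   sizes (must sum to at most `n_genes`).
#' @param effect_mouse,effect_human Class mean shift in SD units.
#' @param n_mouse_per_class,n_human_per_class Length-2 integer vectors
#'   (control, disease).
#' @param noise_sd Noise standard deviation.
#' @param n_pathways,pathway_size Gene-set collection shape.
#' @param deg_pathway_purity Fraction of each true pathway drawn from human
#'   truth DEGs.
#' @param prop_true_pathways Fraction of pathways planted as truly enriched.
#' @param mouse_subcohorts 1 (default) or 2; with 2, the mouse cohort is
#'   split into two equal sub-cohorts (sample IDs prefixed `m1_`/`m2_`) and
#'   each sub-cohort expresses the shared signal plus its own half of the
#'   mouse-only genes — a heterogeneous multi-strain design.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 300, n_shared_deg = 20, n_mouse_only_deg = 0,
                       n_human_only_deg = 0, effect_mouse = 2,
                       effect_human = 2, n_mouse_per_class = c(20, 20),
                       n_human_per_class = c(30, 30), noise_sd = 1,
                       n_pathways = 20, pathway_size = 10,
                       deg_pathway_purity = 0.8, prop_true_pathways = 0.5,
                       mouse_subcohorts = 1, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_shared_deg = as.integer(n_shared_deg),
              n_mouse_only_deg = as.integer(n_mouse_only_deg),
              n_human_only_deg = as.integer(n_human_only_deg),
              effect_mouse = effect_mouse, effect_human = effect_human,
              n_mouse_per_class = as.integer(n_mouse_per_class),
              n_human_per_class = as.integer(n_human_per_class),
              noise_sd = noise_sd, n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              deg_pathway_purity = deg_pathway_purity,
              prop_true_pathways = prop_true_pathways,
              mouse_subcohorts = as.integer(mouse_subcohorts),
              seed = as.integer(seed))
  with(cfg, {
    if (n_shared_deg + n_mouse_only_deg + n_human_only_deg > n_genes)
      stop("planted DEG class sizes exceed n_genes")
    if (any(c(n_mouse_per_class, n_human_per_class) < 1))
      stop("all per-class sample counts must be >= 1")
    if (noise_sd <= 0) stop("noise_sd must be positive")
    if (deg_pathway_purity < 0 || deg_pathway_purity > 1)
      stop("deg_pathway_purity must be in [0, 1]")
    if (pathway_size > n_genes) stop("pathway_size exceeds n_genes")
    if (!mouse_subcohorts %in% 1:2) stop("mouse_subcohorts must be 1 or 2")
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic paired case study with known truth
#'
#' Draws the paired mouse/human cohorts described by a [sim_config()],
#' z-scores each cohort on its own samples, and returns the harmonized case
#' study (the homology map is the identity on the synthetic symbols)
#' together with the planted truth and the pathway collection. True
#' pathways are verified at generation time to be hypergeometrically
#' enriched (BH q < 0.05) for the planted human truth DEGs, resampling a
#' failing set up to 50 times.
#'
#' @param cfg A `sim_config`.
#' @return List with `case_study` (a `case_study`), `truth` (a `sim_truth`:
#'   `shared_degs`, `mouse_only_degs`, `human_only_degs`,
#'   `human_truth_degs` = shared ∪ human-only, `true_pathways`), and
#'   `gene_sets` (a `gene_set_collection`).
#' @export
generate_case_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed %% .Machine$integer.max)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  n_deg <- cfg$n_shared_deg + cfg$n_mouse_only_deg + cfg$n_human_only_deg
  deg_pos <- sample(cfg$n_genes, n_deg)
  shared <- genes[deg_pos[seq_len(cfg$n_shared_deg)]]
  mouse_only <- genes[deg_pos[cfg$n_shared_deg + seq_len(cfg$n_mouse_only_deg)]]
  human_only <- genes[deg_pos[cfg$n_shared_deg + cfg$n_mouse_only_deg +
                                seq_len(cfg$n_human_only_deg)]]

  mouse <- simulate_cohort(genes, cfg$n_mouse_per_class, cfg$noise_sd,
                           union(shared, mouse_only), cfg$effect_mouse,
                           prefix = "m", species = "mouse",
                           name = "sim_mouse", shared = shared,
                           subcohorts = cfg$mouse_subcohorts)
  human <- simulate_cohort(genes, cfg$n_human_per_class, cfg$noise_sd,
                           union(shared, human_only), cfg$effect_human,
                           prefix = "h", species = "human",
                           name = "sim_human", shared = shared,
                           subcohorts = 1L)
  cs <- case_study(zscore_by_gene(mouse), zscore_by_gene(human),
                   disease = "simulated", identifier = sprintf("sim_seed%d", cfg$seed))

  human_truth <- union(shared, human_only)
  gsc <- simulate_pathways(genes, human_truth, cfg)
  truth <- structure(list(shared_degs = shared, mouse_only_degs = mouse_only,
                          human_only_degs = human_only,
                          human_truth_degs = human_truth,
                          true_pathways = attr(gsc, "true_pathways")),
                     class = "sim_truth")
  list(case_study = cs, truth = truth, gene_sets = gsc)
}

simulate_cohort <- function(genes, n_per_class, noise_sd, deg_genes, effect,
                            prefix, species, name, shared, subcohorts) {
  n <- sum(n_per_class)
  labels <- factor(rep(c("control", "disease"), n_per_class),
                   levels = c("control", "disease"))
  if (subcohorts == 2) {
    half <- function(k) c(rep(1L, ceiling(k / 2)), rep(2L, floor(k / 2)))
    sub <- c(half(n_per_class[1]), half(n_per_class[2]))
    ids <- sprintf("%s%d_%03d", prefix, sub, seq_len(n))
  } else {
    sub <- rep(1L, n)
    ids <- sprintf("%s_%03d", prefix, seq_len(n))
  }
  v <- matrix(stats::rnorm(length(genes) * n, sd = noise_sd), length(genes), n,
              dimnames = list(genes, ids))
  disease <- labels == "disease"
  if (subcohorts == 2) {
    ## each sub-cohort carries the shared signal plus its own half of the
    ## cohort-specific genes
    specific <- setdiff(deg_genes, shared)
    halves <- split(specific, rep(1:2, length.out = length(specific)))
    for (s in 1:2) {
      cols <- disease & sub == s
      v[union(shared, halves[[s]]), cols] <-
        v[union(shared, halves[[s]]), cols] + effect * noise_sd
    }
  } else if (length(deg_genes) && any(disease)) {
    v[deg_genes, disease] <- v[deg_genes, disease] + effect * noise_sd
  }
  expression_dataset(v, labels, species = species, name = name)
}

simulate_pathways <- function(genes, human_truth, cfg) {
  n_true <- round(cfg$prop_true_pathways * cfg$n_pathways)
  non_deg <- setdiff(genes, human_truth)
  sets <- vector("list", cfg$n_pathways)
  names(sets) <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  n_from_deg <- round(cfg$deg_pathway_purity * cfg$pathway_size)
  n_from_deg <- min(n_from_deg, length(human_truth))
  for (j in seq_len(cfg$n_pathways)) {
    if (j <= n_true && length(human_truth)) {
      for (attempt in seq_len(50)) {
        s <- c(sample(human_truth, n_from_deg),
               sample(non_deg, cfg$pathway_size - n_from_deg))
        p <- stats::phyper(length(intersect(s, human_truth)) - 1,
                           length(human_truth),
                           length(genes) - length(human_truth),
                           length(s), lower.tail = FALSE)
        ## planted-true sets must individually survive a BH cut across the
        ## whole collection; p * n_pathways bounds the worst-case q
        if (p * cfg$n_pathways < 0.05) break
      }
      sets[[j]] <- s
    } else {
      sets[[j]] <- sample(non_deg, cfg$pathway_size)
    }
  }
  gsc <- gene_set_collection(sets, universe = genes)
  attr(gsc, "true_pathways") <- if (n_true && length(human_truth))
    names(sets)[seq_len(n_true)] else character(0)
  gsc
}

#' Named library of study-condition scenarios
#'
#' Four fixed regimes spanning the translation problem's difficulty axes:
#' \describe{
#'   \item{easy_transfer}{Shared signal only (25 genes, effect 2.5 in both
#'     species, 20/20 mouse and 30/30 human samples): translation is
#'     straightforward and supervised and semi-supervised fits should agree.}
#'   \item{divergent}{A small transferable core (6 shared genes) beneath a
#'     dominant human-only program (40 genes) and a mouse-only program (20
#'     genes), with a tiny mouse cohort (5/5, the surgical-sepsis /
#'     endotoxemia regime): direct mouse analysis largely misses the human
#'     truth, and recovering it requires folding the human samples into
#'     training.}
#'   \item{imbalanced_mouse}{Shared signal with a small, 1:4-imbalanced
#'     mouse cohort (4 control / 16 disease): the small-n, high-imbalance
#'     design regime associated with degraded translation performance.}
#'   \item{heterogeneous_mouse}{Two mouse sub-cohorts with different
#'     cohort-specific effect genes (a two-strain design) beneath a shared
#'     core plus a human-only program.}
#' }
#' Seeds are placeholders; callers re-seed per replicate.
#'
#' @return Named list of `sim_config` objects.
#' @export
scenario_library <- function() {
  list(
    easy_transfer = sim_config(n_genes = 300, n_shared_deg = 25,
                               effect_mouse = 2.5, effect_human = 2.5,
                               n_mouse_per_class = c(20, 20),
                               n_human_per_class = c(30, 30)),
    divergent = sim_config(n_genes = 300, n_shared_deg = 6,
                           n_mouse_only_deg = 20, n_human_only_deg = 40,
                           effect_mouse = 2.5, effect_human = 3,
                           n_mouse_per_class = c(5, 5),
                           n_human_per_class = c(30, 30)),
    imbalanced_mouse = sim_config(n_genes = 300, n_shared_deg = 20,
                                  effect_mouse = 2, effect_human = 2,
                                  n_mouse_per_class = c(4, 16),
                                  n_human_per_class = c(30, 30)),
    heterogeneous_mouse = sim_config(n_genes = 300, n_shared_deg = 10,
                                     n_mouse_only_deg = 20,
                                     n_human_only_deg = 30,
                                     effect_mouse = 2.5, effect_human = 2.5,
                                     n_mouse_per_class = c(10, 10),
                                     n_human_per_class = c(30, 30),
                                     mouse_subcohorts = 2)
  )
}

#' Instantiate a named scenario at a given seed
#' @param scenario Name from [scenario_library()].
#' @param seed Integer seed.
#' @return As [generate_case_study()].
#' @export
simulate_scenario <- function(scenario, seed = 1) {
  lib <- scenario_library()
  if (!scenario %in% names(lib))
    stop("unknown scenario '", scenario, "'; available: ",
         paste(names(lib), collapse = ", "))
  cfg <- lib[[scenario]]
  cfg$seed <- as.integer(seed)
  generate_case_study(cfg)
}

#' Write a simulated case study to disk in the package's file formats
#'
#' Emits the mouse and human expression/phenotype TSVs, the identity
#' homology map, the GMT pathway file, and a JSON truth record.
#'
#' @param sim Output of [generate_case_study()] / [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_case_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- sim$case_study
  paths <- c(mouse_matrix = file.path(dir, "mouse_expression.tsv"),
             mouse_pheno = file.path(dir, "mouse_phenotypes.tsv"),
             human_matrix = file.path(dir, "human_expression.tsv"),
             human_pheno = file.path(dir, "human_phenotypes.tsv"),
             homology = file.path(dir, "homology_map.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression(cs$mouse, paths["mouse_matrix"], paths["mouse_pheno"])
  write_expression(cs$human, paths["human_matrix"], paths["human_pheno"])
  utils::write.table(data.frame(mouse_symbol = gene_ids(cs$mouse),
                                human_symbol = gene_ids(cs$human)),
                     paths["homology"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(sim$gene_sets, paths["gmt"])
  jsonlite::write_json(unclass(sim$truth), paths["truth"], pretty = TRUE)
  invisible(paths)
}
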