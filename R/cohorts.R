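#' The benchmark cohort of mouse and human inflammatory-pathology datasets
#'
#' Metadata for the published benchmark cohort: 6 mouse (training) and 7
#' human (test) microarray datasets spanning burn, trauma, endotoxemia and
#' sepsis, identified by GEO accession. Multi-valued fields
#' (platforms, mouse strains, induction severities) are semicolon-separated
#' and are expanded into separate training/test cohorts by
#' [enumerate_case_studies()].
#'
#' @return A data.frame with columns `species`, `disease`, `accession`,
#'   `platform`, `strain`, `condition_group`, `n_control`, `n_case`.
#' @export
cohort_table <- function() {
  rbind(
    data.frame(species = "human", disease = "Burn", accession = "GSE37069",
               platform = "GPL570", strain = "", condition_group = "",
               n_control = 37, n_case = 553),
    data.frame(species = "human", disease = "Trauma", accession = "GSE36809",
               platform = "GPL570", strain = "", condition_group = "",
               n_control = 37, n_case = 216),
    data.frame(species = "human", disease = "Endotoxemia", accession = "GSE3284",
               platform = "GPL96;GPL97", strain = "", condition_group = "",
               n_control = 16, n_case = 76),
    data.frame(species = "human", disease = "Sepsis", accession = "GSE13904",
               platform = "GPL570", strain = "", condition_group = "",
               n_control = 18, n_case = 158),
    data.frame(species = "human", disease = "Sepsis", accession = "GSE9960",
               platform = "GPL570", strain = "", condition_group = "",
               n_control = 16, n_case = 54),
    data.frame(species = "human", disease = "Sepsis", accession = "GSE28750",
               platform = "GPL570", strain = "", condition_group = "",
               n_control = 20, n_case = 21),
    data.frame(species = "human", disease = "Sepsis", accession = "GSE13015",
               platform = "GPL6947;GPL6106", strain = "", condition_group = "",
               n_control = 29, n_case = 77),
    data.frame(species = "mouse", disease = "Burn", accession = "GSE7404",
               platform = "GPL1261", strain = "C57BL/6J", condition_group = "Burn",
               n_control = 16, n_case = 16),
    data.frame(species = "mouse", disease = "Trauma", accession = "GSE7404",
               platform = "GPL1261", strain = "C57BL/6J", condition_group = "Trauma",
               n_control = 16, n_case = 16),
    data.frame(species = "mouse", disease = "Endotoxemia", accession = "GSE7404",
               platform = "GPL1261", strain = "C57BL/6J", condition_group = "LPS",
               n_control = 8, n_case = 8),
    data.frame(species = "mouse", disease = "Endotoxemia", accession = "GSE5663",
               platform = "GPL81", strain = "C57BL/6J", condition_group = "LPS",
               n_control = 4, n_case = 5),
    data.frame(species = "mouse", disease = "Sepsis", accession = "GSE5663",
               platform = "GPL81", strain = "C57BL/6J",
               condition_group = "Mild CLP Sepsis;CLP Sepsis",
               n_control = 4, n_case = 5),
    data.frame(species = "mouse", disease = "Sepsis", accession = "GSE26472",
               platform = "GPL6778", strain = "C57BL/6J",
               condition_group = "SPS2 Sepsis",
               n_control = 3, n_case = 8),
    data.frame(species = "mouse", disease = "Sepsis", accession = "GSE19668",
               platform = "GPL1261", strain = "AJ;C57",
               condition_group = "SA Sepsis",
               n_control = 5, n_case = 20)
  )
}

split_field <- function(x) strsplit(x, ";", fixed = TRUE)[[1]]

#' Enumerate translation case studies from a cohort table
#'
#' Applies the benchmark's pairing and partitioning rules: a human dataset
#' measured on several platforms contributes one test cohort per platform; a
#' mouse dataset with several induction severities contributes one training
#' cohort per severity; a mouse dataset with several strains contributes one
#' training cohort per strain *plus* a combined-strain cohort (sample sizes
#' summed). A case study is every (mouse training cohort, human test cohort)
#' pair for the same disease. On the default [cohort_table()] this yields
#' exactly 36 case studies.
#'
#' @param cohorts A data.frame in the [cohort_table()] layout.
#' @return A data.frame with one row per case study: `case_study`
#'   (identifier), `disease`, `mouse_accession`, `mouse_cohort`,
#'   `human_accession`, `human_cohort`, `mouse_n_control`, `mouse_n_case`.
#' @export
enumerate_case_studies <- function(cohorts = cohort_table()) {
  stopifnot(all(c("species", "disease", "accession", "platform", "strain",
                  "condition_group", "n_control", "n_case") %in% names(cohorts)))
  humans <- do.call(rbind, lapply(which(cohorts$species == "human"), function(i) {
    row <- cohorts[i, ]
    plats <- split_field(row$platform)
    multi <- length(plats) > 1
    data.frame(disease = row$disease, human_accession = row$accession,
               human_cohort = if (multi) paste0(row$accession, " (", plats, ")")
                              else row$accession)
  }))
  mice <- do.call(rbind, lapply(which(cohorts$species == "mouse"), function(i) {
    row <- cohorts[i, ]
    groups <- split_field(row$condition_group)
    strains <- split_field(row$strain)
    per_strain <- expand.grid(group = groups, strain = strains,
                              stringsAsFactors = FALSE)
    per_strain$n_control <- row$n_control
    per_strain$n_case <- row$n_case
    if (length(strains) > 1) {
      combined <- data.frame(group = groups,
                             strain = paste(strains, collapse = " and "),
                             n_control = row$n_control * length(strains),
                             n_case = row$n_case * length(strains))
      per_strain <- rbind(per_strain, combined)
    }
    qualifier <- if (length(strains) > 1)
      paste(per_strain$strain, "Strain,", per_strain$group)
    else per_strain$group
    needs_qual <- length(groups) > 1 || length(strains) > 1 ||
      !identical(groups, row$disease)
    data.frame(disease = row$disease, mouse_accession = row$accession,
               mouse_cohort = if (needs_qual)
                 paste0(row$accession, " (", qualifier, ")") else row$accession,
               mouse_n_control = per_strain$n_control,
               mouse_n_case = per_strain$n_case)
  }))
  out <- merge(mice, humans, by = "disease", sort = FALSE)
  out <- out[order(match(out$disease, unique(cohorts$disease)),
                   out$mouse_cohort, out$human_cohort), ]
  out$case_study <- sprintf("%02d_%s", seq_len(nrow(out)), out$disease)
  rownames(out) <- NULL
  out[, c("case_study", "disease", "mouse_accession", "mouse_cohort",
          "human_accession", "human_cohort", "mouse_n_control", "mouse_n_case")]
}
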