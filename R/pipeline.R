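#' @title Pipeline stages
#' @description
#' The pipeline is orchestrated as stages over an output directory with a
#' JSON run manifest: \code{simulate} writes synthetic fixtures,
#' \code{enrich} scores every study against the gene sets, \code{cluster}
#' builds the score matrix, applies the filter cascade and segregates the
#' cancer studies into SLC/CA, \code{network} analyses pathway overlap,
#' \code{patient} computes per-patient scores on the selected pathways,
#' \code{classify} cross-validates the SLC/CA classifiers, and
#' \code{survive} runs the median-split survival screen and the infection
#' contingency analysis. Each stage records its outputs in the manifest and
#' refuses to run before its prerequisites. The
#' \code{inst/scripts/slcpath.R} script exposes the stages as shell
#' subcommands.
#' @name pipeline
NULL

manifest_path <- function(dir) file.path(dir, "manifest.json")

read_manifest <- function(dir) {
  p <- manifest_path(dir)
  if (!file.exists(p))
    stop("no run manifest in ", dir, "; run stage_simulate() ",
         "(subcommand 'simulate') first")
  jsonlite::read_json(p, simplifyVector = TRUE)
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, manifest_path(dir), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

require_stage <- function(manifest, stage, command) {
  if (is.null(manifest$stages[[stage]]))
    stop("stage '", stage, "' has not been run; run '", command, "' first")
}

#' Simulate fixtures and initialize a run manifest
#'
#' @param out_dir Output directory.
#' @param sim_config A \code{\link{simulation_config}}.
#' @return The manifest, invisibly.
#' @export
stage_simulate <- function(out_dir, sim_config = simulation_config()) {
  cohort <- simulate_cohort(sim_config)
  paths <- write_cohort(cohort, out_dir)
  studies <- lapply(names(cohort$studies), function(code) {
    list(code = code, group = cohort$studies[[code]]$disease_group,
         matrix = basename(paths$studies[[code]][["matrix"]]),
         annotation = basename(paths$studies[[code]][["annotation"]]))
  })
  names(studies) <- names(cohort$studies)
  manifest <- list(
    seed = sim_config$seed,
    files = list(gmt = basename(paths$gmt), tumour = basename(paths$tumour),
                 normal = basename(paths$normal),
                 clinical = basename(paths$clinical),
                 infection = basename(paths$infection),
                 patient_groups = basename(paths$patient_groups)),
    studies = studies,
    hazard_pathway = cohort$patients$hazard_pathway,
    stages = list(simulate = TRUE))
  write_manifest(manifest, out_dir)
}

load_studies <- function(manifest, dir) {
  studies <- lapply(manifest$studies, function(st)
    read_expression(file.path(dir, st$matrix), file.path(dir, st$annotation),
                    study_code = st$code, disease_group = st$group))
  intersect_gene_universe(studies)
}

#' Score every study against the gene sets
#'
#' @param out_dir Run directory (after \code{\link{stage_simulate}} or with
#'   an equivalent manifest over real data files).
#' @param config An \code{\link{analysis_config}}.
#' @return The manifest, invisibly.
#' @export
stage_enrich <- function(out_dir, config = analysis_config()) {
  manifest <- read_manifest(out_dir)
  require_stage(manifest, "simulate", "simulate")
  pathways <- read_gmt(file.path(out_dir, manifest$files$gmt))
  studies <- load_studies(manifest, out_dir)
  k <- 0L
  for (st in studies) {
    k <- k + 1L
    res <- score_study(st, pathways, config,
                       seed = child_seed(config$seed, 100L + k))
    write_score_results(res, file.path(out_dir, paste0(st$study_code,
                                                       "_scores.tsv")),
                        B = config$n_permutations)
  }
  manifest$stages$enrich <- TRUE
  write_manifest(manifest, out_dir)
}

read_score_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build the score matrix, filter pathways, and segregate SLC/CA
#'
#' @inheritParams stage_enrich
#' @return The manifest, invisibly.
#' @export
stage_cluster <- function(out_dir, config = analysis_config()) {
  manifest <- read_manifest(out_dir)
  require_stage(manifest, "enrich", "enrich")
  codes <- vapply(manifest$studies, `[[`, character(1), "code")
  groups <- stats::setNames(vapply(manifest$studies, `[[`, character(1),
                                   "group"), codes)
  results <- lapply(codes, function(code)
    read_score_results(file.path(out_dir, paste0(code, "_scores.tsv"))))
  names(results) <- codes
  mat <- build_score_matrix(results, groups)
  ss_robust <- filter_ss_robust(mat, config)
  grouping <- cluster_studies(mat, pathway_subset = ss_robust)
  selected <- filter_group_enriched(mat, grouping, config,
                                    ss_robust = ss_robust)
  utils::write.table(data.frame(pathway_id = rownames(mat$scores),
                                mat$scores, check.names = FALSE),
                     file.path(out_dir, "score_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  assign_df <- data.frame(
    study = names(mat$study_groups),
    group = ifelse(names(mat$study_groups) %in% grouping$slc_studies, "SLC",
                   ifelse(names(mat$study_groups) %in% grouping$ca_studies,
                          "CA", mat$study_groups)))
  utils::write.table(assign_df, file.path(out_dir, "study_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_dendrogram_newick(grouping, file.path(out_dir, "dendrogram.nwk"))
  writeLines(ss_robust, file.path(out_dir, "pathways_ss_robust.txt"))
  writeLines(selected, file.path(out_dir, "pathways_selected.txt"))
  manifest$stages$cluster <- TRUE
  write_manifest(manifest, out_dir)
}

#' Pathway-overlap network analysis
#'
#' @inheritParams stage_enrich
#' @return The manifest, invisibly.
#' @export
stage_network <- function(out_dir, config = analysis_config()) {
  manifest <- read_manifest(out_dir)
  require_stage(manifest, "cluster", "cluster")
  pathways <- read_gmt(file.path(out_dir, manifest$files$gmt))
  selected <- readLines(file.path(out_dir, "pathways_selected.txt"))
  net <- build_overlap_network(pathways, config, selected = selected)
  stats_df <- node_centralities(net)
  write_edge_list(net, file.path(out_dir, "network_edges.tsv"))
  utils::write.table(stats_df, file.path(out_dir, "network_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dd <- degree_distribution(net)
  utils::write.table(data.frame(degree = names(dd), frequency = unname(dd)),
                     file.path(out_dir, "degree_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(net$selected) && length(net$selected) < length(net$nodes)) {
    cmp <- compare_selected_degree(stats_df, net$selected)
    utils::write.table(as.data.frame(cmp),
                       file.path(out_dir, "degree_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$stages$network <- TRUE
  write_manifest(manifest, out_dir)
}

read_patient_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Per-patient pathway scores on the selected pathways
#'
#' @inheritParams stage_enrich
#' @return The manifest, invisibly.
#' @export
stage_patient <- function(out_dir, config = analysis_config()) {
  manifest <- read_manifest(out_dir)
  require_stage(manifest, "cluster", "cluster")
  pathways <- read_gmt(file.path(out_dir, manifest$files$gmt))
  selected <- readLines(file.path(out_dir, "pathways_selected.txt"))
  if (!length(selected)) stop("no selected pathways; nothing to score")
  pathways$sets <- pathways$sets[selected]
  tumour <- read_patient_matrix(file.path(out_dir, manifest$files$tumour))
  normal <- read_patient_matrix(file.path(out_dir, manifest$files$normal))
  z <- score_patients(tumour, normal, pathways)
  write_patient_scores(z, file.path(out_dir, "patient_scores.tsv"))
  manifest$stages$patient <- TRUE
  write_manifest(manifest, out_dir)
}

read_patient_scores <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Cross-validated SLC/CA classification from patient scores
#'
#' @inheritParams stage_enrich
#' @return The manifest, invisibly.
#' @export
stage_classify <- function(out_dir, config = analysis_config()) {
  manifest <- read_manifest(out_dir)
  require_stage(manifest, "patient", "patient")
  z <- read_patient_scores(file.path(out_dir, "patient_scores.tsv"))
  grp <- utils::read.delim(file.path(out_dir, manifest$files$patient_groups),
                           stringsAsFactors = FALSE)
  labels <- stats::setNames(grp$group, grp$patient_id)[rownames(z)]
  rows <- list()
  for (kind in c("svm", "nnet")) {
    spec <- classifier_spec(kind, hidden_nodes = config$nn_hidden,
                            weight_decay = config$nn_decay,
                            seed = config$seed)
    cm <- crossval_classify(z, labels, spec, k = config$cv_folds)
    met <- confusion_metrics(cm)
    rows[[kind]] <- data.frame(classifier = kind,
                               accuracy_pct = met$accuracy,
                               misclassification_pct = met$misclassification)
    utils::write.table(as.data.frame(cm$counts),
                       file.path(out_dir, paste0("confusion_", kind, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(do.call(rbind, rows),
                     file.path(out_dir, "classifier_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$classify <- TRUE
  write_manifest(manifest, out_dir)
}

#' Survival screen and infection contingency analysis
#'
#' @inheritParams stage_enrich
#' @return The manifest, invisibly.
#' @export
stage_survive <- function(out_dir, config = analysis_config()) {
  manifest <- read_manifest(out_dir)
  require_stage(manifest, "patient", "patient")
  z <- read_patient_scores(file.path(out_dir, "patient_scores.tsv"))
  clinical <- read_clinical(file.path(out_dir, manifest$files$clinical))
  grp <- utils::read.delim(file.path(out_dir, manifest$files$patient_groups),
                           stringsAsFactors = FALSE)
  labels <- stats::setNames(grp$group, grp$patient_id)
  rows <- lapply(unique(labels), function(g) {
    pts <- names(labels)[labels == g]
    scr <- survival_screen(z[pts, , drop = FALSE],
                           clinical[clinical$patient_id %in% pts, ], config)
    utils::write.table(data.frame(pathway_id = names(scr$pvals),
                                  p = unname(scr$pvals)),
                       file.path(out_dir, paste0("survival_p_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    data.frame(group = g, n_associated = scr$n_associated,
               n_pathways = scr$n_pathways,
               percent_associated = scr$percent_associated)
  })
  utils::write.table(do.call(rbind, rows),
                     file.path(out_dir, "survival_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  inf <- utils::read.delim(file.path(out_dir, manifest$files$infection),
                           stringsAsFactors = FALSE)
  if (length(unique(inf$group)) == 2) {
    tab <- as.matrix(table(inf$group, factor(inf$infected, levels = c(1, 0))))
    ca <- contingency_analysis(tab)
    utils::write.table(
      data.frame(group = rownames(tab), n_infected = tab[, 1],
                 n_total = rowSums(tab), percent = ca$percent,
                 p = ca$p, odds_ratio = ca$odds_ratio),
      file.path(out_dir, "infection_contingency.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$stages$survive <- TRUE
  write_manifest(manifest, out_dir)
}

#' Run the full pipeline on synthetic fixtures
#'
#' Convenience wrapper chaining every stage in order.
#'
#' @param out_dir Output directory.
#' @param sim_config A \code{\link{simulation_config}}.
#' @param config An \code{\link{analysis_config}}.
#' @return The final manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, sim_config = simulation_config(),
                         config = analysis_config()) {
  stage_simulate(out_dir, sim_config)
  stage_enrich(out_dir, config)
  stage_cluster(out_dir, config)
  stage_network(out_dir, config)
  stage_patient(out_dir, config)
  stage_classify(out_dir, config)
  stage_survive(out_dir, config)
}
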