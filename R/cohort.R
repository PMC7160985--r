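#' Assemble the pathway-score matrix across studies
#'
#' Combines per-study \code{\link{score_study}} results into matched
#' pathways x studies matrices of scores and permutation p-values, restricted
#' to the pathways retained (size filter passed) in every study. Pathways
#' missing from any study are dropped, not imputed: a score computed over a
#' different gene subset is not comparable.
#'
#' @param results Named list of \code{\link{score_study}} data.frames, one
#'   per study.
#' @param study_groups Named character vector: study code -> disease-group
#'   label (\code{"SS"} for septic shock; any other label is treated as a
#'   cancer study until \code{\link{cluster_studies}} assigns SLC/CA).
#' @return A list of class \code{score_matrix}: \code{scores}, \code{pvals}
#'   (pathways x studies) and \code{study_groups}.
#' @export
build_score_matrix <- function(results, study_groups) {
  if (length(results) < 2) stop("need at least 2 studies")
  if (is.null(names(results)) ||
      !setequal(names(results), names(study_groups)))
    stop("results and study_groups must be named by the same study codes")
  study_groups <- study_groups[names(results)]
  common <- Reduce(intersect, lapply(results, `[[`, "pathway_id"))
  if (!length(common)) stop("no pathway retained in every study")
  all_ids <- unique(unlist(lapply(results, `[[`, "pathway_id")))
  dropped <- setdiff(all_ids, common)
  if (length(dropped))
    message("build_score_matrix: dropped ", length(dropped),
            " pathway(s) not retained in every study")
  grab <- function(col) {
    m <- vapply(results, function(r) {
      stats::setNames(r[[col]], r$pathway_id)[common]
    }, numeric(length(common)))
    rownames(m) <- common
    m
  }
  structure(list(scores = grab("score"), pvals = grab("p_perm"),
                 study_groups = study_groups),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d pathways x %d studies (%s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%s=%d", names(table(x$study_groups)),
                            table(x$study_groups)), collapse = ", ")))
  invisible(x)
}

#' Robust septic-shock pathway filter
#'
#' Retains the pathways whose permutation p-value is below
#' \code{alpha_enrich} in every septic-shock study (the 272-to-90-style
#' step of the filter cascade).
#'
#' @param mat A \code{\link{build_score_matrix}} result.
#' @param config An \code{\link{analysis_config}}.
#' @param ss_label Label identifying septic-shock studies.
#' @return Character vector of retained pathway IDs.
#' @export
filter_ss_robust <- function(mat, config = analysis_config(),
                             ss_label = "SS") {
  stopifnot(inherits(mat, "score_matrix"))
  ss_cols <- names(mat$study_groups)[mat$study_groups == ss_label]
  if (!length(ss_cols)) stop("no study with group label '", ss_label, "'")
  sig <- mat$pvals[, ss_cols, drop = FALSE] < config$alpha_enrich
  rownames(mat$pvals)[rowSums(sig) == length(ss_cols)]
}

#' Cluster studies and segregate cancers into SLC and CA
#'
#' Complete-linkage agglomerative clustering on the Euclidean distance matrix
#' between study score columns (restricted to a pathway subset, typically the
#' robust septic-shock set). Cutting the tree into two clusters, the cancer
#' studies falling in the cluster that contains the majority of septic-shock
#' studies are labelled sepsis-like cancer (SLC); the rest are cancer-alone
#' (CA). An even split of the SS studies across the two clusters is an
#' ambiguity error requiring manual assignment.
#'
#' @param mat A \code{\link{build_score_matrix}} result.
#' @param pathway_subset Optional pathway IDs to cluster on (default: all).
#' @param ss_label Label identifying septic-shock studies.
#' @return A list of class \code{study_grouping}: \code{dendrogram} (hclust),
#'   \code{slc_studies}, \code{ca_studies}, \code{linkage}, \code{distance}.
#' @export
cluster_studies <- function(mat, pathway_subset = NULL, ss_label = "SS") {
  stopifnot(inherits(mat, "score_matrix"))
  scores <- mat$scores
  if (!is.null(pathway_subset)) {
    missing <- setdiff(pathway_subset, rownames(scores))
    if (length(missing)) stop("pathway subset not in matrix: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    scores <- scores[pathway_subset, , drop = FALSE]
  }
  if (ncol(scores) < 3) stop("need at least 3 studies to cluster")
  hc <- stats::hclust(stats::dist(t(scores), method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = 2)
  ss_studies <- names(mat$study_groups)[mat$study_groups == ss_label]
  ss_counts <- table(factor(cl[ss_studies], levels = c(1, 2)))
  if (ss_counts[1] == ss_counts[2])
    stop("ambiguous clustering: septic-shock studies split evenly across ",
         "the two clusters; assign groups manually")
  ss_cluster <- as.integer(names(which.max(ss_counts)))
  cancer <- setdiff(names(mat$study_groups), ss_studies)
  structure(
    list(dendrogram = hc,
         slc_studies = cancer[cl[cancer] == ss_cluster],
         ca_studies = cancer[cl[cancer] != ss_cluster],
         linkage = "complete", distance = "euclidean"),
    class = "study_grouping")
}

#' @export
print.study_grouping <- function(x, ...) {
  cat("study_grouping (", x$distance, " distance, ", x$linkage, " linkage)\n",
      "  SLC: ", paste(x$slc_studies, collapse = ", "), "\n",
      "  CA:  ", paste(x$ca_studies, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a study dendrogram as Newick text
#'
#' @param grouping A \code{\link{cluster_studies}} result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dendrogram_newick <- function(grouping, path) {
  stopifnot(inherits(grouping, "study_grouping"))
  ape::write.tree(ape::as.phylo(grouping$dendrogram), file = path)
  invisible(path)
}

#' Group-enrichment pathway filter
#'
#' From the robust septic-shock set, retains the pathways significantly
#' enriched (permutation p below \code{alpha_enrich}) in at least
#' \code{group_fraction} of the SLC studies or at least that fraction of the
#' CA studies (the 90-to-66-style step). Significance alone qualifies by
#' default; with \code{require_direction = TRUE} the qualifying fraction must
#' also share the score sign.
#'
#' @param mat A \code{\link{build_score_matrix}} result.
#' @param grouping A \code{\link{cluster_studies}} result.
#' @param config An \code{\link{analysis_config}}.
#' @param ss_robust Pathway IDs that passed \code{\link{filter_ss_robust}}
#'   (default: recomputed from \code{mat}).
#' @param require_direction Require a consistent direction within the
#'   qualifying group.
#' @return Character vector of retained pathway IDs (a subset of
#'   \code{ss_robust}).
#' @export
filter_group_enriched <- function(mat, grouping, config = analysis_config(),
                                  ss_robust = NULL,
                                  require_direction = FALSE) {
  stopifnot(inherits(mat, "score_matrix"), inherits(grouping, "study_grouping"))
  if (is.null(ss_robust)) ss_robust <- filter_ss_robust(mat, config)
  qual_frac <- function(cols, sgn = NULL) {
    if (!length(cols)) return(rep(0, nrow(mat$pvals)))
    hit <- mat$pvals[, cols, drop = FALSE] < config$alpha_enrich
    if (!is.null(sgn)) hit <- hit & (sign(mat$scores[, cols, drop = FALSE]) == sgn)
    rowMeans(hit)
  }
  pass <- function(cols) {
    if (require_direction)
      qual_frac(cols, +1) >= config$group_fraction |
        qual_frac(cols, -1) >= config$group_fraction
    else qual_frac(cols) >= config$group_fraction
  }
  keep <- pass(grouping$slc_studies) | pass(grouping$ca_studies)
  intersect(ss_robust, rownames(mat$pvals)[keep])
}

#' Per-group pathway summaries
#'
#' Mean pathway score per disease group, and per-study counts of
#' significantly up- (score > 0, p below \code{alpha_enrich}) and
#' down-regulated pathways with their group averages.
#'
#' @param mat A \code{\link{build_score_matrix}} result.
#' @param grouping A \code{\link{cluster_studies}} result.
#' @param config An \code{\link{analysis_config}}.
#' @param ss_label Label identifying septic-shock studies.
#' @return A list: \code{group_means} (pathways x groups matrix),
#'   \code{study_counts} (per-study up/down counts) and \code{group_counts}
#'   (group-average up/down counts).
#' @export
group_summary <- function(mat, grouping, config = analysis_config(),
                          ss_label = "SS") {
  stopifnot(inherits(mat, "score_matrix"), inherits(grouping, "study_grouping"))
  groups <- list(SS = names(mat$study_groups)[mat$study_groups == ss_label],
                 SLC = grouping$slc_studies, CA = grouping$ca_studies)
  groups <- groups[lengths(groups) > 0]
  group_means <- vapply(groups, function(cols)
    rowMeans(mat$scores[, cols, drop = FALSE]), numeric(nrow(mat$scores)))
  sig <- mat$pvals < config$alpha_enrich
  up <- colSums(sig & mat$scores > 0)
  down <- colSums(sig & mat$scores < 0)
  study_counts <- data.frame(
    study = colnames(mat$scores),
    group = vapply(colnames(mat$scores), function(s) {
      g <- names(groups)[vapply(groups, function(gg) s %in% gg, logical(1))]
      if (length(g)) g else "unassigned"
    }, character(1)),
    n_up = as.integer(up), n_down = as.integer(down),
    stringsAsFactors = FALSE, row.names = NULL)
  group_counts <- do.call(rbind, lapply(names(groups), function(g) {
    rows <- study_counts$group == g
    data.frame(group = g, mean_up = mean(study_counts$n_up[rows]),
               mean_down = mean(study_counts$n_down[rows]))
  }))
  list(group_means = group_means, study_counts = study_counts,
       group_counts = group_counts)
}

#' Gene-level log2 fold-change for one study
#'
#' LFC = mean(case) - mean(control), per gene, on the log2 scale.
#'
#' @param study An \code{\link{expression_study}}.
#' @return A data.frame with columns \code{gene_id}, \code{lfc}.
#' @export
gene_lfc <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  case <- study$sample_labels == "case"
  if (!any(case) || all(case)) stop("study needs both case and control arms")
  lfc <- rowMeans(study$matrix[, case, drop = FALSE]) -
    rowMeans(study$matrix[, !case, drop = FALSE])
  data.frame(gene_id = study$gene_ids, lfc = unname(lfc),
             stringsAsFactors = FALSE)
}

#' Median log2 fold-change across the studies of a disease group
#'
#' @param studies List of \code{\link{expression_study}} objects from one
#'   disease group.
#' @return Named numeric vector of per-gene median LFC over the common genes.
#' @export
median_group_lfc <- function(studies) {
  if (!length(studies)) stop("need at least one study")
  studies <- intersect_gene_universe(studies)
  lfcs <- vapply(studies, function(s) gene_lfc(s)$lfc,
                 numeric(length(studies[[1]]$gene_ids)))
  stats::setNames(apply(as.matrix(lfcs), 1, stats::median),
                  studies[[1]]$gene_ids)
}

#' Genes with concordant fold-change direction in SLC and SS
#'
#' Keeps the genes whose median LFC has the same non-zero sign in the
#' sepsis-like-cancer and septic-shock groups (the gene-level concordance
#' rule used before gene-level visualization).
#'
#' @param slc_lfc,ss_lfc Named numeric vectors of median LFC.
#' @return Character vector of concordant gene IDs.
#' @export
concordance_filter <- function(slc_lfc, ss_lfc) {
  common <- intersect(names(slc_lfc), names(ss_lfc))
  s1 <- sign(slc_lfc[common])
  s2 <- sign(ss_lfc[common])
  common[s1 == s2 & s1 != 0]
}
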