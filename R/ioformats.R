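#' Construct an expression study
#'
#' Container for one case/control study: a genes x samples matrix of log2
#' expression values, per-sample class labels, and an optional case-to-control
#' pairing (used for paired tumour/normal designs).
#'
#' @param study_code Short study identifier.
#' @param disease_group Disease-group label (e.g. \code{"SS"}, \code{"SLC"},
#'   \code{"CA"}, or any synthetic label).
#' @param matrix Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs), log2 scale.
#' @param sample_labels Character vector, one of \code{"case"}/\code{"control"}
#'   per column of \code{matrix}; names taken from the matrix columns.
#' @param pairing Optional named character vector mapping case sample IDs to
#'   control sample IDs (a bijection).
#'
#' @return An object of class \code{expression_study}.
#' @export
expression_study <- function(study_code, disease_group, matrix,
                             sample_labels, pairing = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("'matrix' must be a numeric matrix")
  if (is.null(rownames(matrix)))
    stop("expression matrix must have gene IDs as rownames")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene IDs in expression matrix; collapse before construction")
  if (length(sample_labels) != ncol(matrix))
    stop("one class label required per sample (got ", length(sample_labels),
         " labels for ", ncol(matrix), " samples)")
  if (!all(sample_labels %in% c("case", "control")))
    stop("sample labels must be 'case' or 'control'")
  names(sample_labels) <- colnames(matrix)
  if (!is.null(pairing)) {
    cases <- names(sample_labels)[sample_labels == "case"]
    ctrls <- names(sample_labels)[sample_labels == "control"]
    if (!setequal(names(pairing), cases) || !setequal(unname(pairing), ctrls) ||
        anyDuplicated(unname(pairing)))
      stop("pairing must be a bijection between case and control samples")
  }
  structure(
    list(study_code = study_code, disease_group = disease_group,
         matrix = matrix, gene_ids = rownames(matrix),
         sample_labels = sample_labels, pairing = pairing),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study '%s' (%s): %d genes x %d samples (%d case / %d control)\n",
              x$study_code, x$disease_group, nrow(x$matrix), ncol(x$matrix),
              sum(x$sample_labels == "case"), sum(x$sample_labels == "control")))
  invisible(x)
}

#' Construct a pathway collection
#'
#' Named gene sets (pathway ID -> character vector of gene IDs) with optional
#' display names and functional annotation.
#'
#' @param sets Named list of character vectors of gene IDs.
#' @param names Optional named character vector of display names.
#' @param annotation Optional named character vector of functional classes.
#' @return An object of class \code{pathway_collection}.
#' @export
pathway_collection <- function(sets, names = NULL, annotation = NULL) {
  if (length(sets) && is.null(base::names(sets)))
    stop("gene sets must be named")
  if (anyDuplicated(base::names(sets)))
    stop("pathway IDs must be unique")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0))
    stop("gene sets must be non-empty")
  if (is.null(names)) {
    names <- stats::setNames(base::names(sets), base::names(sets))
  }
  structure(list(sets = sets, names = names, annotation = annotation),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d sets, sizes %s\n", length(x$sets),
              if (length(x$sets)) paste0(min(lengths(x$sets)), "-",
                                         max(lengths(x$sets))) else "-"))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$sets)

#' Analysis configuration
#'
#' Holds the pipeline constants: the enrichment significance level (0.01),
#' the permutation count (10,000), the minimum retained pathway size (11
#' measured genes; sets of 10 or fewer are discarded), the within-group
#' significance fraction (0.8) for the shared-pathway filter, the 5% overlap
#' rule and minimum degree 3 for the network, the survival screening level
#' (0.1), and the cross-validation / neural-net settings.
#'
#' @param alpha_enrich Permutation significance level for enrichment.
#' @param n_permutations Number of sample relabelings (B).
#' @param min_pathway_size Minimum number of measured genes for a pathway to
#'   be scored.
#' @param group_fraction Fraction of a cancer group's studies in which a
#'   pathway must be significant to pass the group filter.
#' @param overlap_fraction Minimum shared-gene fraction for a network edge.
#' @param min_network_degree Nodes with fewer neighbours are pruned.
#' @param alpha_survival Screening level for the median-split log-rank test.
#' @param cv_folds Number of cross-validation folds.
#' @param nn_hidden Hidden nodes in the neural-net classifier.
#' @param nn_decay Weight decay for the neural-net classifier.
#' @param seed Integer seed used by seeded operations when none is supplied.
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(alpha_enrich = 0.01, n_permutations = 10000,
                            min_pathway_size = 11, group_fraction = 0.8,
                            overlap_fraction = 0.05, min_network_degree = 3,
                            alpha_survival = 0.1, cv_folds = 5,
                            nn_hidden = 3, nn_decay = 0.01, seed = 1L) {
  cfg <- list(alpha_enrich = alpha_enrich, n_permutations = n_permutations,
              min_pathway_size = min_pathway_size,
              group_fraction = group_fraction,
              overlap_fraction = overlap_fraction,
              min_network_degree = min_network_degree,
              alpha_survival = alpha_survival, cv_folds = cv_folds,
              nn_hidden = nn_hidden, nn_decay = nn_decay,
              seed = as.integer(seed))
  validate_analysis_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_analysis_config <- function(cfg) {
  lv <- c("alpha_enrich", "group_fraction", "overlap_fraction",
          "alpha_survival")
  for (k in lv) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v >= 1)
      stop("config value '", k, "' must lie in (0, 1); got ", v)
  }
  cv <- c("n_permutations", "min_pathway_size", "min_network_degree",
          "cv_folds", "nn_hidden")
  for (k in cv) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stop("config value '", k, "' must be a positive integer; got ", v)
  }
  if (!is.numeric(cfg$nn_decay) || cfg$nn_decay < 0)
    stop("config value 'nn_decay' must be non-negative")
  invisible(cfg)
}

#' Load an analysis configuration from a YAML file
#'
#' Keys absent from the file take the standard defaults (see
#' \code{\link{analysis_config}}); unknown keys are an error, as are values
#' outside their valid range.
#'
#' @param path Path to a YAML file (may be empty).
#' @return An \code{analysis_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Read gene sets from a GMT file
#'
#' One set per non-empty line: set name, description, then tab-separated gene
#' IDs. Duplicate genes within a line are dropped.
#'
#' @param path Path to the GMT file.
#' @return A \code{\link{pathway_collection}}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(pathway_collection(stats::setNames(list(), character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed GMT line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, character(1), 1L)
  descs <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  pathway_collection(sets, names = stats::setNames(descs, ids))
}

#' Write gene sets to a GMT file
#'
#' @param pathways A \code{\link{pathway_collection}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  ids <- names(pathways$sets)
  lines <- vapply(ids, function(id) {
    paste(c(id, pathways$names[[id]], pathways$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression study from tab-delimited files
#'
#' The matrix file has a gene-ID column followed by one column per sample;
#' the annotation file has columns \code{sample_id}, \code{class} (case or
#' control) and optionally \code{pair_id}. Duplicate gene rows are collapsed
#' by keeping the row with the highest mean expression. When
#' \code{scale = "linear"} values are transformed to log2(x + 1).
#'
#' @param matrix_path Path to the expression table.
#' @param annotation_path Path to the sample annotation table.
#' @param study_code Study identifier (defaults to the matrix file name).
#' @param disease_group Disease-group label.
#' @param scale \code{"log2"} (stored as-is) or \code{"linear"}.
#' @return An \code{\link{expression_study}}.
#' @export
read_expression <- function(matrix_path, annotation_path,
                            study_code = NULL, disease_group = "unknown",
                            scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (is.null(study_code))
    study_code <- sub("\\.[^.]+$", "", basename(matrix_path))
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyDuplicated(gene_ids)) {
    means <- rowMeans(mat)
    ord <- order(gene_ids, -means)
    keep <- ord[!duplicated(gene_ids[ord])]
    keep <- sort(keep)
    mat <- mat[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  rownames(mat) <- gene_ids
  if (scale == "linear") mat <- log2(mat + 1)

  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  req <- c("sample_id", "class")
  if (!all(req %in% names(ann)))
    stop("annotation must contain columns: ", paste(req, collapse = ", "))
  missing_ann <- setdiff(colnames(mat), ann$sample_id)
  missing_mat <- setdiff(ann$sample_id, colnames(mat))
  if (length(missing_ann) || length(missing_mat))
    stop("annotation/matrix sample mismatch; unlabelled samples: [",
         paste(missing_ann, collapse = ", "), "]; samples absent from matrix: [",
         paste(missing_mat, collapse = ", "), "]")
  ann <- ann[match(colnames(mat), ann$sample_id), ]
  pairing <- NULL
  if ("pair_id" %in% names(ann) && any(nzchar(ann$pair_id) & !is.na(ann$pair_id))) {
    ok <- !is.na(ann$pair_id) & nzchar(ann$pair_id)
    pr <- split(ann$sample_id[ok], ann$pair_id[ok])
    cases <- vapply(pr, function(s) s[ann$class[match(s, ann$sample_id)] == "case"][1], character(1))
    ctrls <- vapply(pr, function(s) s[ann$class[match(s, ann$sample_id)] == "control"][1], character(1))
    pairing <- stats::setNames(ctrls, cases)
  }
  expression_study(study_code, disease_group, mat,
                   sample_labels = ann$class, pairing = pairing)
}

#' Write an expression study to tab-delimited files
#'
#' @param study An \code{\link{expression_study}}.
#' @param matrix_path Output path for the expression table.
#' @param annotation_path Output path for the sample annotation.
#' @return \code{matrix_path}, invisibly.
#' @export
write_expression <- function(study, matrix_path, annotation_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene_id = study$gene_ids, study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(sample_id = names(study$sample_labels),
                    class = unname(study$sample_labels),
                    stringsAsFactors = FALSE)
  if (!is.null(study$pairing)) {
    pair_id <- stats::setNames(rep(NA_character_, nrow(ann)), ann$sample_id)
    pid <- paste0("pair", seq_along(study$pairing))
    pair_id[names(study$pairing)] <- pid
    pair_id[unname(study$pairing)] <- pid
    ann$pair_id <- unname(pair_id)
  }
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read a clinical table (patient_id, days, event)
#'
#' @param path Tab-delimited file with columns \code{patient_id},
#'   \code{days} (non-negative follow-up days) and \code{event}
#'   (1 = death, 0 = censored).
#' @return A data.frame with those columns.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "days", "event")
  if (!all(req %in% names(cl)))
    stop("clinical table must contain columns: ", paste(req, collapse = ", "))
  if (any(cl$days < 0)) stop("negative follow-up days")
  if (!all(cl$event %in% c(0, 1))) stop("event must be 0 or 1")
  cl[req]
}

#' Restrict studies to their common gene universe
#'
#' Mirrors the multi-study convention of analysing only genes measured in
#' every study: all returned studies contain exactly the intersection of
#' gene IDs, in identical order.
#'
#' @param studies List of \code{\link{expression_study}} objects.
#' @return The studies, each restricted to the common genes.
#' @export
intersect_gene_universe <- function(studies) {
  if (!length(studies)) stop("need at least one study")
  common <- Reduce(intersect, lapply(studies, `[[`, "gene_ids"))
  if (!length(common))
    stop("gene universes have empty intersection")
  lapply(studies, function(s) {
    s$matrix <- s$matrix[common, , drop = FALSE]
    s$gene_ids <- common
    s
  })
}
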