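# Case-indicator matrix for permutation relabelings.
#
# Sampled mode permutes the label vector itself (column b marks sample i as
# case iff labels[perm_b[i]] == "case"), so swapping the case/control labels
# of the study maps every relabeling to its complement and leaves the null
# distribution of |S| unchanged. When the number of distinct relabelings
# choose(n, n_case) is <= B, all of them are enumerated instead of sampled.
perm_case_matrix <- function(labels, B, seed) {
  n <- length(labels)
  is_case <- labels == "case"
  n1 <- sum(is_case)
  n_distinct <- suppressWarnings(choose(n, n1))
  if (is.finite(n_distinct) && n_distinct <= B) {
    sets <- utils::combn(n, n1)
    P <- matrix(0, nrow = n, ncol = ncol(sets))
    P[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n1))] <- 1
    return(list(P = P, exhaustive = TRUE))
  }
  set.seed(seed)
  P <- matrix(0, nrow = n, ncol = B)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    P[is_case[perm], b] <- 1
  }
  list(P = P, exhaustive = FALSE)
}

# Pooled-variance two-sample t-statistics (case minus control) for every gene
# under every relabeling. X: genes x samples; P: samples x B case indicators
# with constant column sum. Genes with zero pooled variance get t = 0.
tstat_matrix <- function(X, P) {
  n1 <- sum(P[, 1])
  n0 <- nrow(P) - n1
  if (n1 < 2 || n0 < 2)
    stop("need at least 2 samples in each arm to compute t-statistics")
  X2 <- X * X
  s1 <- X %*% P
  q1 <- X2 %*% P
  rs <- rowSums(X)
  rs2 <- rowSums(X2)
  m1 <- s1 / n1
  m0 <- (rs - s1) / n0
  ssq1 <- q1 - s1 * s1 / n1
  ssq0 <- (rs2 - q1) - (rs - s1)^2 / n0
  sp2 <- (ssq1 + ssq0) / (n1 + n0 - 2)
  # zero-variance threshold scales with the gene's own magnitude so that
  # rescaling the expression matrix leaves the flag (and t) unchanged
  tol <- 1e-9 * (rs2 / (n1 + n0)) + .Machine$double.xmin
  se <- sqrt(pmax(sp2, 0) * (1 / n1 + 1 / n0))
  t <- (m1 - m0) / se
  t[sp2 <= tol] <- 0
  t
}

#' Gene-level t-statistics for a case/control study
#'
#' Pooled-variance two-sample t per gene, oriented case minus control. Genes
#' whose pooled variance is zero are assigned t = 0 and flagged.
#'
#' @param study An \code{\link{expression_study}} with >= 2 samples per arm.
#' @return A data.frame with columns \code{gene_id}, \code{t},
#'   \code{zero_variance}.
#' @export
gene_tstats <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  labels <- study$sample_labels
  if (sum(labels == "case") < 2 || sum(labels == "control") < 2)
    stop("need at least 2 case and 2 control samples")
  P <- matrix(as.numeric(labels == "case"), ncol = 1)
  t <- tstat_matrix(study$matrix, P)[, 1]
  data.frame(gene_id = study$gene_ids, t = unname(t),
             zero_variance = unname(t == 0 &
               apply(study$matrix, 1, function(r) stats::var(r) == 0)),
             stringsAsFactors = FALSE)
}

#' Pathway activity score
#'
#' The weighted average of gene-level t-statistics over a gene set: the sum
#' of the t-statistics of the measured pathway genes divided by the square
#' root of their number. Positive scores indicate up-regulation in cases.
#'
#' @param tstats Either the data.frame returned by \code{\link{gene_tstats}}
#'   or a named numeric vector of t-statistics.
#' @param pathway_genes Character vector of gene IDs.
#' @return The score S (length-1 numeric) with attribute \code{n_genes_used}.
#' @export
pathway_score <- function(tstats, pathway_genes) {
  if (is.data.frame(tstats))
    tstats <- stats::setNames(tstats$t, tstats$gene_id)
  genes <- intersect(pathway_genes, names(tstats))
  if (!length(genes))
    stop("no pathway genes measured in the study")
  s <- sum(tstats[genes]) / sqrt(length(genes))
  attr(s, "n_genes_used") <- length(genes)
  s
}

perm_pvalue <- function(s_obs, s_sim, alternative) {
  tol <- 1e-8 * (1 + abs(s_obs))
  switch(alternative,
         two.sided = mean(abs(s_sim) >= abs(s_obs) - tol),
         greater   = mean(s_sim >= s_obs - tol),
         less      = mean(s_sim <= s_obs + tol))
}

#' Permutation null for a single pathway score
#'
#' Relabels samples as case/control (preserving arm sizes) B times,
#' recomputes every gene-level t-statistic and the pathway score for each
#' relabeling, and reports the fraction of simulated scores at least as
#' extreme as the observed score. When the number of distinct relabelings is
#' at most B, all of them are enumerated exactly instead of sampled.
#'
#' @param study An \code{\link{expression_study}}.
#' @param pathway_genes Character vector of gene IDs.
#' @param B Number of relabelings (>= 100).
#' @param seed Integer seed (ignored in exhaustive mode).
#' @param alternative \code{"two.sided"} (extremeness on |S|, the default),
#'   \code{"greater"} or \code{"less"}.
#' @return A list of class \code{pathway_score_result}: \code{n_genes_used},
#'   \code{score}, \code{p_perm}, \code{direction}, \code{null_mean},
#'   \code{null_sd}, \code{exhaustive}.
#' @export
permutation_null <- function(study, pathway_genes, B = 10000, seed = 1L,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(study, "expression_study"))
  if (B < 100) stop("B must be >= 100 (permutation null too unstable)")
  genes <- intersect(pathway_genes, study$gene_ids)
  if (!length(genes)) stop("no pathway genes measured in the study")
  X <- study$matrix[genes, , drop = FALSE]
  labels <- study$sample_labels
  obs <- tstat_matrix(X, matrix(as.numeric(labels == "case"), ncol = 1))[, 1]
  s_obs <- sum(obs) / sqrt(length(genes))
  pm <- perm_case_matrix(labels, B, seed)
  s_sim <- colSums(tstat_matrix(X, pm$P)) / sqrt(length(genes))
  structure(
    list(n_genes_used = length(genes), score = s_obs,
         p_perm = perm_pvalue(s_obs, s_sim, alternative),
         direction = sign(s_obs),
         null_mean = mean(s_sim), null_sd = stats::sd(s_sim),
         exhaustive = pm$exhaustive),
    class = "pathway_score_result")
}

#' Score every pathway in a study
#'
#' Applies the size filter (pathways with fewer than
#' \code{config$min_pathway_size} measured genes are discarded, i.e. sets of
#' 10 or fewer under the defaults), then computes the observed score and
#' permutation p-value for every retained pathway. A single set of B
#' relabelings is drawn per study and shared across all pathways, so the
#' pathway null distributions are computed from the same relabeled
#' t-statistic matrix.
#'
#' @param study An \code{\link{expression_study}}.
#' @param pathways A \code{\link{pathway_collection}}.
#' @param config An \code{\link{analysis_config}}.
#' @param seed Integer seed (default \code{config$seed}).
#' @param alternative Sidedness of the permutation p-value.
#' @return A data.frame with one row per retained pathway: \code{pathway_id},
#'   \code{n_genes_used}, \code{score}, \code{p_perm}, \code{direction},
#'   \code{null_mean}, \code{null_sd}. Skipped (too-small) pathway IDs are in
#'   attribute \code{"skipped"}.
#' @export
score_study <- function(study, pathways, config = analysis_config(),
                        seed = config$seed,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(study, "expression_study"),
            inherits(pathways, "pathway_collection"))
  measured <- lapply(pathways$sets, intersect, study$gene_ids)
  sizes <- lengths(measured)
  retained <- names(measured)[sizes >= config$min_pathway_size]
  skipped <- setdiff(names(measured), retained)
  if (length(skipped))
    message("score_study(", study$study_code, "): skipped ", length(skipped),
            " pathway(s) with fewer than ", config$min_pathway_size,
            " measured genes: ", paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  if (!length(retained))
    stop("no pathway has >= ", config$min_pathway_size, " measured genes")

  X <- study$matrix
  labels <- study$sample_labels
  t_obs <- tstat_matrix(X, matrix(as.numeric(labels == "case"), ncol = 1))
  pm <- perm_case_matrix(labels, config$n_permutations, seed)
  t_sim <- tstat_matrix(X, pm$P)

  M <- matrix(0, nrow = length(retained), ncol = nrow(X),
              dimnames = list(retained, rownames(X)))
  for (pid in retained) M[pid, measured[[pid]]] <- 1
  w <- 1 / sqrt(sizes[retained])
  s_obs <- as.vector(M %*% t_obs) * w
  s_sim <- (M %*% t_sim) * w

  p <- vapply(seq_along(retained), function(i)
    perm_pvalue(s_obs[i], s_sim[i, ], alternative), numeric(1))
  res <- data.frame(
    pathway_id = retained,
    n_genes_used = as.integer(sizes[retained]),
    score = s_obs,
    p_perm = p,
    direction = sign(s_obs),
    null_mean = rowMeans(s_sim),
    null_sd = apply(s_sim, 1, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "skipped") <- skipped
  attr(res, "exhaustive") <- pm$exhaustive
  res
}

#' Write per-study pathway score results
#'
#' Tab-delimited emit of a \code{\link{score_study}} result. A permutation
#' p-value of exactly 0 is rendered as \code{< 1/B} in the text output
#' (column \code{p_display}); the numeric column keeps the raw fraction.
#'
#' @param results \code{\link{score_study}} data.frame.
#' @param path Output path.
#' @param B Permutation count used (for the \code{< 1/B} display).
#' @return \code{path}, invisibly.
#' @export
write_score_results <- function(results, path, B = 10000) {
  out <- results
  out$p_display <- ifelse(results$p_perm == 0, paste0("< ", format(1 / B)),
                          format(results$p_perm))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
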