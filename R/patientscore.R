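#' Patient-normalized expression (tumour minus normal)
#'
#' Element-wise difference E = T - N between a patient's tumour and adjacent
#' normal log2 expression vectors.
#'
#' @param tumour,normal Named numeric vectors with identical gene order.
#' @return Named numeric vector E.
#' @export
patient_normalized_expression <- function(tumour, normal) {
  if (length(tumour) != length(normal))
    stop("tumour and normal vectors differ in length")
  if (!identical(names(tumour), names(normal)))
    stop("tumour and normal vectors differ in gene order")
  tumour - normal
}

#' Per-patient pathway scores
#'
#' For each selected pathway P, Z_P = sum over measured pathway genes of E_g,
#' divided by the square root of the number of genes actually used. Genes
#' missing from the patient's vector are dropped per pathway (the divisor is
#' adjusted); a pathway with no measured gene is skipped with a message.
#'
#' @param E Named numeric vector from
#'   \code{\link{patient_normalized_expression}}.
#' @param pathways A \code{\link{pathway_collection}} (typically restricted
#'   to the selected shared pathways).
#' @return Named numeric vector of scores Z, one per scored pathway, with
#'   attribute \code{n_genes_used}.
#' @export
patient_pathway_scores <- function(E, pathways) {
  stopifnot(inherits(pathways, "pathway_collection"))
  measured <- lapply(pathways$sets, intersect, names(E))
  empty <- names(measured)[lengths(measured) == 0]
  if (length(empty))
    message("patient_pathway_scores: skipped pathway(s) with no measured ",
            "gene: ", paste(empty, collapse = ", "))
  measured <- measured[lengths(measured) > 0]
  z <- vapply(measured, function(g) sum(E[g]) / sqrt(length(g)), numeric(1))
  attr(z, "n_genes_used") <- lengths(measured)
  z
}

#' Score every patient of a paired cohort
#'
#' Applies E = T - N and the pathway score to each patient.
#'
#' @param tumour,normal Genes x patients matrices with identical dimnames.
#' @param pathways A \code{\link{pathway_collection}}.
#' @return Patients x pathways numeric matrix of scores Z.
#' @export
score_patients <- function(tumour, normal, pathways) {
  if (!identical(dimnames(tumour), dimnames(normal)))
    stop("tumour and normal matrices must share dimnames")
  E <- tumour - normal
  measured <- lapply(pathways$sets, intersect, rownames(E))
  measured <- measured[lengths(measured) > 0]
  if (!length(measured)) stop("no pathway gene measured in the cohort")
  z <- vapply(measured, function(g)
    colSums(E[g, , drop = FALSE]) / sqrt(length(g)), numeric(ncol(E)))
  if (ncol(E) == 1) z <- matrix(z, nrow = 1,
                                dimnames = list(colnames(E), names(measured)))
  z
}

#' Write the patients x pathways score table
#'
#' @param scores Matrix from \code{\link{score_patients}}.
#' @param path Output path (tab-delimited).
#' @return \code{path}, invisibly.
#' @export
write_patient_scores <- function(scores, path) {
  df <- data.frame(patient_id = rownames(scores), scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
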