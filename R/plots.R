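#' Heat map of the pathway-score matrix
#'
#' @param mat A \code{\link{build_score_matrix}} result.
#' @param pathway_subset Optional pathway IDs to display.
#' @param file Optional PNG path; when given the plot is written there.
#' @param ... Passed to \code{\link[stats]{heatmap}}.
#' @return \code{NULL}, invisibly.
#' @export
plot_score_heatmap <- function(mat, pathway_subset = NULL, file = NULL, ...) {
  stopifnot(inherits(mat, "score_matrix"))
  m <- mat$scores
  if (!is.null(pathway_subset)) m <- m[pathway_subset, , drop = FALSE]
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900)
    on.exit(grDevices::dev.off())
  }
  stats::heatmap(m, scale = "none",
                 col = grDevices::hcl.colors(64, "Green-Orange"), ...)
  invisible(NULL)
}

#' Box plot of group-mean pathway scores
#'
#' @param group_means Pathways x groups matrix from
#'   \code{\link{group_summary}}.
#' @param file Optional PNG path.
#' @return \code{NULL}, invisibly.
#' @export
plot_group_boxplot <- function(group_means, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(as.data.frame(group_means),
                    ylab = "mean pathway score", xlab = "disease group")
  graphics::abline(h = 0, lty = 2)
  invisible(NULL)
}

#' Kaplan-Meier plot for a median-split comparison
#'
#' @param assoc A \code{\link{logrank_association}} result.
#' @param main Plot title.
#' @param file Optional PNG path.
#' @return \code{NULL}, invisibly.
#' @export
plot_km <- function(assoc, main = "", file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(assoc$fit, col = c("blue", "red"), xlab = "days",
                 ylab = "survival probability",
                 main = sprintf("%s (log-rank p = %.3g)", main, assoc$p))
  graphics::legend("topright", legend = c("low score", "high score"),
                   col = c("blue", "red"), lty = 1)
  invisible(NULL)
}

#' Degree-distribution plot of the overlap network
#'
#' @param network An \code{\link{build_overlap_network}} result.
#' @param file Optional PNG path.
#' @return \code{NULL}, invisibly.
#' @export
plot_degree_distribution <- function(network, file = NULL) {
  dd <- degree_distribution(network)
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(as.integer(names(dd)), dd, type = "h", lwd = 3,
                 xlab = "degree", ylab = "relative frequency")
  invisible(NULL)
}
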