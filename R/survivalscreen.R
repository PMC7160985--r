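#' Median split of patient pathway scores
#'
#' Patients with score strictly above the median form the high group; scores
#' at or below the median (including ties) form the low group. If either
#' group would be empty (e.g. all scores identical) the split is refused and
#' \code{NULL} is returned with a message, so the pathway can be skipped.
#'
#' @param scores Named numeric vector (one pathway's score per patient,
#'   >= 4 patients).
#' @return Named character vector of \code{"high"}/\code{"low"}, or
#'   \code{NULL} when no valid split exists.
#' @export
median_split <- function(scores) {
  if (length(scores) < 4) stop("need at least 4 patients for a median split")
  med <- stats::median(scores)
  grp <- ifelse(scores > med, "high", "low")
  if (length(unique(grp)) < 2) {
    message("median_split: no valid split (all scores on one side of the ",
            "median); pathway skipped")
    return(NULL)
  }
  stats::setNames(grp, names(scores))
}

#' Log-rank association between a score split and survival
#'
#' Two-group log-rank test of the Kaplan-Meier curves for the high- and
#' low-score patients.
#'
#' @param records Data.frame with columns \code{patient_id}, \code{days},
#'   \code{event} (1 = death, 0 = censored).
#' @param assignment Named \code{"high"}/\code{"low"} vector from
#'   \code{\link{median_split}} (names = patient IDs).
#' @param warn_no_events Flag the comparison as unstable when a group has no
#'   events.
#' @return A list: \code{p} (log-rank p-value), \code{chisq}, \code{fit}
#'   (survfit object for plotting), \code{unstable}.
#' @export
logrank_association <- function(records, assignment, warn_no_events = TRUE) {
  if (is.null(names(assignment)))
    stop("assignment must be named by patient ID")
  idx <- match(names(assignment), records$patient_id)
  if (anyNA(idx)) stop("patients missing from clinical records: ",
                       paste(names(assignment)[is.na(idx)], collapse = ", "))
  dat <- data.frame(days = records$days[idx], event = records$event[idx],
                    group = factor(assignment, levels = c("low", "high")))
  if (any(table(dat$group) == 0)) stop("a split group has zero patients")
  events_per_group <- tapply(dat$event, dat$group, sum)
  unstable <- any(events_per_group == 0)
  if (unstable && warn_no_events)
    warning("a score group has zero events; log-rank comparison is unstable")
  sd_fit <- survival::survdiff(survival::Surv(days, event) ~ group, data = dat)
  p <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(days, event) ~ group, data = dat)
  list(p = unname(p), chisq = unname(sd_fit$chisq), fit = fit,
       unstable = unstable)
}

#' Integer percentage of a screened proportion
#'
#' @param n_hit,n_total Counts.
#' @return \code{round(100 * n_hit / n_total)} as an integer.
#' @export
screen_percent <- function(n_hit, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  as.integer(round(100 * n_hit / n_total))
}

#' Median-split survival screen over all pathways
#'
#' For each pathway, splits the patients at the median score and tests the
#' high/low Kaplan-Meier curves with the log-rank test; reports the
#' proportion of pathways associated with survival at
#' \code{alpha_survival} (p < 0.1 under the defaults), converted to an
#' integer percentage of all screened pathways.
#'
#' @param scores Patients x pathways matrix (e.g. from
#'   \code{\link{score_patients}}).
#' @param records Clinical data.frame (\code{patient_id}, \code{days},
#'   \code{event}).
#' @param config An \code{\link{analysis_config}}.
#' @return A list: \code{pvals} (named per-pathway p, NA when skipped),
#'   \code{n_associated}, \code{n_pathways}, \code{percent_associated}.
#' @export
survival_screen <- function(scores, records, config = analysis_config()) {
  if (is.null(rownames(scores))) stop("scores must have patient IDs as rownames")
  pvals <- vapply(colnames(scores), function(pw) {
    split <- median_split(scores[, pw])
    if (is.null(split)) return(NA_real_)
    logrank_association(records, split, warn_no_events = FALSE)$p
  }, numeric(1))
  n_assoc <- sum(pvals < config$alpha_survival, na.rm = TRUE)
  list(pvals = pvals, n_associated = n_assoc, n_pathways = ncol(scores),
       percent_associated = screen_percent(n_assoc, ncol(scores)))
}

#' 2x2 contingency analysis of infection status by cancer group
#'
#' Per-group percentages, a two-sided Fisher exact test, and the sample odds
#' ratio (ad/bc). A chi-square test is available by flag.
#'
#' @param counts 2x2 matrix: rows = groups (e.g. SLC, CA), columns =
#'   status (e.g. integrated, not integrated).
#' @param test \code{"fisher"} (default) or \code{"chisq"}.
#' @return A list: \code{percent} (per-group percent with the status),
#'   \code{p}, \code{odds_ratio}, \code{test}.
#' @export
contingency_analysis <- function(counts, test = c("fisher", "chisq")) {
  test <- match.arg(test)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: a zero margin")
  pct <- 100 * counts[, 1] / rowSums(counts)
  p <- if (test == "fisher") stats::fisher.test(counts)$p.value
       else stats::chisq.test(counts)$p.value
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  list(percent = pct, p = p, odds_ratio = unname(or), test = test)
}
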