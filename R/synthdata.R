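#' Simulation configuration
#'
#' Defines the synthetic study conditions: a gene universe, overlapping gene
#' sets, planted per-pathway mean shifts that are concordant between the
#' septic-shock (SS) and sepsis-like-cancer (SLC) groups and discordant in the
#' cancer-alone (CA) group, paired tumour/normal patients, survival times
#' whose hazard depends on a designated pathway score, and group-dependent
#' infection labels.
#'
#' Defaults emulate the structure the pipeline assumes: 6 studies per disease
#' group with 20 case and 20 control samples each, 100 pathways of 15-40
#' genes of which the first 20 are perturbed (log2 shift 1.0, per-gene noise
#' SD 1.0, upward in SS and SLC, downward in CA), chained 50% set overlap,
#' a log-hazard of 1.5 per SD of the designated pathway score, and infection
#' rates of 7.5% (SLC) versus 0.66% (CA).
#'
#' @param n_genes Size of the gene universe.
#' @param n_pathways Number of gene sets.
#' @param pathway_size_range Length-2 integer vector (min, max) set sizes;
#'   the minimum must be at least 11 (smaller sets are discarded from
#'   scoring).
#' @param overlap_factor Fraction in [0, 1): consecutive pathways share
#'   \code{round(overlap_factor * min(size_i, size_{i+1}))} genes.
#' @param effect_size Mean log2 shift per perturbed gene (>= 0).
#' @param noise_sd Per-gene standard deviation on the log2 scale.
#' @param n_perturbed Number of planted (perturbed) pathways.
#' @param group_templates Named list: disease group -> list(pathways =
#'   pathway IDs, sign = +1 or -1). \code{NULL} gives the default
#'   SS/SLC-concordant, CA-discordant layout over the first
#'   \code{n_perturbed} pathways.
#' @param n_studies_per_group Named integer vector of studies per group.
#' @param n_case,n_control Samples per arm in each study.
#' @param n_patients Paired tumour/normal patients per cancer group.
#' @param hazard_coefficient Log-hazard per standard deviation of the
#'   designated pathway score.
#' @param hazard_pathway Pathway whose patient score drives the hazard
#'   (default: the first planted pathway).
#' @param infection_rates Named probabilities of the binary infection label
#'   per cancer group.
#' @param baseline_median_days Median survival (days) at hazard ratio 1.
#' @param censor_horizon Administrative censoring time in days (default
#'   5 x \code{baseline_median_days}).
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genes = 2000, n_pathways = 100,
                              pathway_size_range = c(15L, 40L),
                              overlap_factor = 0.5,
                              effect_size = 1.0, noise_sd = 1.0,
                              n_perturbed = 20,
                              group_templates = NULL,
                              n_studies_per_group = c(SS = 6L, SLC = 6L, CA = 6L),
                              n_case = 20L, n_control = 20L,
                              n_patients = 100L,
                              hazard_coefficient = 1.5,
                              hazard_pathway = NULL,
                              infection_rates = c(SLC = 0.075, CA = 0.0066),
                              baseline_median_days = 1000,
                              censor_horizon = 5 * baseline_median_days,
                              seed = 1L) {
  if (pathway_size_range[1] < 11)
    stop("pathway_size_range minimum must be >= 11 (smaller sets are discarded)")
  if (pathway_size_range[1] > pathway_size_range[2])
    stop("pathway_size_range must be (min, max) with min <= max")
  if (overlap_factor < 0 || overlap_factor >= 1)
    stop("overlap_factor must lie in [0, 1)")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (any(infection_rates < 0 | infection_rates > 1))
    stop("infection_rates must lie in [0, 1]")
  if (!is.finite(hazard_coefficient))
    stop("hazard_coefficient must be finite")
  pw_ids <- sprintf("PW%03d", seq_len(n_pathways))
  if (is.null(group_templates)) {
    if (n_perturbed > n_pathways)
      stop("n_perturbed exceeds n_pathways")
    planted <- pw_ids[seq_len(n_perturbed)]
    group_templates <- list(
      SS  = list(pathways = planted, sign = +1),
      SLC = list(pathways = planted, sign = +1),
      CA  = list(pathways = planted, sign = -1))
  }
  for (g in names(group_templates)) {
    tpl <- group_templates[[g]]
    if (!all(tpl$pathways %in% pw_ids))
      stop("group template '", g, "' references unknown pathway IDs")
    if (!tpl$sign %in% c(-1, 1))
      stop("group template sign must be +1 or -1")
  }
  if (!all(names(n_studies_per_group) %in% names(group_templates)))
    stop("n_studies_per_group names must match group_templates")
  if (is.null(hazard_pathway))
    hazard_pathway <- group_templates[[1]]$pathways[1]
  structure(
    list(n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
         pathway_size_range = as.integer(pathway_size_range),
         overlap_factor = overlap_factor, effect_size = effect_size,
         noise_sd = noise_sd, pathway_ids = pw_ids,
         group_templates = group_templates,
         n_studies_per_group = n_studies_per_group,
         n_case = as.integer(n_case), n_control = as.integer(n_control),
         n_patients = as.integer(n_patients),
         hazard_coefficient = hazard_coefficient,
         hazard_pathway = hazard_pathway,
         infection_rates = infection_rates,
         baseline_median_days = baseline_median_days,
         censor_horizon = censor_horizon, seed = as.integer(seed)),
    class = "simulation_config")
}

# deterministic child seed, kept within 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Generate an overlapping pathway collection
#'
#' Emulates curated gene-set collections with shared membership: gene-set
#' sizes are drawn uniformly from \code{pathway_size_range}, and each pathway
#' shares \code{round(overlap_factor * min(size_i, size_{i+1}))} genes with
#' its predecessor (sampled from the predecessor's membership, so shared
#' blocks propagate along the chain and produce hub structure).
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{\link{pathway_collection}}; reproducible for a fixed seed.
#' @export
make_pathway_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$seed, 1L))
  np <- config$n_pathways
  size_choices <- seq(config$pathway_size_range[1], config$pathway_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), np, replace = TRUE)]
  n_share <- c(0L, vapply(seq_len(np - 1L), function(i) {
    as.integer(round(config$overlap_factor * min(sizes[i], sizes[i + 1L])))
  }, integer(1)))
  # the overlap chain restarts after the planted block so that planted gene
  # shifts never leak into unperturbed sets: sensitivity and false-positive
  # bookkeeping over the planted pathways stay well defined
  perturbed <- config$pathway_ids %in%
    unique(unlist(lapply(config$group_templates, `[[`, "pathways")))
  boundary <- which(perturbed[-1L] != perturbed[-np]) + 1L
  n_share[boundary] <- 0L
  fresh_needed <- sum(sizes - n_share)
  if (fresh_needed > config$n_genes)
    stop("configuration error: gene universe (", config$n_genes,
         " genes) too small for ", np, " sets needing ", fresh_needed,
         " distinct genes")
  universe <- sprintf("g%05d", seq_len(config$n_genes))
  next_free <- 1L
  sets <- vector("list", np)
  for (i in seq_len(np)) {
    shared <- if (n_share[i] > 0)
      sample(sets[[i - 1L]], n_share[i]) else character()
    n_new <- sizes[i] - length(shared)
    fresh <- universe[seq.int(next_free, length.out = n_new)]
    next_free <- next_free + n_new
    sets[[i]] <- c(shared, fresh)
  }
  names(sets) <- config$pathway_ids
  pathway_collection(sets,
                     names = stats::setNames(paste("Synthetic pathway",
                                                   config$pathway_ids),
                                             config$pathway_ids))
}

# union of perturbed-pathway genes for one group template (no shift stacking)
template_shift <- function(template, pathways, config) {
  tpl <- config$group_templates[[template]]
  genes <- unique(unlist(pathways$sets[tpl$pathways], use.names = FALSE))
  shift <- stats::setNames(numeric(config$n_genes),
                           sprintf("g%05d", seq_len(config$n_genes)))
  shift[genes] <- tpl$sign * config$effect_size
  shift
}

#' Simulate one case/control expression study
#'
#' Control samples are drawn i.i.d. per gene from N(0, noise_sd) on the log2
#' scale; case samples have their means shifted by +/- effect_size for every
#' gene belonging to at least one of the group template's perturbed pathways
#' (a gene in several perturbed pathways is shifted once, not cumulatively).
#'
#' @param template Disease-group label present in the config's
#'   \code{group_templates}.
#' @param pathways The \code{\link{pathway_collection}} (gene membership for
#'   the planted shifts).
#' @param config A \code{\link{simulation_config}}.
#' @param seed Integer seed for this study.
#' @param study_code Optional study identifier.
#' @return An \code{\link{expression_study}}; deterministic for a fixed seed.
#' @export
simulate_study <- function(template, pathways, config, seed,
                           study_code = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!template %in% names(config$group_templates))
    stop("unknown group template: ", template)
  if (config$n_case < 1 || config$n_control < 1)
    stop("n_case and n_control must be >= 1")
  if (is.null(study_code)) study_code <- paste0(template, "_", seed)
  set.seed(seed)
  g <- config$n_genes
  n <- config$n_case + config$n_control
  mat <- matrix(stats::rnorm(g * n, sd = config$noise_sd), nrow = g)
  rownames(mat) <- sprintf("g%05d", seq_len(g))
  colnames(mat) <- sprintf("%s_smp%03d", study_code, seq_len(n))
  shift <- template_shift(template, pathways, config)
  case_cols <- seq_len(config$n_case)
  mat[, case_cols] <- mat[, case_cols] + shift
  labels <- c(rep("case", config$n_case), rep("control", config$n_control))
  expression_study(study_code, template, mat, labels)
}

#' Simulate paired tumour/normal patients with survival and infection labels
#'
#' Each patient's normal vector N is baseline noise; the tumour vector is
#' T = N + planted group shift + independent noise, so the paired difference
#' E = T - N has mean equal to the planted shift. Survival times follow an
#' exponential model whose log-hazard is \code{hazard_coefficient} times the
#' cohort-standardized patient score on the designated hazard pathway, with
#' administrative censoring at \code{censor_horizon}. The infection label is
#' Bernoulli with the group's configured rate.
#'
#' @param pathways A \code{\link{pathway_collection}}.
#' @param config A \code{\link{simulation_config}}.
#' @param seed Integer seed.
#' @param groups Cancer groups to simulate patients for (default: the
#'   configured infection-rate groups).
#' @return A list of class \code{patient_cohort} with elements
#'   \code{tumour}, \code{normal} (genes x patients matrices), \code{group},
#'   \code{clinical} (patient_id, days, event), \code{infection} and
#'   \code{hazard_pathway}.
#' @export
simulate_patients <- function(pathways, config, seed,
                              groups = names(config$infection_rates)) {
  stopifnot(inherits(config, "simulation_config"))
  groups <- intersect(groups, names(config$group_templates))
  if (!length(groups)) stop("no patient groups to simulate")
  set.seed(seed)
  g <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(g))
  per_group <- lapply(groups, function(grp) {
    n <- config$n_patients
    N <- matrix(stats::rnorm(g * n, sd = config$noise_sd), nrow = g)
    Tm <- N + matrix(stats::rnorm(g * n, sd = config$noise_sd), nrow = g) +
      template_shift(grp, pathways, config)
    rownames(N) <- rownames(Tm) <- gene_ids
    ids <- sprintf("%s_pt%03d", grp, seq_len(n))
    colnames(N) <- colnames(Tm) <- ids
    list(normal = N, tumour = Tm, group = stats::setNames(rep(grp, n), ids))
  })
  normal <- do.call(cbind, lapply(per_group, `[[`, "normal"))
  tumour <- do.call(cbind, lapply(per_group, `[[`, "tumour"))
  group <- do.call(c, lapply(per_group, `[[`, "group"))

  hz_genes <- pathways$sets[[config$hazard_pathway]]
  E <- tumour[hz_genes, , drop = FALSE] - normal[hz_genes, , drop = FALSE]
  z <- colSums(E) / sqrt(length(hz_genes))
  zstd <- as.numeric(scale(z))
  lambda0 <- log(2) / config$baseline_median_days
  raw_days <- stats::rexp(length(zstd),
                          rate = lambda0 * exp(config$hazard_coefficient * zstd))
  event <- as.integer(raw_days <= config$censor_horizon)
  days <- pmin(raw_days, config$censor_horizon)
  rates <- config$infection_rates[group]
  rates[is.na(rates)] <- 0
  infected <- stats::rbinom(length(group), 1, rates)
  structure(
    list(tumour = tumour, normal = normal, group = group,
         clinical = data.frame(patient_id = names(group), days = days,
                               event = event, stringsAsFactors = FALSE),
         infection = data.frame(patient_id = names(group),
                                infected = infected,
                                group = unname(group),
                                stringsAsFactors = FALSE),
         hazard_pathway = config$hazard_pathway),
    class = "patient_cohort")
}

#' Simulate a full multi-study cohort
#'
#' Generates the pathway collection, all configured studies per disease
#' group, and the paired patient cohort with clinical and infection labels.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list of class \code{synthetic_cohort} with elements
#'   \code{pathways}, \code{studies} (named list of
#'   \code{\link{expression_study}}), \code{patients}
#'   (\code{patient_cohort}) and \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pathways <- make_pathway_collection(config)
  studies <- list()
  k <- 10L
  for (grp in names(config$n_studies_per_group)) {
    n_st <- config$n_studies_per_group[[grp]]
    for (j in seq_len(n_st)) {
      k <- k + 1L
      code <- sprintf("%s_study%02d", grp, j)
      studies[[code]] <- simulate_study(grp, pathways, config,
                                        seed = child_seed(config$seed, k),
                                        study_code = code)
    }
  }
  patients <- simulate_patients(pathways, config,
                                seed = child_seed(config$seed, 2L))
  structure(list(pathways = pathways, studies = studies, patients = patients,
                 config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Emits the gene sets as GMT, one expression matrix and annotation per
#' study, paired tumour/normal matrices, and clinical and infection tables,
#' all tab-delimited.
#'
#' @param cohort A \code{\link{simulate_cohort}} result.
#' @param dir Output directory (created if absent).
#' @return Named list of written file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(gmt = file.path(dir, "pathways.gmt"))
  write_gmt(cohort$pathways, paths$gmt)
  paths$studies <- lapply(names(cohort$studies), function(code) {
    mp <- file.path(dir, paste0(code, "_expr.tsv"))
    ap <- file.path(dir, paste0(code, "_samples.tsv"))
    write_expression(cohort$studies[[code]], mp, ap)
    c(matrix = mp, annotation = ap)
  })
  names(paths$studies) <- names(cohort$studies)
  pc <- cohort$patients
  write_patient_matrix <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths$tumour <- file.path(dir, "patients_tumour.tsv")
  paths$normal <- file.path(dir, "patients_normal.tsv")
  write_patient_matrix(pc$tumour, paths$tumour)
  write_patient_matrix(pc$normal, paths$normal)
  paths$clinical <- file.path(dir, "clinical.tsv")
  utils::write.table(pc$clinical, paths$clinical, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$infection <- file.path(dir, "infection.tsv")
  utils::write.table(pc$infection, paths$infection, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$patient_groups <- file.path(dir, "patient_groups.tsv")
  utils::write.table(data.frame(patient_id = names(pc$group),
                                group = unname(pc$group)),
                     paths$patient_groups, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
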