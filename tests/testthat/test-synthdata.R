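test_that("pathway collections honour size range, overlap and determinism", {
  cfg <- simulation_config(n_genes = 2000, n_pathways = 10, n_perturbed = 2,
                           pathway_size_range = c(50L, 50L),
                           overlap_factor = 0.2, seed = 11)
  pw <- make_pathway_collection(cfg)
  expect_length(pw$sets, 10)
  expect_true(all(lengths(pw$sets) == 50))
  # consecutive sets share exactly round(0.2 * 50) = 10 genes; the chain
  # restarts after the planted block, so check a pair inside the null block
  inter <- length(intersect(pw$sets[["PW009"]], pw$sets[["PW010"]]))
  expect_identical(inter, 10L)
  # fixed seed -> bit-identical collection
  pw2 <- make_pathway_collection(cfg)
  expect_identical(pw, pw2)
  # all pathway genes live in the configured universe
  expect_true(all(unlist(pw$sets) %in% sprintf("g%05d", 1:2000)))
})

test_that("zero overlap factor gives pairwise-disjoint sets", {
  cfg <- simulation_config(n_genes = 3000, n_pathways = 8, n_perturbed = 2,
                           overlap_factor = 0, seed = 2)
  pw <- make_pathway_collection(cfg)
  for (i in 1:7) for (j in (i + 1):8)
    expect_length(intersect(pw$sets[[i]], pw$sets[[j]]), 0)
})

test_that("degenerate generator configurations are rejected", {
  expect_error(simulation_config(pathway_size_range = c(5L, 20L)), ">= 11")
  expect_error(simulation_config(effect_size = -1), "effect_size")
  expect_error(simulation_config(infection_rates = c(SLC = 1.2, CA = 0)),
               "infection_rates")
  expect_error(simulation_config(overlap_factor = 1), "overlap_factor")
  # universe too small for the requested sets
  cfg <- simulation_config(n_genes = 100, n_pathways = 50,
                           overlap_factor = 0, seed = 1)
  expect_error(make_pathway_collection(cfg), "too small")
  # single pathway is fine
  cfg1 <- simulation_config(n_genes = 100, n_pathways = 1, n_perturbed = 1,
                            seed = 1)
  expect_length(make_pathway_collection(cfg1)$sets, 1)
})

test_that("planted shifts are concordant between SS and SLC templates", {
  cfg <- simulation_config(n_genes = 800, n_pathways = 10, n_perturbed = 3,
                           n_case = 20, n_control = 20, seed = 4)
  pw <- make_pathway_collection(cfg)
  planted_genes <- unique(unlist(pw$sets[1:3]))
  mean_diff <- function(st) {
    case <- st$sample_labels == "case"
    rowMeans(st$matrix[planted_genes, case]) -
      rowMeans(st$matrix[planted_genes, !case])
  }
  agree <- replicate(20, {
    s <- sample.int(1e6, 1)
    d_ss <- mean_diff(simulate_study("SS", pw, cfg, seed = s))
    d_slc <- mean_diff(simulate_study("SLC", pw, cfg, seed = s + 1))
    mean(sign(d_ss) == sign(d_slc))
  })
  expect_gt(mean(agree), 0.95)
  # CA template shifts the same genes the other way
  set.seed(99)
  d_ca <- mean_diff(simulate_study("CA", pw, cfg, seed = 7))
  expect_lt(mean(d_ca), 0)
})

test_that("simulate_study validates its inputs and is seed-deterministic", {
  cfg <- simulation_config(n_genes = 200, n_pathways = 3, n_perturbed = 1,
                           n_case = 0, n_control = 10, seed = 1)
  pw_cfg <- simulation_config(n_genes = 200, n_pathways = 3, n_perturbed = 1,
                              seed = 1)
  pw <- make_pathway_collection(pw_cfg)
  expect_error(simulate_study("SS", pw, cfg, seed = 1), "n_case")
  expect_error(simulate_study("nope", pw, pw_cfg, seed = 1),
               "unknown group template")
  s1 <- simulate_study("SS", pw, pw_cfg, seed = 5)
  s2 <- simulate_study("SS", pw, pw_cfg, seed = 5)
  expect_identical(s1, s2)
})

test_that("paired patients have mean-zero tumour-normal difference when unshifted", {
  cfg <- simulation_config(n_genes = 300, n_pathways = 5, n_perturbed = 2,
                           effect_size = 0, n_patients = 40,
                           hazard_coefficient = 0, seed = 6)
  pw <- make_pathway_collection(cfg)
  pc <- simulate_patients(pw, cfg, seed = 8, groups = "SLC")
  E <- pc$tumour - pc$normal
  expect_identical(rownames(pc$tumour), rownames(pc$normal))
  expect_lt(abs(mean(E)), 0.05)
  expect_true(all(pc$clinical$days >= 0))
  expect_true(all(pc$clinical$event %in% 0:1))
  expect_true(all(pc$infection$infected %in% 0:1))
})

test_that("cohort fixtures round-trip through the plain-text writers", {
  cfg <- simulation_config(n_genes = 300, n_pathways = 5, n_perturbed = 2,
                           n_studies_per_group = c(SS = 1L, SLC = 1L, CA = 1L),
                           n_case = 4, n_control = 4, n_patients = 6, seed = 9)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  pw2 <- read_gmt(paths$gmt)
  expect_identical(pw2$sets, co$pathways$sets)
  st <- co$studies[[1]]
  st2 <- read_expression(paths$studies[[1]][["matrix"]],
                         paths$studies[[1]][["annotation"]],
                         study_code = st$study_code,
                         disease_group = st$disease_group)
  expect_equal(st2$matrix, st$matrix, tolerance = 1e-9)
  expect_identical(st2$sample_labels, st$sample_labels)
})
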