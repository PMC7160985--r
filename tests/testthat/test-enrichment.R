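test_that("gene t-statistics match the pooled-variance hand calculation", {
  # case {3, 5}, control {1, 1}: mean diff 3, pooled sd 1, se 1, t = 3
  mat <- rbind(gA = c(3, 5, 1, 1), gB = c(2, 2, 2, 2))
  st <- make_tiny_study(mat, n_case = 2)
  ts <- gene_tstats(st)
  expect_equal(ts$t[ts$gene_id == "gA"], 3)
  # constant gene: zero pooled variance -> t = 0 and flagged
  expect_equal(ts$t[ts$gene_id == "gB"], 0)
  expect_true(ts$zero_variance[ts$gene_id == "gB"])
  expect_false(ts$zero_variance[ts$gene_id == "gA"])
})

test_that("t-statistics agree with t.test on random data", {
  set.seed(21)
  mat <- matrix(rnorm(50 * 12), 50, 12,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  st <- make_tiny_study(mat, n_case = 5)
  ts <- gene_tstats(st)
  for (i in c(1, 17, 50))
    expect_equal(ts$t[i], oracle_t(mat[i, 1:5], mat[i, 6:12]),
                 tolerance = 1e-10)
  # identical arms give t = 0 (to machine precision) everywhere
  same <- make_tiny_study(cbind(mat[, 1:5], mat[, 1:5]), n_case = 5)
  expect_true(all(abs(gene_tstats(same)$t) < 1e-10))
  # fewer than 2 samples in an arm is an error
  expect_error(gene_tstats(make_tiny_study(mat[, 1:4], n_case = 1)),
               "at least 2")
})

test_that("the pathway score is sum(t)/sqrt(n)", {
  t4 <- stats::setNames(c(2, 2, 2, 2), paste0("g", 1:4))
  expect_equal(as.numeric(pathway_score(t4, paste0("g", 1:4))), 4)
  expect_equal(as.numeric(pathway_score(t4 * 0, paste0("g", 1:4))), 0)
  set.seed(3)
  tr <- stats::setNames(rnorm(25), paste0("g", 1:25))
  s <- pathway_score(tr, names(tr))
  expect_equal(as.numeric(s), sum(tr) / sqrt(25), tolerance = 1e-14)
  expect_identical(attr(s, "n_genes_used"), 25L)
  # genes absent from the study are dropped from n
  s2 <- pathway_score(tr, c(names(tr)[1:10], "not_measured"))
  expect_identical(attr(s2, "n_genes_used"), 10L)
})

test_that("small studies switch to exhaustive enumeration matching brute force", {
  set.seed(8)
  mat <- matrix(rnorm(30 * 6), 30, 6,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  mat[1:12, 1:3] <- mat[1:12, 1:3] + 1   # some signal
  st <- make_tiny_study(mat, n_case = 3)
  genes <- paste0("g", 1:12)
  res <- permutation_null(st, genes, B = 1000, seed = 4)
  expect_true(res$exhaustive)
  expect_equal(res$p_perm, oracle_exhaustive_p(mat, st$sample_labels, genes),
               tolerance = 1e-12)
  # exhaustive p over C(6,3) = 20 relabelings is a multiple of 1/20
  expect_equal(res$p_perm * 20, round(res$p_perm * 20))
})

test_that("observed score zero yields permutation p of 1", {
  mat <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 15), nrow = 15,
                dimnames = list(paste0("g", 1:15), paste0("s", 1:6)))
  st <- make_tiny_study(mat, n_case = 3)   # case columns identical to control
  res <- permutation_null(st, paste0("g", 1:15), B = 100, seed = 1)
  expect_equal(res$score, 0)
  expect_equal(res$p_perm, 1)
  expect_error(permutation_null(st, paste0("g", 1:15), B = 50), ">= 100")
})

test_that("scores and p-values are invariant to expression rescaling", {
  set.seed(13)
  mat <- matrix(rnorm(40 * 16), 40, 16,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:16)))
  st1 <- make_tiny_study(mat, n_case = 8)
  st2 <- make_tiny_study(mat * 7.3, n_case = 8)
  genes <- paste0("g", 1:20)
  r1 <- permutation_null(st1, genes, B = 300, seed = 6)
  r2 <- permutation_null(st2, genes, B = 300, seed = 6)
  expect_equal(r1$score, r2$score, tolerance = 1e-10)
  expect_equal(r1$p_perm, r2$p_perm)
})

test_that("swapping case/control flips the score sign and preserves p", {
  set.seed(17)
  mat <- matrix(rnorm(30 * 15), 30, 15,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:15)))
  mat[1:10, 1:7] <- mat[1:10, 1:7] + 0.8
  st <- make_tiny_study(mat, n_case = 7)
  swapped <- st
  swapped$sample_labels[] <- ifelse(st$sample_labels == "case",
                                    "control", "case")
  genes <- paste0("g", 1:10)
  r1 <- permutation_null(st, genes, B = 500, seed = 9)
  r2 <- permutation_null(swapped, genes, B = 500, seed = 9)
  expect_equal(r2$score, -r1$score, tolerance = 1e-12)
  expect_identical(r2$p_perm, r1$p_perm)
})

test_that("score_study applies the size filter and shares relabelings", {
  set.seed(31)
  mat <- matrix(rnorm(60 * 12), 60, 12,
                dimnames = list(paste0("g", 1:60), paste0("s", 1:12)))
  st <- make_tiny_study(mat, n_case = 6)
  pw <- pathway_collection(list(big1 = paste0("g", 1:20),
                                big2 = paste0("g", 21:45),
                                tiny = paste0("g", 46:50)))
  cfg <- analysis_config(n_permutations = 200)
  expect_message(res <- score_study(st, pw, cfg, seed = 2), "tiny")
  expect_identical(res$pathway_id, c("big1", "big2"))
  expect_identical(attr(res, "skipped"), "tiny")
  # per-pathway results equal the single-pathway path with the same seed
  single <- permutation_null(st, pw$sets$big1, B = 200, seed = 2)
  expect_equal(res$score[1], single$score, tolerance = 1e-12)
  expect_equal(res$p_perm[1], single$p_perm)
  # all pathways too small -> error
  small <- pathway_collection(list(s1 = paste0("g", 1:5)))
  expect_error(suppressMessages(score_study(st, small, cfg)), "no pathway")
})

test_that("a planted pathway is detected with high power", {
  cfg <- simulation_config(n_genes = 600, n_pathways = 10, n_perturbed = 1,
                           overlap_factor = 0, n_case = 20, n_control = 20,
                           effect_size = 1, seed = 23)
  pw <- make_pathway_collection(cfg)
  ac <- analysis_config(n_permutations = 500)
  set.seed(23)
  hits <- replicate(20, {
    st <- simulate_study("SS", pw, cfg, seed = sample.int(1e6, 1))
    res <- score_study(st, pw, ac, seed = sample.int(1e6, 1))
    top <- res$pathway_id[which.max(res$score)]
    top == "PW001" && res$p_perm[res$pathway_id == "PW001"] < 0.01
  })
  expect_gte(mean(hits), 0.95)
})
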