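# small deterministic score-matrix fixture: 4 pathways x 5 studies
fake_matrix <- function() {
  scores <- matrix(c( 5,  4,  6,  5, -4,
                      3,  3,  3, -3, -3,
                     -2, -2, -2, -2, -2,
                      1,  1,  1,  1,  1),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("P", 1:4),
                                   c("ss1", "ss2", "c1", "c2", "c3")))
  pvals <- matrix(c(0.001, 0.002, 0.001, 0.003, 0.5,
                    0.005, 0.009, 0.004, 0.006, 0.2,
                    0.02,  0.001, 0.3,   0.4,   0.5,
                    0.5,   0.6,   0.7,   0.8,   0.9),
                  nrow = 4, byrow = TRUE, dimnames = dimnames(scores))
  structure(list(scores = scores, pvals = pvals,
                 study_groups = c(ss1 = "SS", ss2 = "SS", c1 = "cancer",
                                  c2 = "cancer", c3 = "cancer")),
            class = "score_matrix")
}

test_that("score-matrix assembly keeps shared pathways and bookkeeping", {
  r1 <- data.frame(pathway_id = c("P1", "P2"), n_genes_used = c(20L, 15L),
                   score = c(1, 2), p_perm = c(0.1, 0.2),
                   direction = c(1, 1), null_mean = 0, null_sd = 1)
  r2 <- r1; r2$score <- c(3, 4)
  r3 <- rbind(r1, data.frame(pathway_id = "P3", n_genes_used = 12L,
                             score = 9, p_perm = 0.01, direction = 1,
                             null_mean = 0, null_sd = 1))
  expect_message(
    mat <- build_score_matrix(list(a = r1, b = r2, c = r3),
                              c(a = "SS", b = "SS", c = "cancer")),
    "dropped 1")
  expect_identical(dim(mat$scores), c(2L, 3L))
  expect_identical(rownames(mat$scores), c("P1", "P2"))
  expect_equal(mat$scores["P1", ], c(a = 1, b = 3, c = 1))
  expect_error(build_score_matrix(list(a = r1), c(a = "SS")), "at least 2")
})

test_that("the robust SS filter requires significance in every SS study", {
  mat <- fake_matrix()
  cfg <- analysis_config()
  # P1, P2 below alpha in both SS studies; P3 fails in ss1 (0.02), P4 fails
  expect_identical(filter_ss_robust(mat, cfg), c("P1", "P2"))
  # boundary: p = 0.009 in all SS studies is retained, p = 0.011 is not
  mat$pvals["P3", c("ss1", "ss2")] <- c(0.009, 0.009)
  expect_true("P3" %in% filter_ss_robust(mat, cfg))
  mat$pvals["P3", "ss2"] <- 0.011
  expect_false("P3" %in% filter_ss_robust(mat, cfg))
})

test_that("clustering segregates cancer studies by the SS-containing clade", {
  mat <- fake_matrix()
  gr <- cluster_studies(mat, pathway_subset = c("P1", "P2"))
  expect_setequal(gr$slc_studies, c("c1", "c2"))
  expect_setequal(gr$ca_studies, "c3")
  expect_identical(gr$linkage, "complete")
  # invariance to study column order
  perm <- c(4, 2, 5, 1, 3)
  mat2 <- mat
  mat2$scores <- mat$scores[, perm]
  mat2$pvals <- mat$pvals[, perm]
  mat2$study_groups <- mat$study_groups[perm]
  gr2 <- cluster_studies(mat2, pathway_subset = c("P1", "P2"))
  expect_setequal(gr2$slc_studies, gr$slc_studies)
  # invariance to pathway row order
  mat3 <- mat
  mat3$scores <- mat$scores[4:1, ]
  mat3$pvals <- mat$pvals[4:1, ]
  gr3 <- cluster_studies(mat3, pathway_subset = c("P1", "P2"))
  expect_setequal(gr3$slc_studies, gr$slc_studies)
})

test_that("identical study columns merge at height zero", {
  mat <- fake_matrix()
  mat$scores[, "c1"] <- mat$scores[, "ss1"]
  gr <- cluster_studies(mat)
  expect_equal(min(gr$dendrogram$height), 0)
  first <- gr$dendrogram$merge[1, ]
  expect_setequal(gr$dendrogram$labels[-first],
                  c("ss1", "c1"))
})

test_that("an even SS split across the 2-cut is an ambiguity error", {
  scores <- matrix(c(10, -10, 10.2, -10.2), nrow = 1,
                   dimnames = list("P1", c("ss1", "ss2", "c1", "c2")))
  mat <- structure(list(scores = scores, pvals = scores * 0 + 0.001,
                        study_groups = c(ss1 = "SS", ss2 = "SS",
                                         c1 = "cancer", c2 = "cancer")),
                   class = "score_matrix")
  expect_error(cluster_studies(mat), "ambiguous")
})

test_that("group filter retains pathways enriched in enough of one group", {
  # 6 SLC studies: significant in 5 (83% >= 80%) -> retained
  pv <- matrix(0.5, nrow = 2, ncol = 8,
               dimnames = list(c("A", "B"),
                               c(paste0("slc", 1:6), paste0("ca", 1:2))))
  pv["A", paste0("slc", 1:5)] <- 0.001
  pv["B", paste0("slc", 1:4)] <- 0.001   # 67% of SLC
  pv["B", "ca1"] <- 0.001                # 50% of CA
  mat <- structure(list(scores = pv * 0 + 1, pvals = pv,
                        study_groups = stats::setNames(rep("cancer", 8),
                                                       colnames(pv))),
                   class = "score_matrix")
  gr <- structure(list(slc_studies = paste0("slc", 1:6),
                       ca_studies = paste0("ca", 1:2)),
                  class = "study_grouping")
  keep <- filter_group_enriched(mat, gr, analysis_config(),
                                ss_robust = c("A", "B"))
  expect_identical(keep, "A")
  # the cascade is monotone: the group-filtered set is inside ss_robust
  keep2 <- filter_group_enriched(mat, gr, analysis_config(), ss_robust = "B")
  expect_length(keep2, 0)
})

test_that("group summaries average scores and count directions", {
  mat <- fake_matrix()
  gr <- structure(list(slc_studies = c("c1", "c2"), ca_studies = "c3"),
                  class = "study_grouping")
  gs <- group_summary(mat, gr, analysis_config())
  expect_equal(gs$group_means["P1", "SS"], mean(c(5, 4)))
  # single-study group mean equals that study's scores
  expect_equal(unname(gs$group_means[, "CA"]), unname(mat$scores[, "c3"]))
  # convexity: group mean between per-study min and max
  for (g in colnames(gs$group_means)) {
    cols <- switch(g, SS = c("ss1", "ss2"), SLC = c("c1", "c2"), CA = "c3")
    expect_true(all(gs$group_means[, g] >=
                      apply(mat$scores[, cols, drop = FALSE], 1, min) - 1e-12))
    expect_true(all(gs$group_means[, g] <=
                      apply(mat$scores[, cols, drop = FALSE], 1, max) + 1e-12))
  }
  # all-negative significant scores in a study count as down, not up
  cnt <- gs$study_counts
  expect_equal(cnt$n_up[cnt$study == "ss1"], 2)   # P1, P2 sig and positive
  expect_equal(cnt$n_down[cnt$study == "ss2"], 1) # P3 sig and negative
})

test_that("LFC, group medians, and the concordance filter follow the rules", {
  mat <- rbind(gA = c(6, 6, 4, 4), gB = c(1, 1, 3, 3))
  st <- make_tiny_study(mat, n_case = 2)
  lfc <- gene_lfc(st)
  expect_equal(lfc$lfc[lfc$gene_id == "gA"], 2)
  expect_equal(lfc$lfc[lfc$gene_id == "gB"], -2)

  slc <- c(gA = 1, gB = -1, gC = 0.5)
  ss <- c(gA = 2, gB = 1, gC = -0.5)
  expect_identical(concordance_filter(slc, ss), "gA")

  # median across studies
  sts <- lapply(c(0, 1, 5), function(d) {
    m <- mat; m["gA", 1:2] <- m["gA", 1:2] + d
    make_tiny_study(m, n_case = 2, code = paste0("s", d))
  })
  med <- median_group_lfc(sts)
  expect_equal(unname(med["gA"]), 3)  # medians of 2, 3, 7
})
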