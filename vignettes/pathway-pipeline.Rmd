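---
title: "Pathway-level comparison of septic shock and cancer transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level comparison of septic shock and cancer transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcpath)
```

## The problem

Septic shock (SS) and some cancers share a transcriptional host-response
signature. Given several case/control whole-blood SS studies and many paired
tumour/normal cancer cohorts, the question is which biological pathways are
robustly dysregulated in SS, which cancers share that dysregulation
("sepsis-like cancer", SLC) and which do not ("cancer alone", CA), and
whether the shared pathway signature carries clinical information (group
membership of an individual patient, survival).

`slcpath` implements that analysis as a reusable pipeline: permutation-based
pathway scoring of each study, a robust multi-study filter cascade,
hierarchical clustering of study-level pathway signatures, a pathway-overlap
network, per-patient pathway scores, cross-validated group classification,
and median-split survival screening. A synthetic-data generator with planted
effects makes every stage testable without access to the original
repositories.

## The pathway score and its permutation null

For one study, each gene `g` gets a pooled-variance two-sample t-statistic
`t_g` (case minus control). A pathway `P` with `n` measured genes is scored
by the weighted average

    S(P) = sum_{g in P} t_g / sqrt(n),

so `S` is approximately standard normal for an uninformative gene set of
independent genes, and positive `S` means up-regulation in cases. Pathways
with 10 or fewer measured genes are discarded (`min_pathway_size = 11`).

Significance is assessed by sample relabeling: case/control labels are
permuted (arm sizes preserved), all gene t-statistics and the pathway score
are recomputed, and the permutation p-value is the raw fraction of simulated
scores at least as extreme as the observed one over `B = 10,000` relabelings
(`n_permutations`; tests and desk-scale runs use `B = 1,000`). Three
conventions are deliberate:

* **Two-sided extremeness on |S|** with the direction reported separately;
  a one-sided mode is available via the `alternative` argument.
* **Raw fraction, no +1 correction**: `p = 0` is possible and is rendered as
  `< 1/B` in text output.
* **Ties count as extreme** (`>=`, within a small relative tolerance), the
  conservative choice.

One matrix of relabelings is drawn per study and shared by all pathways,
which is faster and makes pathway scores comparable against a common null.
When the number of distinct relabelings `choose(n, n_case)` is at most `B`,
all of them are enumerated, so small studies (e.g. 3 vs 3, 20 relabelings)
get exact p-values. Relabelings are generated by permuting the label vector
itself; a useful consequence is that swapping the case and control labels
maps every relabeling to its complement, so the score flips sign and the
p-value is preserved exactly, even in sampled mode.

The t-statistic variant is pooled-variance (equal-variance); an unequal
variance flavour was considered but the pooled form matches the row-wise t
conventionally used by permutation-based set enrichment. Genes with zero
pooled variance get `t = 0` and are flagged; the zero-variance threshold
scales with the gene's own magnitude so that rescaling the expression matrix
leaves every `t`, `S` and `p` unchanged.

## Filter cascade and SLC/CA segregation

1. **Robust SS set**: pathways with `p < alpha_enrich` (default 0.01) in
   *every* SS study.
2. **Clustering**: Euclidean distances between study score columns
   (restricted to the robust SS set), complete-linkage agglomeration
   (`dist()` + `hclust()`), tree cut at `k = 2`. The cancer studies in the
   cluster holding the majority of SS studies become SLC, the rest CA. The
   published analysis identified the SS clade visually; majority-of-SS is
   the deterministic formalization, and an even SS split raises an
   ambiguity error rather than guessing.
3. **Group filter**: of the robust SS set, keep pathways significant in at
   least `group_fraction` (default 0.8) of the SLC studies or of the CA
   studies. The published description mentions significance only, so the
   default is direction-agnostic; `require_direction = TRUE` additionally
   demands a consistent score sign within the qualifying group.

The cascade is monotone by construction (group-filtered set ⊆ robust SS set
⊆ all pathways). Pathways that fail the size filter in any study are dropped
from the score matrix rather than imputed, because scores computed over
different gene subsets are not comparable.

Gene-level summaries follow the same conventions: LFC = mean(case) −
mean(control) per gene, group median across studies, and a concordance
filter keeping genes whose median LFC has the same non-zero sign in SLC
and SS.

## Overlap network

Pathways are nodes; an edge joins two sets sharing at least
`overlap_fraction = 0.05` of their genes. "5% of the total number of genes"
is read as 5% of the *union* of the pair (Jaccard ≥ 0.05); dividing by the
smaller set is available via `denominator = "min"`. Nodes connected to fewer
than `min_network_degree = 3` others are dropped in a single pass (the
description reads as one drop step); `iterate_pruning = TRUE` repeats to a
fixed point. Because the pass is single, a survivor's degree can fall below
the threshold afterwards — that is accepted, not patched. Degree and
betweenness (unweighted, undirected, fractional tie splitting, no pair
normalization) come from igraph and are cross-checked in the tests against
a brute-force shortest-path enumeration.

## Patient scores, classification, survival

For a paired patient, `E = T − N` (tumour minus adjacent normal, log2) and
`Z(P) = sum_{g in P} E_g / sqrt(n_P)` over the selected pathways, with
missing genes dropped per pathway (the divisor uses the genes actually
measured) rather than zero-imputed, keeping `Z` a weighted average of
observations.

Classification of SLC vs CA from the per-patient score vector uses
stratified five-fold cross-validation (per-fold class counts within one
sample of the global proportions), pooling out-of-fold predictions into one
confusion matrix. The SVM uses a radial kernel with cost 1 and kernel width
1/#features (the defaults of the `e1071` implementation family); the neural
net has one hidden layer of 3 nodes with weight decay 0.01, logistic/softmax
outputs, at most 500 iterations and seeded initialization. Features are
standardized using training-fold statistics only, to avoid leakage. Accuracy
is 100 × diagonal/total and misclassification its exact complement; the
print method rounds to two and one decimals respectively.

The survival screen splits patients at the median score per pathway
(ties go to the low group — deterministic and conventional), compares the
high/low Kaplan–Meier curves with the log-rank test, and reports the
fraction of pathways with `p < alpha_survival = 0.1` as an integer
percentage. Scores enter only through the split, so any strictly monotone
transform of a pathway's scores leaves its p-value unchanged. The 2×2
infection-by-group analysis uses the two-sided Fisher exact test (exact at
these counts; chi-square by flag) and reports the sample odds ratio ad/bc.

## What the synthetic generator emulates

`simulation_config()` defines the study conditions; its defaults are fixed
and are what the test suite and the acceptance script measure under:

* 100 gene sets of 15–40 genes over a 2,000-gene universe, consecutive sets
  sharing 50% of the smaller size. Chained sharing propagates genes along
  the collection and yields the dense, hub-heavy overlap structure typical
  of curated pathway collections (the published KEGG network averaged >40
  neighbours per node).
* The first 20 pathways are perturbed: every member gene's mean is shifted
  by `effect_size = 1.0` log2 units (upward in SS and SLC, downward in CA),
  against per-gene noise with `noise_sd = 1.0`. A gene in several perturbed
  pathways is shifted once — no stacking — so the per-gene effect stays
  interpretable. The overlap chain restarts at the planted-block boundary so
  planted shifts never leak into nominally null sets and recovery
  sensitivity/false-positive counts are well defined.
* 6 studies per disease group with 20 case and 20 control samples each,
  mirroring the multi-study design (6 SS cohorts; tens of samples per arm).
* Baseline expression is Gaussian on the log2 scale: every downstream
  statistic consumes log-scale matrices, so count-level realism adds nothing
  the pipeline would see.
* 100 paired patients per cancer group: `N` is baseline noise,
  `T = N + shift + noise`. Survival is exponential with log-hazard
  `hazard_coefficient = 1.5` per SD of the designated pathway score,
  baseline median 1,000 days, administratively censored at 5× that horizon
  (no censoring model was published; an administrative cutoff is the
  simplest defensible choice). Infection labels are Bernoulli at 7.5% (SLC)
  vs 0.66% (CA), the published integration rates.

What it does **not** emulate: batch effects, probe-level microarray
artefacts, FPKM/count noise, gene–gene correlation beyond the planted
shifts, non-proportional hazards, and real pathway biology. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under its stated assumptions — not that the published pathway
lists (the 90/66 sets, the 244-node network, the 537/542 validation
accuracy) would be reproduced; those depend on the original TCGA/GEO/KEGG
snapshots and are documented as worked examples only.

## Numerical choices and degenerate inputs

* Permutation p tie tolerance: `1e-8 * (1 + |S_obs|)` relative band, so
  genuine ties (identity and complement relabelings) count as extreme under
  floating-point arithmetic.
* `B < 100` is rejected outright (unstable null).
* Studies need ≥ 2 samples per arm for t-statistics; simulation requires
  ≥ 1 per arm and errors on `n_case = 0`.
* Duplicate gene rows at load keep the highest-mean row — the original
  probe-collapse rule was not published; highest-mean is a common,
  deterministic convention.
* All-identical scores cannot be median-split; the pathway is skipped and
  logged, and enters the screened denominator as NA.
* Empty post-pruning networks, empty gene-universe intersections, and
  degenerate 2×2 margins are errors with diagnostics, never silent results.

## Problem sizes used by the tests

The shipped suite runs the recovery study at 25 replicate cohorts
(6+6+6 studies, B = 1,000), the calibration study at 6 effect-free studies
× 200 pathways (1,200 p-values), classifier checks at n = 200 with 10 of 66
informative features, and survival power/level at 200 replicate cohorts of
100 patients. The acceptance script repeats the same measurements at
reduced replicate counts. These sizes were chosen as the smallest that keep
Monte-Carlo error well inside the asserted bands.

## Limitations

* The per-sample score used for classification is the paired-patient `Z`;
  the published validation instead formed per-sample scores from group-level
  t-statistics on independent GEO sets, a construction the text does not
  fully specify. Unpaired-sample scoring is therefore out of scope.
* The screen thresholds raw permutation p-values (no FDR), as published.
* Clustering assumes the two-cluster cut is meaningful; with weak signal the
  SLC/CA assignment degrades gracefully into the ambiguity error rather
  than a confident wrong answer.
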