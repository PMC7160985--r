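# Independent brute-force oracles used to cross-check the implementation.

# Pooled-variance two-sample t for one gene, via t.test (independent of the
# package's vectorized formula).
oracle_t <- function(case, ctrl) {
  unname(stats::t.test(case, ctrl, var.equal = TRUE)$statistic)
}

# Exhaustive permutation p-value for a pathway score: enumerates every
# case-set of the observed size, recomputes gene t-statistics with t.test,
# and counts |S_sim| >= |S_obs|.
oracle_exhaustive_p <- function(X, labels, genes) {
  n1 <- sum(labels == "case")
  n <- length(labels)
  score_for <- function(case_idx) {
    ts <- apply(X[genes, , drop = FALSE], 1, function(row)
      oracle_t(row[case_idx], row[-case_idx]))
    sum(ts) / sqrt(length(genes))
  }
  s_obs <- score_for(which(labels == "case"))
  sims <- apply(utils::combn(n, n1), 2, score_for)
  mean(abs(sims) >= abs(s_obs) - 1e-10)
}

# Shortest-path counts via adjacency-matrix powers: the number of walks of
# length d(s,t) between s and t equals the number of shortest paths.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  pow <- diag(n)
  counts <- vector("list", n + 1)
  counts[[1]] <- pow
  for (L in seq_len(n)) {
    pow <- pow %*% adj
    counts[[L + 1]] <- pow
    D[D == Inf & pow > 0] <- L
  }
  npaths <- function(s, t) {
    if (s == t) return(1)
    if (!is.finite(D[s, t])) return(0)
    counts[[D[s, t] + 1]][s, t]
  }
  bw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        tot <- tot + npaths(s, v) * npaths(v, t) / npaths(s, t)
    }
    bw[v] <- tot
  }
  bw
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small deterministic two-arm study built from explicit values.
make_tiny_study <- function(mat, n_case, code = "tiny", group = "SS") {
  labels <- c(rep("case", n_case), rep("control", ncol(mat) - n_case))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  expression_study(code, group, mat, labels)
}

# Wrap an arbitrary undirected igraph as an overlap_network for centrality
# checks on synthetic graphs.
wrap_graph <- function(g) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g)
  structure(list(graph = g, nodes = igraph::V(g)$name,
                 edges = data.frame(from = el[, 1], to = el[, 2]),
                 selected = character()),
            class = "overlap_network")
}

# Collection whose overlap graph (at Jaccard >= 0.05) is a path A - B - C.
path_collection <- function() {
  pathway_collection(list(
    A = paste0("g", 1:20),
    B = paste0("g", 11:30),
    C = paste0("g", 21:40)))
}
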