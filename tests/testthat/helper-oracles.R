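# Independent oracles and small constructors shared across tests.

# study with explicit values: genes x samples matrix built from a list
make_study <- function(rows, design) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- names(design)
  expression_study(m, design)
}

make_ppi <- function(...) {
  pairs <- list(...)
  ppi_graph(data.frame(a = vapply(pairs, `[`, "", 1L),
                       b = vapply(pairs, `[`, "", 2L)))
}

# brute-force local clustering coefficient via dense adjacency triple loop
oracle_cc <- function(edges_df, nodes) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges_df))) {
    A[edges_df$gene_a[i], edges_df$gene_b[i]] <- TRUE
    A[edges_df$gene_b[i], edges_df$gene_a[i]] <- TRUE
  }
  sapply(nodes, function(v) {
    nbrs <- which(A[v, ])
    k <- length(nbrs)
    if (k < 2) return(0)
    e <- 0
    for (a in seq_along(nbrs)) for (b in seq_len(a - 1))
      if (A[nbrs[a], nbrs[b]]) e <- e + 1
    2 * e / (k * (k - 1))
  })
}

# random simple graph as a state_network-like edge frame
random_graph <- function(n_nodes, p_edge) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- combn(nodes, 2)
  keep <- runif(ncol(pairs)) < p_edge
  data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
             stringsAsFactors = FALSE)
}

as_network <- function(edges_df, state = "S", id = 1L) {
  structure(list(state = state, id = id,
                 edges = data.frame(gene_a = edges_df$gene_a,
                                    gene_b = edges_df$gene_b,
                                    r = rep(1, nrow(edges_df)),
                                    p = rep(0, nrow(edges_df)),
                                    stringsAsFactors = FALSE),
                 genes = sort(unique(c(edges_df$gene_a, edges_df$gene_b)))),
            class = "state_network")
}

# exhaustive hypergeometric upper tail: enumerate all C(N, n) draws
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- combn(N, n)
  in_set <- seq_len(K)  # first K universe elements form the set
  mean(apply(draws, 2, function(d) sum(d %in% in_set) >= k))
}

# Monte-Carlo permutation p for a Pearson correlation
oracle_perm_p <- function(a, b, n_perm = 10000L) {
  robs <- abs(cor(a, b))
  hits <- 0L
  for (i in seq_len(n_perm))
    if (abs(cor(a, sample(b))) >= robs - 1e-12) hits <- hits + 1L
  (1 + hits) / (1 + n_perm)
}

# trend_records from explicit per-state (D, C) vectors, genes as names
make_records <- function(genes, sequence, D, C) {
  stats_list <- lapply(seq_along(sequence), function(i)
    data.frame(gene = genes, state = sequence[i],
               D = D[, i], C = C[, i], presence_fraction = 1,
               stringsAsFactors = FALSE))
  names(stats_list) <- sequence
  trend_records(stats_list, sequence)
}
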