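test_that("pearson_p handles identity, zero correlation, and contracts", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(pearson_p(a, a)$r, 1)
  expect_lt(pearson_p(a, a)$p, 1e-12)
  x <- rep(c(1, -1), 4)
  y <- rep(c(1, 1, -1, -1), 2)  # sample r exactly 0
  expect_equal(pearson_p(x, y)$r, 0)
  expect_equal(pearson_p(x, y)$p, 1)
  expect_error(pearson_p(1:2, 2:1), "n >= 3")
  expect_error(pearson_p(rep(1, 5), 1:5), "zero-variance")
})

test_that("t-based p matches a 10,000-permutation oracle at n = 8", {
  set.seed(31)
  a <- rnorm(8)
  b <- 0.8 * scale(a)[, 1] + sqrt(1 - 0.64) * rnorm(8)
  pt_based <- pearson_p(a, b)$p
  set.seed(99)
  p_oracle <- oracle_perm_p(a, b, 10000L)
  expect_lt(abs(pt_based - p_oracle), 0.01)
  # the package's own permutation mode agrees with the oracle too
  p_perm <- pearson_p(a, b, method = "permutation", n_perm = 10000L,
                      seed = 7)$p
  expect_lt(abs(p_perm - p_oracle), 0.01)
})

test_that("network edges need both correlation and PPI support", {
  design <- c(S1 = "X", S2 = "X", S3 = "X", S4 = "X")
  prof <- c(1, 2, 3, 4)
  st <- make_study(list(A = prof, B = prof + 0.001 * c(1, -1, 1, -1),
                        C = c(4, 1, 3, 2)), design)
  with_ppi <- build_network(st, make_ppi(c("A", "B")), ggin_config(p0 = 0.01))
  expect_equal(nrow(with_ppi$edges), 1L)
  without <- build_network(st, make_ppi(c("A", "C")), ggin_config(p0 = 0.01))
  expect_false(any(without$edges$gene_a == "A" & without$edges$gene_b == "B"))
  expect_error(build_network(subset_samples(st, c("S1", "S2")),
                             make_ppi(c("A", "B"))), "3 arrays")
})

test_that("build_network equals a brute-force all-pairs filter on a toy study", {
  set.seed(17)
  design <- setNames(rep("X", 8), sprintf("S%d", 1:8))
  rows <- setNames(lapply(1:5, function(i) rnorm(8)), LETTERS[1:5])
  rows$B <- rows$A + rnorm(8, sd = 0.1)     # strongly correlated pair
  rows$D <- -rows$C + rnorm(8, sd = 0.1)
  st <- make_study(rows, design)
  ppi <- make_ppi(c("A", "B"), c("A", "C"), c("C", "D"), c("D", "E"))
  net <- build_network(st, ppi, ggin_config(p0 = 0.05))
  # oracle: exhaustive scan of PPI pairs with cor.test
  keep <- apply(ppi$edges, 1, function(e)
    cor.test(st$values[e[1], ], st$values[e[2], ])$p.value <= 0.05)
  oracle <- ppi$edges[keep, ]
  expect_equal(nrow(net$edges), nrow(oracle))
  expect_setequal(paste(net$edges$gene_a, net$edges$gene_b),
                  paste(oracle$a, oracle$b))
})

test_that("ensemble size follows the state's sample count", {
  fx <- make_fixture("tiny")
  cfg <- ggin_config(n_subsamples = 10L, seed = 3L)
  expect_length(subsample_ensemble(fx$study, "Nor", fx$ppi, cfg), 1L)
  ens <- subsample_ensemble(fx$study, "Ade", fx$ppi, cfg)
  expect_length(ens, 10L)
  ens2 <- subsample_ensemble(fx$study, "Ade", fx$ppi, cfg)
  expect_identical(lapply(ens, `[[`, "edges"), lapply(ens2, `[[`, "edges"))
  expect_error(subsample_ensemble(fx$study, "XXX", fx$ppi, cfg), "absent")
})

test_that("clustering coefficient: triangle, star, and 100-graph oracle", {
  tri <- as_network(data.frame(gene_a = c("A", "B", "A"),
                               gene_b = c("B", "C", "C")))
  expect_equal(clustering_coefficient(tri, "A"), 1)
  star <- as_network(data.frame(gene_a = rep("HUB", 4),
                                gene_b = c("A", "B", "C", "D")))
  expect_equal(clustering_coefficient(star, "HUB"), 0)
  expect_error(clustering_coefficient(star, "Z"), "not in network")

  set.seed(23)
  for (i in 1:100) {
    ed <- random_graph(30, 0.15)
    if (!nrow(ed)) next
    net <- as_network(ed)
    expect_equal(clustering_coefficient(net),
                 oracle_cc(ed, net$genes)[net$genes],
                 tolerance = 1e-12)
  }
})

test_that("network summary metrics are internally consistent", {
  ed <- data.frame(gene_a = c("A", "B", "A", "C", "D"),
                   gene_b = c("B", "C", "C", "D", "E"))
  s <- summarize_network(as_network(ed))
  expect_equal(s$n_nodes, 5L)
  expect_equal(s$n_edges, 5L)
  expect_equal(s$mean_degree, 2 * 5 / 5)
  expect_equal(s$giant_component_size, 5L)
  expect_equal(s$mean_clustering, mean(oracle_cc(ed, c("A", "B", "C", "D", "E"))))
  expect_error(summarize_network(as_network(ed[0, ])), "empty")
})

test_that("power-law fit recovers an exact synthetic histogram slope", {
  k <- 1:20
  count <- 1000 * k^(-2)  # exact log-log line of slope -2
  expect_equal(power_law_fit(k, count), -2, tolerance = 1e-10)
})

test_that("gene stats aggregate over the ensemble as stated", {
  nets <- list(
    as_network(data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"))),
    as_network(data.frame(gene_a = c("A", "A", "A", "A"),
                          gene_b = c("B", "C", "D", "E"))),
    as_network(data.frame(gene_a = "B", gene_b = "C")))
  st <- aggregate_gene_stats(nets, c("A", "B", "C", "D", "E", "Z"))
  expect_equal(st$D[st$gene == "A"], mean(c(2, 4, 0)))
  expect_equal(st$D[st$gene == "Z"], 0)
  expect_equal(st$C[st$gene == "Z"], 0)
  expect_equal(st$presence_fraction[st$gene == "Z"], 0)
  one <- aggregate_gene_stats(nets[1], c("A", "B", "C"))
  expect_equal(one$D, c(2, 1, 1))
})

test_that("degree/clustering profile excludes degree-1 genes and normalizes", {
  tri <- as_network(data.frame(gene_a = c("A", "B", "A"),
                               gene_b = c("B", "C", "C")))
  prof <- degree_cc_profile(list(tri))
  expect_equal(sum(prof$pct), 100)
  expect_equal(prof$degree[prof$pct == 100], 2L)
  expect_match(as.character(prof$c_range[prof$pct == 100]), "1")

  # degree-2 genes have C in {0, 1}: path graph center has C = 0
  path <- as_network(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")))
  expect_equal(clustering_coefficient(path, "B"), 0)

  per <- degree_cc_profile(list(tri, path), per_network = TRUE)
  sums <- tapply(per$pct, per$network, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("edge sets are monotone in p0 and always PPI-supported", {
  fx <- make_fixture("tiny")
  smp <- state_samples(fx$study, "CRC")
  sub <- subset_samples(fx$study, smp[1:8])
  keys <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  e001 <- keys(build_network(sub, fx$ppi, ggin_config(p0 = 0.001)))
  e01 <- keys(build_network(sub, fx$ppi, ggin_config(p0 = 0.01)))
  e05 <- keys(build_network(sub, fx$ppi, ggin_config(p0 = 0.05)))
  expect_true(all(e001 %in% e01))
  expect_true(all(e01 %in% e05))
  ppi_keys <- paste(fx$ppi$edges$a, fx$ppi$edges$b)
  expect_true(all(e05 %in% ppi_keys))
})
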