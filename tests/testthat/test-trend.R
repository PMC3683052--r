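seq3 <- c("Nor", "Ade", "CRC")

test_that("the ToP predicate reproduces the documented selection patterns", {
  D <- rbind(CDK2 = c(1, 22, 48),   # grows into the final state
             MYC = c(1, 0, 21),     # dips below Nor at the intermediate
             PEAK = c(10, 20, 15),  # final not maximal
             WEAK = c(1, 2, 4))     # never a hub (all D <= 4)
  C <- rbind(CDK2 = c(0, 0.05, 0.05),
             MYC = c(0, 0, 0.03),
             PEAK = c(0, 0.1, 0.2),
             WEAK = c(0, 0.5, 0.5))
  rec <- make_records(rownames(D), seq3, D, C)
  res <- top_select(rec, top_config())
  expect_setequal(res$genes, c("CDK2", "MYC"))
  expect_equal(res$summary$n_selected, 2L)
})

test_that("trend modes and hub options are honoured", {
  D <- rbind(G1 = c(1, 6, 8),   # monotone hub
             G2 = c(1, 0, 8))   # dip at intermediate
  C <- rbind(G1 = c(0, 0.2, 0.3), G2 = c(0, 0, 0.3))
  rec <- make_records(rownames(D), seq3, D, C)
  expect_setequal(top_select(rec, top_config())$genes, c("G1", "G2"))
  expect_equal(top_select(rec, top_config(trend_mode = "monotone"))$genes,
               "G1")
  # C decreasing into the final state is tolerated within c_tolerance
  D3 <- rbind(G3 = c(1, 6, 8)); C3 <- rbind(G3 = c(0, 0.3, 0.28))
  rec3 <- make_records("G3", seq3, D3, C3)
  expect_length(top_select(rec3, top_config())$genes, 0L)
  expect_equal(top_select(rec3, top_config(c_tolerance = 0.05))$genes, "G3")
})

test_that("TPS keeps ToP genes that are DEGs in at least one contrast", {
  D <- rbind(A = c(0, 6, 9), B = c(0, 6, 9), C = c(0, 6, 9))
  Cc <- rbind(A = c(0, 0.2, 0.3), B = c(0, 0.2, 0.3), C = c(0, 0.2, 0.3))
  rec <- make_records(rownames(D), seq3, D, Cc)
  top <- top_select(rec)
  deg_x <- data.frame(gene = c("A", "B", "C"), p = 0.001,
                      p_adj = c(0.01, 0.5, 0.5), fc = c(2.0, 1.1, 1.1))
  deg_f <- data.frame(gene = c("A", "B", "C"), p = 0.001,
                      p_adj = c(0.5, 0.01, 0.5), fc = c(1.1, 1.8, 1.1))
  tps <- tps_select(top, deg_x, deg_f)
  expect_setequal(tps$genes, c("A", "B"))       # C is a DEG in neither
  expect_true(all(tps$genes %in% top$genes))    # TPS is a subset of ToP
  expect_error(tps_select(top, deg_x[1:2, ], deg_f[1:2, ]), "C")
})

test_that("sequence combination reproduces union/partition bookkeeping", {
  # the two-sequence TPS bookkeeping: |A| = 134, |B| = 74, overlap 67
  a <- sprintf("A%03d", 1:134)
  b <- c(a[1:67], sprintf("B%03d", 1:7))
  comb <- combine_sequences(a, b)
  expect_equal(comb$summary$n_union, 141L)
  expect_equal(comb$summary$n_exclusive_a, 67L)
  expect_equal(comb$summary$n_common, 67L)
  expect_equal(comb$summary$n_exclusive_b, 7L)
  # the ToP-level bookkeeping: 389 and 381 with 373 shared
  a <- sprintf("A%03d", 1:389)
  b <- c(a[1:373], sprintf("B%03d", 1:8))
  expect_equal(combine_sequences(a, b)$summary$n_union, 397L)
  # disjoint sets
  comb <- combine_sequences(c("X", "Y"), c("Z", "W"))
  expect_equal(comb$summary$n_common, 0L)
  expect_equal(comb$summary$n_union, 4L)
  # partition always sums to the union
  with(comb$summary,
       expect_equal(n_exclusive_a + n_common + n_exclusive_b, n_union))
})

test_that("hit rate is the catalog share of the selection", {
  catalog <- gene_catalog(sprintf("CG%03d", 1:100))
  sel <- c(sprintf("CG%03d", 1:40), sprintf("XX%03d", 1:34))  # 40 of 74
  hr <- hit_rate(sel, catalog)
  expect_equal(attr(hr, "percent_int"), 54)
  expect_equal(as.numeric(hr), 100 * 40 / 74)
  expect_equal(as.numeric(hit_rate(sprintf("CG%03d", 5:10), catalog)), 100)
  expect_equal(as.numeric(hit_rate(c("NO1", "NO2"), catalog)), 0)
  expect_error(hit_rate(character(0), catalog), "empty")
})

test_that("early-marker screening applies fold, p, and exclusivity rules", {
  genes <- c("PSAT1", "SUPT16H", "SLOW", "LATE", "SHARED")
  D <- rbind(PSAT1 = c(0, 5, 18), SUPT16H = c(1, 5, 8),
             SLOW = c(2, 5, 30), LATE = c(0, 6, 20), SHARED = c(0, 7, 22))
  C <- matrix(0.2, 5, 3, dimnames = list(genes, NULL))
  C[, 1] <- 0
  rec <- make_records(genes, seq3, D, C)
  tps <- structure(list(genes = genes, sequence = seq3), class = "selection_result")
  deg_x <- data.frame(gene = genes,
                      p = c(1e-6, 5.39e-5, 1e-6, 5e-4, 1e-6),
                      p_adj = rep(1e-3, 5), fc = rep(2, 5))
  deg_other <- data.frame(gene = genes, p = rep(0.5, 5),
                          p_adj = c(0.5, 0.5, 0.5, 0.5, 0.01),
                          fc = c(1, 1, 1, 1, 1.9))
  res <- early_markers(tps, rec, deg_x, deg_other)
  # PSAT1: D 0 -> 5 with p < 1e-6 passes; SUPT16H: exactly 5-fold passes;
  # SLOW: 2.5-fold fails; LATE: p = 5e-4 fails; SHARED: tps-DEG elsewhere
  expect_setequal(res$genes, c("PSAT1", "SUPT16H"))
  relaxed <- early_markers(tps, rec, deg_x, deg_other,
                           early_marker_config(deg_p_threshold = 5e-4 + 1e-9))
  expect_true("LATE" %in% relaxed$genes)
  no_excl <- early_markers(tps, rec, deg_x, NULL,
                           early_marker_config(exclusivity = FALSE))
  expect_true("SHARED" %in% no_excl$genes)
  expect_error(early_markers(tps, rec, deg_x, deg_other, state = "CRC"),
               "intermediate")
})
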