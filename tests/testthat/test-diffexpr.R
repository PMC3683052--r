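test_that("identical groups give p = 1 and fc = 1", {
  design <- setNames(rep(c("A", "B"), each = 3), sprintf("S%d", 1:6))
  st <- make_study(list(G1 = c(1, 2, 3, 1, 2, 3), G2 = c(5, 6, 7, 5, 6, 7)),
                   design)
  tab <- two_class_test(st, c("S1", "S2", "S3"), c("S4", "S5", "S6"))
  expect_equal(tab$p, c(1, 1))
  expect_equal(tab$fc, c(1, 1))
  expect_false(any(is_deg(tab, deg_config(), "tps")))
})

test_that("a +1 log2 shift at vanishing noise gives fold change 2", {
  set.seed(1)
  design <- setNames(rep(c("A", "B"), each = 4), sprintf("S%d", 1:8))
  base <- rnorm(4, sd = 1e-6)
  st <- make_study(list(G1 = c(base + 1, base), G2 = c(base, base)), design)
  tab <- two_class_test(st, sprintf("S%d", 1:4), sprintf("S%d", 5:8))
  expect_equal(tab$fc[1], 2, tolerance = 1e-5)
  expect_equal(tab$fc[2], 1, tolerance = 1e-5)
})

test_that("group contracts are enforced", {
  design <- setNames(rep(c("A", "B"), each = 3), sprintf("S%d", 1:6))
  st <- make_study(list(G1 = rnorm(6)), design)
  expect_error(two_class_test(st, c("S1", "S2"), c("S2", "S3")), "overlap")
  expect_error(two_class_test(st, "S1", c("S4", "S5")), ">= 2")
})

test_that("type-I error is calibrated under the null", {
  fracs <- sapply(1:20, function(s) {
    set.seed(100 + s)
    design <- setNames(rep(c("A", "B"), each = 8), sprintf("S%d", 1:16))
    m <- matrix(rnorm(1000 * 16), 1000,
                dimnames = list(sprintf("G%04d", 1:1000), names(design)))
    tab <- two_class_test(expression_study(m, design),
                          sprintf("S%d", 1:8), sprintf("S%d", 9:16))
    mean(tab$p < 0.05)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("pooled permutation p is calibrated under the full null", {
  set.seed(42)
  design <- setNames(rep(c("A", "B"), each = 6), sprintf("S%d", 1:12))
  m <- matrix(rnorm(500 * 12), 500,
              dimnames = list(sprintf("G%03d", 1:500), names(design)))
  tab <- two_class_test(expression_study(m, design),
                        sprintf("S%d", 1:6), sprintf("S%d", 7:12),
                        n_perm = 200L, seed = 9L)
  frac <- mean(tab$perm_p < 0.05)
  mc_sd <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(frac - 0.05), 0.02 + 2 * mc_sd)
})

test_that("fold changes are reciprocal across contrast direction", {
  set.seed(3)
  design <- setNames(rep(c("A", "B"), each = 4), sprintf("S%d", 1:8))
  m <- matrix(rnorm(50 * 8, 8), 50,
              dimnames = list(sprintf("G%02d", 1:50), names(design)))
  st <- expression_study(m, design)
  ab <- two_class_test(st, sprintf("S%d", 1:4), sprintf("S%d", 5:8))
  ba <- two_class_test(st, sprintf("S%d", 5:8), sprintf("S%d", 1:4))
  expect_equal(ab$fc * ba$fc, rep(1, 50))
  expect_equal(ab$p, ba$p)
})

test_that("one-way ANOVA behaves at the null and under separation", {
  set.seed(8)
  design <- setNames(rep(c("A", "B", "C"), each = 6), sprintf("S%d", 1:18))
  m <- matrix(rnorm(2000 * 18), 2000,
              dimnames = list(sprintf("G%04d", 1:2000), names(design)))
  st <- expression_study(m, design)
  tab <- multi_class_anova(st)
  expect_lt(abs(mean(tab$p < 0.05) - 0.05), 0.02)

  m2 <- m
  m2[1:10, design == "C"] <- m2[1:10, design == "C"] + 10
  tab2 <- multi_class_anova(expression_study(m2, design))
  expect_true(all(tab2$p[1:10] < 1e-8))

  expect_error(multi_class_anova(st, c("A", "B")), ">= 3")
})

test_that("the DEG predicate implements both arms and both modes", {
  rec <- data.frame(gene = c("X", "Y", "Z"),
                    p = c(0.01, 0.01, 0.001),
                    p_adj = c(0.04, 0.04, 0.01),
                    fc = c(1.6, 1.2, 0.5))
  expect_equal(is_deg(rec, deg_config(), "tps"), c(TRUE, FALSE, TRUE))
  expect_error(is_deg(rec, deg_config(), "nope"), "unknown mode")
  expect_error(is_deg(rec, deg_config(), "signature"), "perm_fdr")
  rec$perm_fdr <- c(1e-4, 1e-4, 1e-4)
  expect_equal(is_deg(rec, deg_config(), "signature"),
               c(TRUE, FALSE, FALSE))  # signature mode is up-regulation only
})

test_that("BH adjustment matches the closed form and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))  # independent reference
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})
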