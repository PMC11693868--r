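test_that("FPKM follows its defining formula and scale invariance", {
  counts <- matrix(c(100, 0, 50, 10), nrow = 2,
                   dimnames = list(c("t1", "t2"), c("l1", "l2")))
  f <- compute_fpkm(counts, c(t1 = 1000, t2 = 500),
                    c(l1 = 1e6, l2 = 2e6))
  expect_equal(f["t1", "l1"], 100)           # 100 * 1e9 / (1000 * 1e6)
  expect_equal(f["t2", "l1"], 0)
  expect_equal(f["t2", "l2"], 10 * 1e9 / (500 * 2e6))
  # doubling counts and totals leaves FPKM unchanged
  f2 <- compute_fpkm(2 * counts, c(t1 = 1000, t2 = 500),
                     2 * c(l1 = 1e6, l2 = 2e6))
  expect_equal(f2, f)
  expect_error(compute_fpkm(counts, c(1000, 500, 1), c(1e6, 1e6)),
               "shape")
})

test_that("Fisher exact p matches independent enumeration", {
  # fixed table from small/large margins
  expect_equal(fisher_gene_p(30, 1e6, 5, 1e6),
               fisher_enum_oracle(30, 1e6, 5, 1e6), tolerance = 1e-12)
  # reference implementation agreement on random small tables
  set.seed(21)
  for (i in 1:50) {
    x1 <- rpois(1, 20); x2 <- rpois(1, 20)
    t1 <- 5000 + rpois(1, 100); t2 <- 8000 + rpois(1, 100)
    expect_equal(fisher_gene_p(x1, t1, x2, t2),
                 fisher_enum_oracle(x1, t1, x2, t2), tolerance = 1e-12)
    expect_equal(fisher_gene_p(x1, t1, x2, t2),
                 stats::fisher.test(matrix(c(x1, t1 - x1, x2, t2 - x2),
                                           2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("identical libraries yield no calls and zero fold changes", {
  x <- stats::setNames(c(500, 20, 1200), c("g1", "g2", "g3"))
  f <- stats::setNames(c(50, 2, 120), names(x))
  res <- call_differential(x, x, f, f, 1e6, 1e6)
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$flag, rep("ns", 3))
})

test_that("all three criteria are required for a call", {
  genes <- c("big_fc", "low_expr", "flat")
  counts_a <- stats::setNames(c(2000, 8, 1000), genes)
  counts_b <- stats::setNames(c(400, 2, 980), genes)
  fpkm_a <- stats::setNames(c(2.0, 0.08, 10), genes)
  fpkm_b <- stats::setNames(c(0.4, 0.02, 9.8), genes)
  res <- call_differential(counts_a, counts_b, fpkm_a, fpkm_b, 1e6, 1e6)
  # |log2fc| of (2.0 vs 0.4 with pseudocount) passes 1; call rides on p_adj
  r1 <- res[res$gene_id == "big_fc", ]
  expect_gte(abs(r1$log2fc), 1)
  expect_equal(r1$flag, if (r1$p_adj <= 0.001) "up_A" else "ns")
  # below the expression filter: never tested, never called
  expect_false(res$tested[res$gene_id == "low_expr"])
  expect_equal(res$flag[res$gene_id == "low_expr"], "ns")
  # no fold change: ns regardless of p
  expect_equal(res$flag[res$gene_id == "flat"], "ns")
})

test_that("BH adjustment is monotone and restricted to tested genes", {
  sim <- simulate_experiment(simulation_params(n_genes = 80, seed = 13))
  res <- call_deg_dtg(sim$abundance)$transcriptome
  tested <- res[res$tested, ]
  ord <- order(tested$p_raw)
  expect_true(all(diff(tested$p_adj[ord]) >= -1e-12))
  expect_true(all(tested$p_adj >= tested$p_raw - 1e-12))
  expect_true(all(is.na(res$p_adj[!res$tested])))
})

test_that("condition swap flips call directions exactly", {
  sim <- simulate_experiment(simulation_params(n_genes = 60, seed = 17))
  gc <- gene_counts(sim$abundance)
  gf <- gene_fpkm(sim$abundance)
  a <- stats::setNames(gc[, "A_cyto"], rownames(gc))
  b <- stats::setNames(gc[, "B_cyto"], rownames(gc))
  fa <- stats::setNames(gf[, "A_cyto"], rownames(gf))
  fb <- stats::setNames(gf[, "B_cyto"], rownames(gf))
  fwd <- call_differential(a, b, fa, fb, 1e6, 1e6)
  rev <- call_differential(b, a, fb, fa, 1e6, 1e6)
  swap <- c(up_A = "up_B", up_B = "up_A", ns = "ns")
  expect_equal(rev$flag, unname(swap[fwd$flag]))
  expect_equal(rev$log2fc, -fwd$log2fc)
})

test_that("overlap statistics are exact set arithmetic", {
  expect_equal(overlap_calls(c("a", "b"), c("c", "d"))$n_shared, 0)
  same <- overlap_calls(c("a", "b"), c("b", "a"))
  expect_equal(same$frac_of_deg, 1.0)
  expect_equal(same$frac_of_dtg, 1.0)
  # the headline configuration: 2267 and 2252 calls sharing 1769 genes
  deg <- sprintf("g%d", 1:2267)
  dtg <- c(sprintf("g%d", 1:1769), sprintf("x%d", 1:(2252 - 1769)))
  ov <- overlap_calls(deg, dtg)
  expect_equal(ov$n_shared, 1769)
  expect_equal(ov$frac_of_deg, 1769 / 2267)
  expect_equal(round(ov$frac_of_deg, 2), 0.78)
})
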