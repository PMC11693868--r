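test_that("composition proportions respect the expression filter", {
  counts <- rbind(t1 = c(60, 50, 60, 50),
                  t2 = c(40, 50, 40, 50),
                  t3 = c(0.5, 0.5, 0.5, 0.5))
  # lengths chosen so t3 falls below 1 FPKM at depth 1e6
  ab <- make_fixture_abundance(counts,
                               c(t1 = "g1", t2 = "g1", t3 = "g1"),
                               lengths = c(t1 = 1000, t2 = 1000,
                                           t3 = 1000))
  cp <- isoform_proportions(ab, "g1", "A", "cytosolic")
  expect_equal(cp, c(t1 = 0.6, t2 = 0.4))  # t3 dropped, renormalized
  single <- make_fixture_abundance(matrix(c(10, 10, 10, 10), 1,
                                          dimnames = list("t9", NULL)),
                                   c(t9 = "g9"))
  expect_equal(isoform_proportions(single, "g9", "A", "cytosolic"),
               c(t9 = 1.0))
})

test_that("the selective-usage chi-square matches the Pearson oracle", {
  # fixed example, pseudocount 0, no merging
  tab <- rbind(cyto = c(50, 50), ribo = c(90, 10))
  res <- selective_usage_test(c(a = 50, b = 50), c(a = 90, b = 10),
                              min_expected = 0, pseudocount = 0)
  oracle <- pearson_chi2_oracle(tab)
  expect_equal(res$stat, oracle$stat, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$stat, 800 / 70 + 800 / 30, tolerance = 1e-10)
  expect_equal(res$df, 1)
  # proportional rows are perfectly homogeneous
  h <- selective_usage_test(c(a = 30, b = 60, c = 10),
                            c(a = 90, b = 180, c = 30),
                            min_expected = 0, pseudocount = 0)
  expect_equal(h$stat, 0)
  expect_equal(h$p, 1)
})

test_that("low-expected isoforms are merged into an 'other' bin", {
  cyto <- c(a = 100, b = 80, c = 2)
  ribo <- c(a = 90, b = 85, c = 3)
  full <- selective_usage_test(cyto, ribo, min_expected = 0,
                               pseudocount = 0)
  merged <- selective_usage_test(cyto, ribo, min_expected = 5,
                                 pseudocount = 0)
  expect_equal(full$df, 2)
  expect_equal(merged$df, 1)          # df drops by one
  expect_true("c" %in% merged$merged)
  expect_equal(merged$k_used, 2)
  # single-isoform genes are marked not testable
  k1 <- selective_usage_test(c(a = 10), c(a = 20))
  expect_true(is.na(k1$p))
})

test_that("BH selection q-values match a hand adjustment", {
  p <- c(g1 = 0.001, g2 = 0.02, g3 = 0.9)
  adj <- adjust_selection_pvalues(p, alpha = 0.05)
  expect_equal(adj$q_value, c(0.003, 0.03, 0.9))
  expect_equal(adj$selected, c(TRUE, TRUE, FALSE))
  # permuting input order keeps q-values attached to the same genes
  adj2 <- adjust_selection_pvalues(p[c(3, 1, 2)], alpha = 0.05)
  expect_equal(adj2$q_value[match(adj$gene_id, adj2$gene_id)],
               adj$q_value)
})

test_that("Diff_CP is the fraction difference and sums to zero", {
  d <- diff_cp(c(t1 = 0.5, t2 = 0.5), c(t1 = 0.8, t2 = 0.2))
  expect_equal(d, c(t1 = 0.3, t2 = -0.3))
  expect_equal(diff_cp(c(t1 = 0.4, t2 = 0.6), c(t1 = 0.4, t2 = 0.6)),
               c(t1 = 0, t2 = 0))
  # union semantics: isoform absent from one fraction counts as 0
  d2 <- diff_cp(c(t1 = 1), c(t1 = 0.7, t2 = 0.3))
  expect_equal(d2, c(t1 = -0.3, t2 = 0.3))
  set.seed(4)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    a <- stats::setNames(prop.table(runif(k)), paste0("t", 1:k))
    b <- stats::setNames(prop.table(runif(k)), paste0("t", 1:k))
    expect_equal(sum(diff_cp(a, b)), 0, tolerance = 1e-12)
  }
})

test_that("extreme isoforms follow argmax/argmin with documented ties", {
  e <- extreme_isoforms(c(t1 = 0.3, t2 = -0.3))
  expect_equal(e$max_pos_tx, "t1")
  expect_equal(e$max_neg_tx, "t2")
  # tie on Diff_CP broken by higher cytosolic CP
  e2 <- extreme_isoforms(c(t1 = 0.2, t2 = 0.2, t3 = -0.4),
                         cp_cyto = c(t1 = 0.5, t2 = 0.3, t3 = 0.2))
  expect_equal(e2$max_pos_tx, "t1")
  expect_equal(e2$max_neg_tx, "t3")
  # negation swaps the pair
  e3 <- extreme_isoforms(-c(t1 = 0.2, t2 = 0.2, t3 = -0.4),
                         cp_cyto = c(t1 = 0.5, t2 = 0.3, t3 = 0.2))
  expect_equal(e3$max_pos_tx, e2$max_neg_tx)
  expect_equal(e3$max_neg_tx, e2$max_pos_tx)
  expect_true(extreme_isoforms(c(t1 = 0, t2 = 0))$no_selection)
})

test_that("structural comparison reports exactly the differing elements", {
  # two isoforms differing only in the 3'UTR end
  rows <- list(
    list("chr1", "exon", 101L, 500L, "+", "g", "tA"),
    list("chr1", "CDS", 201L, 400L, "+", "g", "tA"),
    list("chr1", "exon", 101L, 700L, "+", "g", "tB"),
    list("chr1", "CDS", 201L, 400L, "+", "g", "tB"),
    # extra 5' exon entirely upstream of the shared CDS
    list("chr1", "exon", 1L, 50L, "+", "g", "tC"),
    list("chr1", "exon", 101L, 500L, "+", "g", "tC"),
    list("chr1", "CDS", 201L, 400L, "+", "g", "tC"),
    # CDS-less transcript
    list("chr1", "exon", 101L, 500L, "+", "g", "tD"))
  catalog <- parse_gtf(write_fixture_gtf(rows))
  expect_equal(compare_structural_elements("tA", "tA", catalog),
               character(0))
  expect_equal(compare_structural_elements("tA", "tB", catalog), "utr3")
  expect_equal(compare_structural_elements("tA", "tC", catalog), "utr5")
  # coding vs non-coding: every element present in either is reported
  expect_setequal(compare_structural_elements("tA", "tD", catalog),
                  c("utr5", "utr3", "cds"))
  rows2 <- list(list("chr1", "exon", 1L, 50L, "+", "g2", "tZ"))
  cat2 <- parse_gtf(write_fixture_gtf(c(rows, rows2)))
  expect_error(compare_structural_elements("tA", "tZ", cat2),
               "different genes")
})

test_that("multi-isoform proportions count filtered expressed isoforms", {
  counts <- rbind(g1.t1 = c(60, 60, 60, 60),
                  g1.t2 = c(40, 0.5, 40, 40),
                  g2.t1 = c(100, 100, 100, 100),
                  g3.t1 = c(30, 30, 30, 30),
                  g3.t2 = c(30, 30, 30, 30))
  ab <- make_fixture_abundance(
    counts, c(g1.t1 = "g1", g1.t2 = "g1", g2.t1 = "g2",
              g3.t1 = "g3", g3.t2 = "g3"))
  cyto <- multi_isoform_stats(ab, "A", "cytosolic")
  ribo <- multi_isoform_stats(ab, "A", "ribosome")
  expect_equal(cyto$proportion, 2 / 3)
  expect_equal(ribo$proportion, 1 / 3)  # g1.t2 below filter in ribosome
  expect_equal(cyto$n_genes_total, 3)
})

test_that("the proportion test matches the Yates chi-square oracle", {
  # hand-computed 2x2 with continuity correction: (40/100 vs 20/100)
  o <- c(40, 60, 20, 80)
  e <- c(30, 70, 30, 70)
  stat <- sum((abs(o - e) - 0.5)^2 / e)
  expect_equal(proportion_test(40, 100, 20, 100),
               stats::pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # symmetry and the identical-proportions case
  expect_equal(proportion_test(40, 100, 20, 100),
               proportion_test(20, 100, 40, 100))
  expect_equal(proportion_test(30, 100, 30, 100), 1)
  expect_error(proportion_test(5, 0, 1, 10), "sample sizes")
})

test_that("dominance needs both an absolute and a relative margin", {
  expect_equal(call_dominant_transcript(c(t1 = 1)), "t1")
  expect_equal(call_dominant_transcript(c(t1 = 0.7, t2 = 0.2, t3 = 0.1)),
               "t1")
  expect_true(is.na(call_dominant_transcript(
    c(t1 = 0.45, t2 = 0.44, t3 = 0.11))))       # fails cp_min
  expect_true(is.na(call_dominant_transcript(
    c(t1 = 0.55, t2 = 0.45))))                  # fails ratio_min
  expect_error(call_dominant_transcript(numeric(0)), "empty")

  expect_equal(detect_dominant_switch("t1", "t1"), "unchanged")
  expect_equal(detect_dominant_switch("t1", "t2"), "switched")
  expect_equal(detect_dominant_switch("t1", NA_character_), "undefined")
})

test_that("planted selection drives calls, sensitive to effect size", {
  run <- function(shift) {
    p <- simulation_params(n_genes = 200, frac_selection_genes = 0.3,
                           selection_cp_shift = shift, frac_de_genes = 0,
                           frac_te_shift_genes = 0,
                           frac_dominant_switch = 0,
                           library_depth = 2e5, seed = 31)
    sim <- simulate_experiment(p)
    iso <- isoform_selection_analysis(sim$abundance, "A",
                                      catalog = sim$catalog)
    truth <- sim$truth$genes
    planted <- truth$gene_id[truth$is_selected]
    called <- iso$genes$gene_id[iso$genes$selected]
    length(intersect(planted, called)) / length(planted)
  }
  expect_gt(run(0.3), 0.8)
  expect_gte(run(0.3), run(0.1))
})

test_that("planted dominant switches are detected from counts", {
  p <- simulation_params(n_genes = 300, frac_dominant_switch = 0.4,
                         frac_selection_genes = 0, frac_de_genes = 0,
                         frac_te_shift_genes = 0, library_depth = 1e6,
                         seed = 37)
  sim <- simulate_experiment(p)
  iso <- isoform_selection_analysis(sim$abundance, "A",
                                    catalog = sim$catalog)
  truth <- sim$truth$genes
  truth_switch <- !is.na(truth$dominant_cyto) &
    !is.na(truth$dominant_ribo) &
    truth$dominant_cyto != truth$dominant_ribo
  g <- merge(iso$genes, data.frame(gene_id = truth$gene_id,
                                   truth_switch = truth_switch))
  sens <- mean(g$dominant_status[g$truth_switch] == "switched")
  bg <- mean(g$dominant_status[!g$truth_switch] == "switched")
  expect_gt(sens, 0.8)
  expect_gt(sens, bg)
})
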