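test_that("simulation is deterministic given the seed", {
  p <- simulation_params(n_genes = 30, seed = 42)
  s1 <- simulate_experiment(p)
  s2 <- simulate_experiment(p)
  expect_identical(s1$abundance$counts, s2$abundance$counts)
  expect_identical(s1$truth$genes, s2$truth$genes)
  expect_identical(s1$catalog$features, s2$catalog$features)
  s3 <- simulate_experiment(simulation_params(n_genes = 30, seed = 43))
  expect_false(identical(s1$abundance$counts, s3$abundance$counts))
})

test_that("parameter validation rejects out-of-domain settings", {
  expect_error(simulation_params(n_genes = 0), "n_genes")
  expect_error(simulation_params(nb_dispersion = 0), "nb_dispersion")
  expect_error(simulation_params(frac_de_genes = 1.2), "frac_de_genes")
  expect_error(simulation_params(selection_cp_shift = 0.7),
               "selection_cp_shift")
})

test_that("isoform-count distribution is honoured", {
  p2 <- simulation_params(n_genes = 50,
                          isoform_count_weights = c(0, 1, 0, 0, 0),
                          seed = 1)
  cat2 <- generate_catalog(p2)
  expect_equal(n_transcripts(cat2) / n_genes(cat2), 2.0)

  p1 <- simulation_params(n_genes = 50,
                          isoform_count_weights = c(1, 0, 0, 0, 0),
                          frac_selection_genes = 1, seed = 1)
  sim1 <- simulate_experiment(p1)
  # no gene eligible for selection or switch effects
  expect_false(any(sim1$truth$genes$is_selected))
  expect_false(any(sim1$truth$genes$is_switch_planted))
})

test_that("the CP planting rule shifts the target and renormalizes", {
  expect_equal(plant_cp_shift(c(0.5, 0.5), 0.3, 1), c(0.8, 0.2))
  expect_equal(plant_cp_shift(c(0.2, 0.3, 0.5), 0.3, 3),
               c(0.2 * 0.2 / 0.5, 0.3 * 0.2 / 0.5, 0.8))
  # capped at 1
  expect_equal(plant_cp_shift(c(0.9, 0.1), 0.3, 1), c(1, 0))
  for (k in 2:5) {
    cp <- plant_cp_shift(rep(1 / k, k), 0.25, k)
    expect_equal(sum(cp), 1)
    expect_true(all(cp >= 0 & cp <= 1))
  }
})

test_that("planted proportions are simplex-valid and recorded in truth", {
  sim <- simulate_experiment(simulation_params(
    n_genes = 120, frac_selection_genes = 0.5, frac_dominant_switch = 0.3,
    seed = 8))
  iso <- sim$truth$isoforms
  sums <- aggregate(cbind(cp_cyto, cp_ribo, planted_cp_shift) ~ gene_id,
                    iso, sum)
  expect_equal(sums$cp_cyto, rep(1, nrow(sums)))
  expect_equal(sums$cp_ribo, rep(1, nrow(sums)))
  expect_equal(sums$planted_cp_shift, rep(0, nrow(sums)))
  expect_true(all(iso$cp_ribo >= 0 & iso$cp_ribo <= 1))
  single <- sim$truth$genes$n_isoforms == 1
  expect_false(any(sim$truth$genes$is_selected[single]))
})

test_that("expected library counts match depth-scaled gene expression", {
  # Monte-Carlo check of E[count] = depth * mu_g / sum(mu) on the
  # condition-A cytosolic library, 200 replicate draws at fixed expression.
  p <- simulation_params(n_genes = 20, frac_de_genes = 0,
                         frac_te_shift_genes = 0, frac_selection_genes = 0,
                         frac_dominant_switch = 0, library_depth = 1e5,
                         seed = 5)
  catalog <- generate_catalog(p)
  acc_obs <- 0
  acc_exp <- 0
  for (r in 1:200) {
    pr <- p
    pr$seed <- 1000 + r
    sim <- simulate_counts(catalog, pr)
    mu <- sim$truth$genes$baseline_expression
    acc_obs <- acc_obs +
      gene_counts(sim$abundance)[sim$truth$genes$gene_id, "A_cyto"]
    acc_exp <- acc_exp + 1e5 * mu / sum(mu)
  }
  rel <- abs(acc_obs - acc_exp) / acc_exp
  # per-gene mean over 200 replicates within 1% where the noise allows
  # (SE < 0.3%); very low-expressed genes are bounded at 5%
  hi <- acc_exp / 200 > 500
  expect_true(all(rel[hi] < 0.01))
  expect_true(all(rel < 0.05))

  one <- simulate_counts(catalog, p)
  gtot <- rowsum(one$truth$isoforms$cp_cyto, one$truth$isoforms$gene_id)
  expect_equal(unname(gtot[, 1]), rep(1, 20))
})

test_that("a null simulation with vanishing dispersion sits at expectation", {
  p <- simulation_params(n_genes = 40, frac_de_genes = 0,
                         frac_te_shift_genes = 0, frac_selection_genes = 0,
                         frac_dominant_switch = 0, nb_dispersion = 1e-9,
                         library_depth = 1e6, seed = 2)
  sim <- simulate_experiment(p)
  de <- call_deg_dtg(sim$abundance)
  expect_lte(sum(de$transcriptome$flag != "ns"), 1)
  expect_lte(sum(de$translatome$flag != "ns"), 1)
  te <- te_analysis(sim$abundance)
  expect_lte(sum(te$calls$flag != "ns"), 1)
})
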