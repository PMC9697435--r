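# Gene-set mixed ANOVA and chi-square enrichment.

test_that("a single-gene set reduces to that gene's paired fit", {
  cfg <- tiny_config(nGeneSets = 1L, setSize = 1L, nFeatures = 10L)
  sim <- simulateExpression(cfg)
  gs <- fitGeneSet(sim$matrix, sim$design, geneSets(sim$sets)$SET01, "SET01")
  gene_fit <- fitPaired(omicsValues(sim$matrix)[1, ], sim$design)
  expect_equal(gs$fold_change, gene_fit$fold_change, tolerance = 1e-12)
  expect_equal(gs$p, gene_fit$p, tolerance = 1e-12)
  expect_equal(gs$ci_low, gene_fit$ci_low, tolerance = 1e-12)
})

test_that("a set of identical genes keeps the common fold change", {
  design <- make_design(6, 6)
  base <- seq(7, 8.1, length.out = 12)
  v <- make_feature(design, base, diff = log2(1.09))
  m <- rbind(g1 = v, g2 = v, g3 = v)[, designSheet(design)$sample_id]
  ann <- data.frame(feature_id = c("g1", "g2", "g3"),
                    gene_symbol = c("A", "B", "C"), region_class = "na")
  om <- OmicsMatrix(m, "expression_log2", annotation = ann)
  gs <- fitGeneSet(om, design, c("A", "B", "C"), "TRIPLET",
                   with_interaction = FALSE)
  expect_equal(gs$fold_change, 1.09, tolerance = 1e-9)
  expect_identical(gs$n_genes, 3L)
})

test_that("gene order within a set does not change the fit", {
  cfg <- tiny_config(seed = 41L)
  sim <- simulateExpression(cfg)
  genes <- geneSets(sim$sets)$SET01
  a <- fitGeneSet(sim$matrix, sim$design, genes, "SET01")
  b <- fitGeneSet(sim$matrix, sim$design, rev(genes), "SET01")
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("probes of one gene are averaged before the gene-level model", {
  cfg <- tiny_config(probesPerGene = 3L, nFeatures = 24L, nGeneSets = 2L,
                     setSize = 4L, seed = 42L)
  sim <- simulateExpression(cfg)
  gs <- fitGeneSet(sim$matrix, sim$design, geneSets(sim$sets)$SET01, "SET01",
                   with_interaction = FALSE)
  expect_identical(gs$n_probes, 12L)
  expect_identical(gs$n_genes, 4L)
  # manual collapse oracle
  ann <- featureAnnotation(sim$matrix)
  keep <- ann$gene_symbol %in% geneSets(sim$sets)$SET01
  per_gene <- rowsum(omicsValues(sim$matrix)[keep, ],
                     ann$gene_symbol[keep]) / 3
  y <- colMeans(per_gene)
  oracle <- fitPaired(y, sim$design)
  expect_equal(gs$p, oracle$p, tolerance = 1e-12)
})

test_that("missing set members are counted, a fully absent set errors", {
  cfg <- tiny_config(seed = 43L)
  sim <- simulateExpression(cfg)
  genes <- c(geneSets(sim$sets)$SET01, "NOTONCHIP1", "NOTONCHIP2")
  gs <- fitGeneSet(sim$matrix, sim$design, genes, "AUGMENTED")
  expect_identical(gs$n_genes_missing, 2L)
  expect_error(fitGeneSet(sim$matrix, sim$design, c("NOPE1", "NOPE2"), "GONE"),
               "NOPE1")
})

test_that("set variance components recover the generating variances", {
  cfg <- simulationConfig(nPersons = c(EOCRC = 60L, LOCRC = 60L),
                          nFeatures = 12L, nGeneSets = 1L, setSize = 12L,
                          sigmaPerson = 1, sigmaError = 0.5, seed = 44L)
  sim <- simulateExpression(cfg)
  gs <- fitGeneSet(sim$matrix, sim$design, geneSets(sim$sets)$SET01, "SET01",
                   with_interaction = FALSE)
  # generator has no extra sample-level effect: person ~ 1, sample ~ 0,
  # residual ~ 0.25
  expect_equal(gs$sigma2_person, 1, tolerance = 0.35)
  expect_lt(gs$sigma2_sample, 0.05)
  expect_equal(gs$sigma2_error, 0.25, tolerance = 0.05)
})

test_that("group fold changes and interaction recover a 1.26 vs 1.16 set contrast", {
  cfg <- simulationConfig(nPersons = c(EOCRC = 80L, LOCRC = 80L),
                          nFeatures = 12L, nGeneSets = 1L, setSize = 12L,
                          sigmaPerson = 1, sigmaError = 0.35,
                          tissueEffectLog2 = log2(1.16),
                          interactionEffectLog2 = log2(1.26 / 1.16),
                          interactionGroup = "LOCRC", seed = 45L)
  sim <- simulateExpression(cfg)
  gs <- fitGeneSet(sim$matrix, sim$design, geneSets(sim$sets)$SET01, "SET01")
  expect_equal(gs$fold_change_locrc, 1.26, tolerance = 0.06)
  expect_equal(gs$fold_change_eocrc, 1.16, tolerance = 0.06)
  # paired group fits are person-controlled, so each group's tumor effect
  # must be individually significant
  expect_lt(gs$p_locrc, 1e-6)
  expect_lt(gs$p_eocrc, 1e-6)
})

test_that("enrichment score matches the 2x2 chi-square oracle", {
  # sig: 10 of 100 in category; chip: 100 of 10000 in category
  chip <- sprintf("G%05d", 1:10000)
  cat_g <- chip[1:100]
  sig <- c(chip[1:10], chip[201:290])
  res <- enrichmentScore(sig, cat_g, chip, "FOCUS")
  # textbook Pearson statistic on {10,90,90,9810}
  tab <- matrix(c(10, 90, 90, 9810), 2, 2, byrow = TRUE)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - exp_tab)^2 / exp_tab)
  expect_equal(res$chi2, chi2, tolerance = 1e-9)
  expect_equal(res$enrichment_score,
               -log10(pchisq(chi2, 1, lower.tail = FALSE)), tolerance = 1e-9)
  expect_identical(c(res$k_sig_in_cat, res$k_sig_total,
                     res$n_chip_in_cat, res$n_chip_total),
                   c(10L, 100L, 100L, 10000L))
})

test_that("enrichment score is 0 at the null and degenerate inputs are flagged", {
  chip <- sprintf("G%03d", 1:100)
  cat_g <- chip[1:20]
  sig <- c(chip[1:2], chip[21:28])     # 2/10 in category = 20/100 on chip
  res <- enrichmentScore(sig, cat_g, chip)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$enrichment_score, 0, tolerance = 1e-12)

  expect_identical(enrichmentScore(character(0), cat_g, chip)$flag,
                   "no_significant_genes")
  expect_identical(enrichmentScore(sig, chip, chip)$flag, "degenerate_margin")
})

test_that("doubling all enrichment counts increases the score", {
  chip <- sprintf("G%05d", 1:2000)
  cat_g <- chip[1:100]
  sig <- c(chip[1:20], chip[101:180])
  r1 <- enrichmentScore(sig, cat_g, chip)
  tab <- matrix(c(r1$k_sig_in_cat, r1$k_sig_total - r1$k_sig_in_cat,
                  r1$n_chip_in_cat - r1$k_sig_in_cat,
                  (r1$n_chip_total - r1$k_sig_total) -
                    (r1$n_chip_in_cat - r1$k_sig_in_cat)), 2, 2)
  r2 <- chiSquareTest(2 * tab)
  expect_equal(r2$chi2, 2 * r1$chi2, tolerance = 1e-9)
  expect_gt(-log10(r2$p), r1$enrichment_score)
})

test_that("enrichment score equals -log10 of the clinical chi-square on the same table", {
  chip <- sprintf("G%04d", 1:500)
  cat_g <- chip[1:60]
  sig <- c(chip[1:25], chip[61:110])
  res <- enrichmentScore(sig, cat_g, chip)
  tab <- matrix(c(25, 50, 35, 390), 2, 2, byrow = TRUE)
  ct <- chiSquareTest(tab)
  expect_equal(res$p, ct$p, tolerance = 1e-12)
  expect_equal(res$enrichment_score, -log10(ct$p), tolerance = 1e-12)
})

test_that("set interaction p is uniform under the null", {
  # single-gene sets make the set-level interaction identical to the
  # feature-level one; 1000 null features stand in for 1000 null sets
  cfg <- simulationConfig(nPersons = c(EOCRC = 12L, LOCRC = 12L),
                          nFeatures = 1000L, nGeneSets = 1L, setSize = 1L,
                          sigmaPerson = 0,     # global null incl. person
                          tissueEffectLog2 = 0, interactionEffectLog2 = 0,
                          seed = 46L)
  sim <- simulateExpression(cfg)
  fi <- fitInteractionMatrix(sim$matrix, sim$design)
  ks <- suppressWarnings(ks.test(fi$interaction_p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and the set route agrees with the feature route on a subsample
  for (i in c(2, 500)) {
    gs <- fitGeneSet(sim$matrix, sim$design,
                     featureAnnotation(sim$matrix)$gene_symbol[i], "solo")
    expect_equal(gs$interaction_p, fi$interaction_p[i], tolerance = 1e-12)
  }
})
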