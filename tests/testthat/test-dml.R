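# BH FDR, DML calling, Venn partition.

test_that("BH q-values match the brute-force step-up oracle", {
  expect_equal(bhFdr(0.04), 0.04)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_identical(bhFdr(numeric(0)), numeric(0))
  set.seed(51)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bhFdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("a strong shared DML is recovered with its delta beta", {
  cfg <- simulationConfig(
    nPersons = c(EOCRC = 20L, LOCRC = 20L), nFeatures = 60L,
    betaBaselineRange = c(0.3, 0.4), betaSigmaPerson = 0.05,
    betaSigmaError = 0.05,
    dmlCounts = c(common = 5L, common_diff = 0L, eocrc_only_ns = 0L,
                  eocrc_specific = 0L, locrc_specific = 0L),
    dmlDelta = {
      m <- rbind(common = c(0.3, 0.3), common_diff = c(0, 0),
                 eocrc_only_ns = c(0, 0), eocrc_specific = c(0, 0),
                 locrc_specific = c(0, 0))
      colnames(m) <- c("EOCRC", "LOCRC"); m
    }, seed = 52L)
  sim <- simulateMethylation(cfg)
  rec <- classifyVenn(callDml(sim$matrix, sim$design, sim$manifest))
  truth <- sim$truth[sim$truth$dml_class == "common", ]
  hit <- rec[match(truth$locus_id, rec$locus_id), ]
  expect_true(all(hit$dml_locrc & hit$dml_eocrc))
  expect_equal(hit$delta_beta_locrc, rep(0.3, 5), tolerance = 0.03)
  expect_equal(hit$delta_beta_eocrc, rep(0.3, 5), tolerance = 0.03)
  expect_true(all(hit$venn_class %in% c("I", "II")))
})

test_that("deep-sea loci are excluded before testing", {
  cfg <- simulationConfig(nPersons = c(EOCRC = 10L, LOCRC = 10L),
                          nFeatures = 600L, seed = 53L)
  sim <- simulateMethylation(cfg)
  rec <- callDml(sim$matrix, sim$design, sim$manifest)
  deep <- sim$manifest$feature_id[sim$manifest$region_class == "deep_sea"]
  expect_gt(length(deep), 0)
  expect_identical(intersect(rec$locus_id, deep), character(0))
  expect_identical(sort(rec$locus_id),
                   sort(setdiff(sim$manifest$feature_id, deep)))
  # a locus absent from the manifest is an error
  expect_error(callDml(sim$matrix, sim$design, sim$manifest[-1, ]),
               "missing from the manifest")
})

test_that("the null dataset yields few DML (FDR control)", {
  cfg <- simulationConfig(
    nPersons = c(EOCRC = 15L, LOCRC = 15L), nFeatures = 1000L,
    dmlCounts = c(common = 0L, common_diff = 0L, eocrc_only_ns = 0L,
                  eocrc_specific = 0L, locrc_specific = 0L), seed = 54L)
  sim <- simulateMethylation(cfg)
  rec <- callDml(sim$matrix, sim$design, sim$manifest)
  # under the global null the expected number of BH discoveries is tiny;
  # allow a generous margin over the 5% bound
  expect_lt(sum(rec$dml_locrc) / nrow(rec), 0.05)
  expect_lt(sum(rec$dml_eocrc) / nrow(rec), 0.05)
})

test_that("Venn classes follow their defining predicates", {
  rec <- data.frame(
    locus_id = paste0("cg", 1:7),
    delta_beta_locrc = 0.1, delta_beta_eocrc = 0.1,
    fdr_locrc = c(0.01, 0.01, 0.9, 0.9, 0.9, 0.01, 0.01),
    fdr_eocrc = c(0.01, 0.01, 0.01, 0.01, 0.9, 0.9, 0.9),
    dml_locrc = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    dml_eocrc = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    interaction_p = c(0.5, 0.01, 0.5, 0.01, 0.5, 0.01, 0.5))
  out <- classifyVenn(rec)
  expect_identical(out$venn_class,
                   c("I", "II", "III", "IV", "not_dml", "V", "locrc_only_ns"))
  # with alpha -> 0, classes II, IV and V empty
  out0 <- classifyVenn(rec, interaction_alpha = 1e-300)
  expect_identical(sum(out0$venn_class %in% c("II", "IV", "V")), 0L)
  # relabeling the onset groups swaps the class-III/V axis symmetrically
  sw <- rec
  sw[c("dml_locrc", "dml_eocrc")] <- rec[c("dml_eocrc", "dml_locrc")]
  out_sw <- classifyVenn(sw)
  expect_identical(sum(out_sw$venn_class == "V"),
                   sum(out$venn_class == "IV"))
  expect_identical(sum(out_sw$venn_class == "III"),
                   sum(out$venn_class == "locrc_only_ns"))
  expect_identical(sum(out_sw$venn_class %in% c("I", "II")),
                   sum(out$venn_class %in% c("I", "II")))
})

test_that("the partition is exhaustive and its arithmetic closes", {
  cfg <- simulationConfig(nPersons = c(EOCRC = 25L, LOCRC = 25L),
                          nFeatures = 600L, seed = 55L)
  sim <- simulateMethylation(cfg)
  rec <- classifyVenn(callDml(sim$matrix, sim$design, sim$manifest))
  summ <- summarizePartition(rec)
  counts <- setNames(summ$by_class$n, summ$by_class$venn_class)
  # every locus in exactly one class
  expect_identical(sum(counts), nrow(rec))
  # |I| + |II| = common DML; |III| + |IV| = EOCRC-only DML
  expect_identical(unname(counts["I"] + counts["II"]), summ$n_common)
  expect_identical(unname(counts["III"] + counts["IV"]), summ$n_eocrc_only)
  expect_identical(unname(counts["V"] + counts["locrc_only_ns"]),
                   summ$n_locrc_only)
  expect_identical(summ$n_common + summ$n_eocrc_only, summ$n_dml_eocrc)
  expect_identical(summ$n_common + summ$n_locrc_only, summ$n_dml_locrc)
  # re-evaluating the predicate from stored fields reproduces the class
  re <- classifyVenn(rec[, setdiff(names(rec), "venn_class")])
  expect_identical(re$venn_class, rec$venn_class)
})

test_that("delta-beta magnitude bins count classified loci correctly", {
  rec <- data.frame(
    locus_id = paste0("cg", 1:4),
    delta_beta_locrc = c(0.25, 0.12, 0.05, 0.0),
    delta_beta_eocrc = c(0.22, 0.15, 0.04, 0.0),
    fdr_locrc = c(0.01, 0.01, 0.9, 0.9), fdr_eocrc = c(0.01, 0.01, 0.9, 0.9),
    dml_locrc = c(TRUE, TRUE, FALSE, FALSE),
    dml_eocrc = c(TRUE, TRUE, FALSE, FALSE),
    interaction_p = 0.5)
  summ <- summarizePartition(classifyVenn(rec))
  cls1 <- summ$by_class[summ$by_class$venn_class == "I", ]
  expect_identical(cls1$n, 2L)
  expect_identical(cls1$n_delta_ge_0.1, 2L)
  expect_identical(cls1$n_delta_ge_0.2, 1L)
  # empty class IV still yields a well-formed export
  expect_identical(nrow(summ$class_iv_export), 0L)
  expect_true(all(c("locus_id", "delta_beta_eocrc") %in%
                    names(summ$class_iv_export)))
})

test_that("EOCRC-specific loci land in class IV with small delta beta", {
  cfg <- simulationConfig(
    nPersons = c(EOCRC = 40L, LOCRC = 40L), nFeatures = 300L,
    betaSigmaPerson = 0.08, betaSigmaError = 0.08,
    dmlCounts = c(common = 0L, common_diff = 0L, eocrc_only_ns = 0L,
                  eocrc_specific = 25L, locrc_specific = 0L), seed = 56L)
  sim <- simulateMethylation(cfg)
  rec <- classifyVenn(callDml(sim$matrix, sim$design, sim$manifest))
  truth <- sim$truth[sim$truth$dml_class == "eocrc_specific", ]
  hit <- rec[match(truth$locus_id, rec$locus_id), ]
  # the designated delta (0.08) stays below the 0.1 robustness bin
  expect_true(all(abs(hit$delta_beta_eocrc) < 0.15))
  expect_gt(mean(hit$venn_class == "IV"), 0.5)
})
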