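# Paired mixed ANOVA, interaction model, variance components, fold change.

test_that("paired ANOVA p equals the paired t-test p and F = t^2", {
  set.seed(21)
  design <- make_design(8, 9)
  cp <- completePairs(design)
  for (i in 1:10) {
    v <- make_feature(design, baseline = rnorm(17, 8, 1),
                      diff = rnorm(17, 0.3, 0.6))
    fit <- fitPaired(v, design)
    tt <- t.test(v[cp$tumor], v[cp$normal], paired = TRUE)
    expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
    expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(fit$effect, unname(tt$estimate), tolerance = 1e-12)
  }
})

test_that("constant differences give the effect with a degenerate-residual flag", {
  design <- make_design(2, 1)
  v <- make_feature(design, baseline = c(5, 6, 7), diff = 1)
  fit <- fitPaired(v, design)
  expect_equal(fit$effect, 1)
  expect_identical(fit$flag, "degenerate_zero_residual")
  expect_equal(fit$sigma2_error, 0)
  expect_gt(fit$p, 0)          # boundary value, still in (0, 1]
})

test_that("too few pairs is flagged inestimable, not an error", {
  design <- PairedDesign(data.frame(
    sample_id = c("aT", "aN", "bT"), person_id = c("a", "a", "b"),
    tissue = c("tumor", "normal", "tumor"), onset_group = "EOCRC"))
  v <- c(aT = 5, aN = 4, bT = 6)
  fit <- fitPaired(v, design)
  expect_identical(fit$flag, "too_few_pairs")
  expect_true(is.na(fit$p))
})

test_that("method-of-moments components solve the EMS system", {
  # balanced paired design: person = (MS_person - MS_error)/2 exactly
  vc <- momVarianceComponents(c(person = 3.1, error = 0.9),
                              emsPairedBalanced())
  expect_equal(unname(vc$components), c((3.1 - 0.9) / 2, 0.9))
  # negative solutions are clamped and flagged
  vc2 <- momVarianceComponents(c(person = 0.5, error = 0.9),
                               emsPairedBalanced())
  expect_equal(vc2$components[["sigma2_person"]], 0)
  expect_true(vc2$negative_clamped[["sigma2_person"]])
  expect_equal(vc2$raw[["sigma2_person"]], -0.2)
  # singular system names the confounded terms
  ems <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(momVarianceComponents(c(a = 1, b = 2), ems), "confounded")
})

test_that("variance components recover simulation truth at n = 200 pairs", {
  # features inside one simulation share person draws, so independent
  # replicate simulations provide the simulation SE
  fits <- do.call(rbind, lapply(1:40, function(i) {
    cfg <- simulationConfig(nPersons = c(EOCRC = 100L, LOCRC = 100L),
                            nFeatures = 1L, nGeneSets = 1L, setSize = 1L,
                            sigmaPerson = 1, sigmaError = 0.5,
                            seed = 3100L + i)
    sim <- simulateExpression(cfg)
    fitPaired(omicsValues(sim$matrix)[1, ], sim$design)
  }))
  expect_lt(abs(mean(fits$sigma2_person) - 1),
            3 * sd(fits$sigma2_person) / sqrt(40))
  expect_lt(abs(mean(fits$sigma2_error) - 0.25),
            3 * sd(fits$sigma2_error) / sqrt(40))
})

test_that("sigma_person = 0 clamps the person component in about half of replicates", {
  cfg <- simulationConfig(nPersons = c(EOCRC = 30L, LOCRC = 30L),
                          nFeatures = 200L, nGeneSets = 1L, setSize = 1L,
                          sigmaPerson = 0, sigmaError = 0.5, seed = 32L)
  sim <- simulateExpression(cfg)
  v <- omicsValues(sim$matrix)
  fits <- do.call(rbind, lapply(seq_len(200), function(i)
    fitPaired(v[i, ], sim$design)))
  expect_equal(mean(fits$person_clamped), 0.5, tolerance = 0.15)
  expect_lt(mean(fits$sigma2_person), 0.05)
})

test_that("signed fold change follows the -1/x convention with ordered CI", {
  expect_equal(foldChangeFromLog2(0, 0.1, 10)$fold_change, 1)
  expect_equal(foldChangeFromLog2(log2(1.46), 0.01, 70)$fold_change, 1.46)
  expect_equal(foldChangeFromLog2(-log2(1.12), 0.01, 70)$fold_change, -1.12)
  # antisymmetry and CI ordering over a grid
  for (e in c(0.01, 0.2, 1, 3)) {
    up <- foldChangeFromLog2(e, 0.05, 20)
    dn <- foldChangeFromLog2(-e, 0.05, 20)
    expect_equal(dn$fold_change, -up$fold_change, tolerance = 1e-12)
    expect_lt(up$ci_low, up$fold_change); expect_gt(up$ci_high, up$fold_change)
  }
  # df <= 0: CI missing, point estimate kept
  z <- foldChangeFromLog2(1, 0.1, 0)
  expect_true(is.na(z$ci_low) && !is.na(z$fold_change))
})

test_that("|fold change| grows and p shrinks with |effect| at fixed se", {
  design <- make_design(6, 6)
  effs <- c(0.1, 0.3, 0.6, 1.2)
  fc <- abs(vapply(effs, function(e)
    foldChangeFromLog2(e, 0.1, 11)$fold_change, numeric(1)))
  expect_true(all(diff(fc) > 0))
  set.seed(33)
  base <- rnorm(12, 8); noise <- rnorm(12, 0, 0.4)
  ps <- vapply(effs, function(e) {
    v <- make_feature(design, base, e + noise)
    fitPaired(v, design)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("interaction model matches the lm/ANOVA oracle and is label-symmetric", {
  set.seed(34)
  design <- make_design(7, 10)
  sh <- designSheet(design)
  for (i in 1:5) {
    v <- make_feature(design, baseline = rnorm(17, 8),
                      diff = rnorm(17, 0.4, 0.5))
    fit <- fitInteraction(v, design)
    lmfit <- lm(v[sh$sample_id] ~ tissue * onset_group, data = sh)
    expect_equal(fit$interaction_p,
                 anova(lmfit)["tissue:onset_group", "Pr(>F)"],
                 tolerance = 1e-10)
    # swapping the group labels leaves interaction_p unchanged
    sw <- sh
    sw$onset_group <- ifelse(sh$onset_group == "EOCRC", "LOCRC", "EOCRC")
    fit_sw <- fitInteraction(v, PairedDesign(sw))
    expect_equal(fit_sw$interaction_p, fit$interaction_p, tolerance = 1e-12)
    expect_equal(fit_sw$interaction_effect, -fit$interaction_effect,
                 tolerance = 1e-12)
  }
  # a missing stratum is an error naming it
  solo <- PairedDesign(sh[sh$onset_group == "EOCRC", ])
  v <- make_feature(design, rnorm(17, 8), 0.5)
  expect_error(fitInteraction(v, solo), "LOCRC")
})

test_that("vectorised fitters agree with their scalar counterparts", {
  set.seed(35)
  cfg <- tiny_config()
  sim <- simulateExpression(cfg)
  m <- omicsValues(sim$matrix)
  fp <- fitPairedMatrix(sim$matrix, sim$design, fold_change = TRUE)
  fi <- fitInteractionMatrix(sim$matrix, sim$design)
  for (i in c(1, 7, 20)) {
    s <- fitPaired(m[i, ], sim$design)
    expect_equal(fp$p[i], s$p, tolerance = 1e-12)
    expect_equal(fp$effect[i], s$effect, tolerance = 1e-12)
    expect_equal(fp$fold_change[i], s$fold_change, tolerance = 1e-12)
    si <- fitInteraction(m[i, ], sim$design)
    expect_equal(fi$interaction_p[i], si$interaction_p, tolerance = 1e-12)
  }
  # pairs with a missing value are excluded per feature
  m2 <- m; m2[1, completePairs(sim$design)$tumor[1]] <- NA
  fp2 <- fitPairedMatrix(m2, sim$design)
  expect_identical(fp2$n_pairs[1], 19)
  expect_identical(fp2$n_pairs[2], 20)
})

test_that("recovered group fold changes mirror a 1.14 vs 1.09 contrast", {
  # the interaction model carries no person term, so person variance sits
  # in its error; a powered fixture keeps both SDs small
  cfg <- simulationConfig(nPersons = c(EOCRC = 150L, LOCRC = 150L),
                          nFeatures = 1L, nGeneSets = 1L, setSize = 1L,
                          sigmaPerson = 0.05, sigmaError = 0.1,
                          tissueEffectLog2 = log2(1.09),
                          interactionEffectLog2 = log2(1.14 / 1.09),
                          interactionGroup = "LOCRC", seed = 36L)
  sim <- simulateExpression(cfg)
  fit <- fitInteraction(omicsValues(sim$matrix)[1, ], sim$design)
  expect_lt(fit$interaction_p, 0.05)
  expect_equal(fit$fold_change_locrc, 1.14, tolerance = 0.05)
  expect_equal(fit$fold_change_eocrc, 1.09, tolerance = 0.05)
})
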