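# In-code fixtures shared across the suite.

# balanced paired design: n_e EOCRC + n_l LOCRC persons, tumor+normal each
make_design <- function(n_e = 3, n_l = 3) {
  ids <- c(sprintf("E%02d", seq_len(n_e)), sprintf("L%02d", seq_len(n_l)))
  onset <- rep(c("EOCRC", "LOCRC"), c(n_e, n_l))
  PairedDesign(data.frame(
    sample_id = c(paste0(ids, "_T"), paste0(ids, "_N")),
    person_id = rep(ids, 2),
    tissue = rep(c("tumor", "normal"), each = length(ids)),
    onset_group = rep(onset, 2), stringsAsFactors = FALSE))
}

# one feature: named value vector over the samples of a design, built from
# per-person baselines plus a tumor-normal difference per person
make_feature <- function(design, baseline, diff) {
  cp <- completePairs(design)
  v <- numeric(0)
  v[cp$normal] <- baseline
  v[cp$tumor] <- baseline + diff
  v
}

# tiny all-signal config for fast simulations; DML counts scaled to fit
tiny_config <- function(..., nPersons = c(EOCRC = 10L, LOCRC = 10L),
                        nFeatures = 20L, nGeneSets = 2L, setSize = 4L,
                        dmlCounts = c(common = 2L, common_diff = 1L,
                                      eocrc_only_ns = 1L,
                                      eocrc_specific = 1L,
                                      locrc_specific = 1L),
                        seed = 11L) {
  simulationConfig(nPersons = nPersons, nFeatures = nFeatures,
                   nGeneSets = nGeneSets, setSize = setSize,
                   dmlCounts = dmlCounts, seed = seed, ...)
}

expect_one_row <- function(df) expect_identical(nrow(df), 1L)

# independent brute-force step-up oracle: for the i-th smallest p, q =
# min over j >= i of p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (pos in seq_len(m)) {
    cand <- vapply(pos:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[pos]] <- min(1, min(cand))
  }
  q
}
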