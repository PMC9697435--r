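# Synthetic paired tumor-normal data with the statistical structure the
# downstream models assume: additive log2 expression with a random person
# intercept, gene-set-structured tissue and tissue x onset effects,
# bounded beta values generated on the logit scale, and clinical tables
# with group-specific category distributions (probability or exact-counts
# mode). One pseudo-random stream per run, seeded explicitly; sub-streams
# are derived from stable named keys so adding one generator never
# perturbs another.

DML_CLASSES <- c("common", "common_diff", "eocrc_only_ns",
                 "eocrc_specific", "locrc_specific")

#' Simulation configuration
#'
#' Defaults state the emulated study design: 67 EOCRC and 98 LOCRC
#' persons, person SD 1.0 and residual SD 0.5 (log2 units), a tumor
#' effect of log2(1.09) on designated gene sets with an extra
#' log2(1.14/1.09) in LOCRC only (so the two group fold changes are 1.09
#' and 1.14), CpG region classes in the 450K manifest proportions, and
#' clinical category proportions from the study's clinical table. See the
#' methods vignette for the rationale behind each default.
#'
#' @slot nPersons named integer, persons per onset group
#' @slot nFeatures total number of probes (expression) or loci (methylation)
#' @slot nGeneSets,setSize,probesPerGene gene-set structure of the
#'   expression features
#' @slot mu grand mean, log2 units
#' @slot sigmaPerson,sigmaError person and residual SDs, log2 units
#' @slot tissueEffectLog2 mean log2 tumor-normal difference on set members
#' @slot interactionEffectLog2 additional tissue effect applied to
#'   \code{interactionGroup} only, on sets listed in \code{interactionSets}
#' @slot interactionGroup \code{"LOCRC"} or \code{"EOCRC"}
#' @slot interactionSets integer indices of the sets carrying the interaction
#' @slot betaBaselineRange interval in [0,1] for baseline beta values
#' @slot betaSigmaPerson,betaSigmaError logit-scale SDs for methylation
#' @slot dmlCounts named integer, loci per designated DML class
#' @slot dmlDelta 5 x 2 matrix of per-class delta beta (rows =
#'   \code{common}, \code{common_diff}, \code{eocrc_only_ns},
#'   \code{eocrc_specific}, \code{locrc_specific}; columns = EOCRC, LOCRC)
#' @slot regionProportions island/shore/shelf/deep_sea probabilities
#' @slot clinicalProportions list: covariate -> categories x group
#'   probability matrix
#' @slot dropNormalFraction fraction of normal samples dropped to emulate
#'   assay failures (unbalanced designs)
#' @slot seed integer seed of the run's random stream
#' @export
setClass("SimulationConfig", representation(
  nPersons = "integer", nFeatures = "integer", nGeneSets = "integer",
  setSize = "integer", probesPerGene = "integer", mu = "numeric",
  sigmaPerson = "numeric", sigmaError = "numeric",
  tissueEffectLog2 = "numeric", interactionEffectLog2 = "numeric",
  interactionGroup = "character", interactionSets = "integer",
  betaBaselineRange = "numeric", betaSigmaPerson = "numeric",
  betaSigmaError = "numeric", dmlCounts = "integer", dmlDelta = "matrix",
  regionProportions = "numeric", clinicalProportions = "list",
  dropNormalFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (!identical(sort(names(object@nPersons)), sort(ONSET_LEVELS)))
    return("nPersons must be named with EOCRC and LOCRC")
  if (any(object@nPersons < 1)) return("each onset group needs >= 1 person")
  if (object@sigmaPerson < 0 || object@sigmaError < 0 ||
      object@betaSigmaPerson < 0 || object@betaSigmaError < 0)
    return("standard deviations must be >= 0")
  if (length(object@betaBaselineRange) != 2 ||
      object@betaBaselineRange[1] > object@betaBaselineRange[2] ||
      object@betaBaselineRange[1] < 0 || object@betaBaselineRange[2] > 1)
    return("betaBaselineRange must be an ordered interval inside [0,1]")
  if (!identical(rownames(object@dmlDelta), DML_CLASSES) ||
      !identical(colnames(object@dmlDelta), ONSET_LEVELS))
    return("dmlDelta must have DML classes as rows, EOCRC/LOCRC as columns")
  if (!identical(sort(names(object@dmlCounts)), sort(DML_CLASSES)))
    return("dmlCounts must be named with all five DML classes")
  lo <- min(object@betaBaselineRange) + min(0, min(object@dmlDelta))
  hi <- max(object@betaBaselineRange) + max(0, max(object@dmlDelta))
  if (lo < 0 || hi > 1)
    return(sprintf("expected beta outside [0,1]: baseline range plus delta spans [%.3f, %.3f]", lo, hi))
  if (!object@interactionGroup %in% ONSET_LEVELS)
    return("interactionGroup must be EOCRC or LOCRC")
  if (abs(sum(object@regionProportions) - 1) > 1e-8)
    return("regionProportions must sum to 1")
  for (cv in names(object@clinicalProportions)) {
    pm <- object@clinicalProportions[[cv]]
    if (!all(ONSET_LEVELS %in% colnames(pm)))
      return(sprintf("clinicalProportions[['%s']] needs EOCRC and LOCRC columns", cv))
    if (any(pm < 0) || any(abs(colSums(pm[, ONSET_LEVELS]) - 1) > 1e-8))
      return(sprintf("clinicalProportions[['%s']] columns must be probabilities summing to 1", cv))
  }
  if (object@dropNormalFraction < 0 || object@dropNormalFraction >= 1)
    return("dropNormalFraction must be in [0, 1)")
  TRUE
})

# Table-1 style clinical category proportions per onset group
default_clinical_proportions <- function() {
  prop <- function(eo, lo) {
    m <- cbind(EOCRC = eo / sum(eo), LOCRC = lo / sum(lo))
    m
  }
  list(
    stage = { m <- prop(c(7, 16, 44), c(30, 26, 42)); rownames(m) <- c("1", "2", "3"); m },
    lvi   = { m <- prop(c(36, 31), c(71, 27)); rownames(m) <- c("absent", "present"); m },
    pni   = { m <- prop(c(53, 14), c(90, 8));  rownames(m) <- c("absent", "present"); m },
    msi   = { m <- prop(c(15, 52), c(26, 72)); rownames(m) <- c("MSI", "MSS"); m },
    sex   = { m <- prop(c(39, 28), c(57, 41)); rownames(m) <- c("male", "female"); m },
    grade = { m <- prop(c(27, 40), c(51, 47)); rownames(m) <- c("low", "high"); m }
  )
}

default_dml_delta <- function() {
  m <- rbind(common          = c(0.20, 0.20),
             common_diff     = c(0.12, 0.25),
             eocrc_only_ns   = c(0.06, 0.04),
             eocrc_specific  = c(0.08, 0.00),
             locrc_specific  = c(0.00, 0.20))
  colnames(m) <- ONSET_LEVELS
  m
}

#' Build a validated SimulationConfig
#'
#' All arguments default to the stated world of the emulated study; see
#' \linkS4class{SimulationConfig} and the methods vignette.
#'
#' @param nPersons persons per onset group, named \code{c(EOCRC=, LOCRC=)}
#' @param nFeatures number of probes/loci
#' @param nGeneSets,setSize,probesPerGene gene-set structure
#' @param mu grand mean (log2)
#' @param sigmaPerson,sigmaError person and residual SD (log2)
#' @param tissueEffectLog2 set-member tumor effect (log2)
#' @param interactionEffectLog2 extra tumor effect in
#'   \code{interactionGroup}
#' @param interactionGroup onset group carrying the interaction
#' @param interactionSets indices of sets carrying it (default: first half)
#' @param betaBaselineRange baseline beta interval
#' @param betaSigmaPerson,betaSigmaError logit-scale SDs
#' @param dmlCounts loci per designated DML class (named)
#' @param dmlDelta 5 x 2 per-class delta-beta matrix
#' @param regionProportions island/shore/shelf/deep_sea probabilities
#' @param clinicalProportions covariate -> categories x group matrix
#' @param dropNormalFraction fraction of normal samples to drop
#' @param seed integer seed
#' @return a \linkS4class{SimulationConfig}
#' @export
simulationConfig <- function(
    nPersons = c(EOCRC = 67L, LOCRC = 98L),
    nFeatures = 1000L, nGeneSets = 4L, setSize = 12L, probesPerGene = 1L,
    mu = 8, sigmaPerson = 1.0, sigmaError = 0.5,
    tissueEffectLog2 = log2(1.09),
    interactionEffectLog2 = log2(1.14) - log2(1.09),
    interactionGroup = "LOCRC", interactionSets = NULL,
    betaBaselineRange = c(0.2, 0.75),
    betaSigmaPerson = 0.5, betaSigmaError = 0.3,
    dmlCounts = c(common = 80L, common_diff = 20L, eocrc_only_ns = 20L,
                  eocrc_specific = 15L, locrc_specific = 20L),
    dmlDelta = default_dml_delta(),
    regionProportions = c(island = 150254, shore = 112067, shelf = 47114,
                          deep_sea = 176112) / (150254 + 112067 + 47114 + 176112),
    clinicalProportions = default_clinical_proportions(),
    dropNormalFraction = 0, seed = 1L) {
  if (is.null(interactionSets))
    interactionSets <- seq_len(max(1L, floor(nGeneSets / 2)))
  np <- as.integer(nPersons); names(np) <- names(nPersons)
  dc <- as.integer(dmlCounts); names(dc) <- names(dmlCounts)
  new("SimulationConfig",
      nPersons = np, nFeatures = as.integer(nFeatures),
      nGeneSets = as.integer(nGeneSets), setSize = as.integer(setSize),
      probesPerGene = as.integer(probesPerGene), mu = mu,
      sigmaPerson = sigmaPerson, sigmaError = sigmaError,
      tissueEffectLog2 = tissueEffectLog2,
      interactionEffectLog2 = interactionEffectLog2,
      interactionGroup = interactionGroup,
      interactionSets = as.integer(interactionSets),
      betaBaselineRange = betaBaselineRange,
      betaSigmaPerson = betaSigmaPerson, betaSigmaError = betaSigmaError,
      dmlCounts = dc, dmlDelta = dmlDelta,
      regionProportions = regionProportions,
      clinicalProportions = clinicalProportions,
      dropNormalFraction = dropNormalFraction, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      sprintf("%d EOCRC + %d LOCRC persons, %d features, seed %d\n",
              object@nPersons[["EOCRC"]], object@nPersons[["LOCRC"]],
              object@nFeatures, object@seed))
})

# deterministic sub-stream seed from a stable named key
local_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 1009 + sum(utf8ToInt(key)) * 131) %% 2147483647)
}

# person ids and the balanced paired sheet (one tumor + one normal each)
base_design <- function(config) {
  ids <- c(sprintf("E%03d", seq_len(config@nPersons[["EOCRC"]])),
           sprintf("L%03d", seq_len(config@nPersons[["LOCRC"]])))
  onset <- rep(ONSET_LEVELS, config@nPersons[ONSET_LEVELS])
  data.frame(
    sample_id = c(paste0(ids, "_T"), paste0(ids, "_N")),
    person_id = rep(ids, 2),
    tissue = rep(TISSUE_LEVELS, each = length(ids)),
    onset_group = rep(onset, 2), stringsAsFactors = FALSE)
}

drop_normals <- function(sheet, frac) {
  if (frac <= 0) return(sheet)
  normals <- which(sheet$tissue == "normal")
  k <- floor(frac * length(normals))
  if (k > 0) sheet <- sheet[-sample(normals, k), , drop = FALSE]
  sheet
}

#' Simulate a paired expression dataset
#'
#' Sampling counterpart of the paired model: value = mu + tissue effect
#' (+ interaction effect if the person's onset group carries it) + person
#' effect ~ N(0, sigmaPerson^2) + error ~ N(0, sigmaError^2). The first
#' \code{nGeneSets x setSize} genes are organised into gene sets carrying
#' the tissue effect (sets in \code{interactionSets} also carry the
#' interaction); remaining genes are null. Deterministic under a fixed
#' seed.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return list: \code{matrix} (an \linkS4class{OmicsMatrix} of kind
#'   \code{expression_log2} with gene_symbol rowData), \code{design}
#'   (a \linkS4class{PairedDesign}), \code{truth} (per-probe true
#'   effects and set membership), \code{sets} (a
#'   \linkS4class{GeneSetLibrary})
#' @export
simulateExpression <- function(config) {
  validObject(config)
  set.seed(local_seed(config@seed, "expression"))
  sheet <- drop_normals(base_design(config), config@dropNormalFraction)

  n_genes <- config@nFeatures %/% config@probesPerGene
  n_member <- config@nGeneSets * config@setSize
  if (n_genes < n_member)
    stop("nFeatures too small for the requested gene-set structure")
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  set_of_gene <- rep(NA_integer_, n_genes)
  set_of_gene[seq_len(n_member)] <- rep(seq_len(config@nGeneSets),
                                        each = config@setSize)
  sets <- lapply(split(genes[seq_len(n_member)],
                       set_of_gene[seq_len(n_member)]), identity)
  names(sets) <- sprintf("SET%02d", seq_len(config@nGeneSets))

  probes <- sprintf("PROBE%06d", seq_len(n_genes * config@probesPerGene))
  gene_of_probe <- rep(genes, each = config@probesPerGene)
  set_of_probe <- rep(set_of_gene, each = config@probesPerGene)

  t_eff <- ifelse(is.na(set_of_probe), 0, config@tissueEffectLog2)
  i_eff <- ifelse(!is.na(set_of_probe) &
                    set_of_probe %in% config@interactionSets,
                  config@interactionEffectLog2, 0)

  persons <- unique(sheet$person_id)
  p_eff <- stats::rnorm(length(persons), 0, config@sigmaPerson)
  names(p_eff) <- persons

  is_tum <- sheet$tissue == "tumor"
  in_grp <- sheet$onset_group == config@interactionGroup
  nf <- length(probes); ns <- nrow(sheet)
  m <- config@mu +
    outer(t_eff, as.numeric(is_tum)) +
    outer(i_eff, as.numeric(is_tum & in_grp)) +
    matrix(rep(p_eff[sheet$person_id], each = nf), nf, ns) +
    matrix(stats::rnorm(nf * ns, 0, config@sigmaError), nf, ns)
  dimnames(m) <- list(probes, sheet$sample_id)

  ann <- data.frame(feature_id = probes, gene_symbol = gene_of_probe,
                    region_class = "na", stringsAsFactors = FALSE)
  truth <- data.frame(
    feature_id = probes, gene_symbol = gene_of_probe,
    set_name = ifelse(is.na(set_of_probe), "",
                      sprintf("SET%02d", set_of_probe)),
    true_tissue_effect = t_eff, true_interaction_effect = i_eff,
    interaction_group = ifelse(i_eff != 0, config@interactionGroup, ""),
    stringsAsFactors = FALSE)

  list(matrix = OmicsMatrix(m, "expression_log2", annotation = ann),
       design = PairedDesign(sheet), truth = truth,
       sets = GeneSetLibrary(sets))
}

#' Simulate a paired methylation (beta value) dataset
#'
#' Per locus: a baseline beta drawn uniformly from
#' \code{betaBaselineRange}; designated DML add the class- and
#' group-specific delta beta to the tumor expectation. Person effects and
#' noise are added on the logit scale and mapped back through the inverse
#' logit, clipped to [0.001, 0.999], so values stay in (0, 1) without
#' truncation pile-up at the bounds. Region classes follow
#' \code{regionProportions}; deep-sea loci are never designated DML
#' (downstream analysis excludes them).
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return list: \code{matrix} (kind \code{methylation_beta} with
#'   region_class rowData), \code{design}, \code{truth} (per-locus class
#'   and per-group true delta beta), \code{manifest} (annotation
#'   data.frame)
#' @export
simulateMethylation <- function(config) {
  validObject(config)
  set.seed(local_seed(config@seed, "methylation"))
  sheet <- drop_normals(base_design(config), config@dropNormalFraction)

  nl <- config@nFeatures
  loci <- sprintf("cg%06d", seq_len(nl))
  region <- sample(names(config@regionProportions), nl, replace = TRUE,
                   prob = config@regionProportions)
  eligible <- which(region != "deep_sea")
  need <- sum(config@dmlCounts)
  if (length(eligible) < need)
    stop("too few non-deep-sea loci for the requested DML counts")
  chosen <- sample(eligible, need)
  dml_class <- rep("", nl)
  dml_class[chosen] <- rep(DML_CLASSES, config@dmlCounts[DML_CLASSES])

  delta <- matrix(0, nl, 2, dimnames = list(loci, ONSET_LEVELS))
  des <- dml_class != ""
  delta[des, ] <- config@dmlDelta[dml_class[des], , drop = FALSE]

  baseline <- stats::runif(nl, config@betaBaselineRange[1],
                           config@betaBaselineRange[2])
  persons <- unique(sheet$person_id)
  p_eff <- stats::rnorm(length(persons), 0, config@betaSigmaPerson)
  names(p_eff) <- persons

  is_tum <- sheet$tissue == "tumor"
  ns <- nrow(sheet)
  expected <- matrix(baseline, nl, ns) +
    delta[, "EOCRC"] %o% as.numeric(is_tum & sheet$onset_group == "EOCRC") +
    delta[, "LOCRC"] %o% as.numeric(is_tum & sheet$onset_group == "LOCRC")
  if (any(expected < 0 | expected > 1))
    stop("config produces expected beta outside [0,1]")
  logit <- stats::qlogis(pmin(pmax(expected, 1e-6), 1 - 1e-6))
  logit <- logit + matrix(rep(p_eff[sheet$person_id], each = nl), nl, ns) +
    matrix(stats::rnorm(nl * ns, 0, config@betaSigmaError), nl, ns)
  beta <- pmin(pmax(stats::plogis(logit), 0.001), 0.999)
  dimnames(beta) <- list(loci, sheet$sample_id)

  manifest <- data.frame(feature_id = loci, gene_symbol = "",
                         region_class = region, stringsAsFactors = FALSE)
  truth <- data.frame(locus_id = loci, region_class = region,
                      dml_class = dml_class,
                      true_delta_eocrc = delta[, "EOCRC"],
                      true_delta_locrc = delta[, "LOCRC"],
                      stringsAsFactors = FALSE)
  list(matrix = OmicsMatrix(beta, "methylation_beta", annotation = manifest),
       design = PairedDesign(sheet), truth = truth, manifest = manifest)
}

#' Simulate a clinical sample sheet
#'
#' Person-level clinical covariates drawn from the group-specific category
#' distributions of \code{clinicalProportions} (probability mode), or
#' assigned to reproduce requested per-group counts exactly
#' (\code{exact_counts} mode). Deterministic under a fixed seed.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param exact_counts optional list: covariate -> categories x group
#'   count matrix (columns EOCRC/LOCRC, each summing to that group's
#'   person count); those covariates are assigned exactly, the rest drawn
#'   from the probabilities
#' @return a \linkS4class{PairedDesign} whose sheet carries the covariates
#' @export
simulateClinical <- function(config, exact_counts = NULL) {
  validObject(config)
  set.seed(local_seed(config@seed, "clinical"))
  sheet <- base_design(config)
  pp <- sheet[!duplicated(sheet$person_id),
              c("person_id", "onset_group"), drop = FALSE]
  covs <- names(config@clinicalProportions)
  vals <- list()
  for (cv in union(covs, names(exact_counts))) {
    v <- rep(NA_character_, nrow(pp))
    for (g in ONSET_LEVELS) {
      idx <- which(pp$onset_group == g)
      if (!is.null(exact_counts) && cv %in% names(exact_counts)) {
        cm <- exact_counts[[cv]]
        if (sum(cm[, g]) != length(idx))
          stop(sprintf("exact counts for '%s' in %s sum to %d, not %d persons",
                       cv, g, sum(cm[, g]), length(idx)))
        v[idx] <- rep(rownames(cm), cm[, g])
      } else {
        pm <- config@clinicalProportions[[cv]]
        v[idx] <- sample(rownames(pm), length(idx), replace = TRUE,
                         prob = pm[, g])
      }
    }
    vals[[cv]] <- v
  }
  for (cv in names(vals))
    sheet[[cv]] <- vals[[cv]][match(sheet$person_id, pp$person_id)]
  PairedDesign(sheet)
}
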