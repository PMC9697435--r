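# End-to-end orchestration: simulate (or load) -> preprocess ->
# per-feature paired ANOVA -> gene-set ANOVA + enrichment -> DML calling
# and Venn partition -> clinical associations. Every stage writes a TSV;
# a JSON manifest records each output with a content hash so a rerun
# under the same seed is verifiably identical.

#' Default pipeline run configuration
#'
#' @param out_dir output directory (created if absent)
#' @param seed integer seed forwarded to the simulators
#' @param fdr_alpha FDR threshold for DML and significant-gene calling
#' @param interaction_alpha threshold on the tissue x onset interaction p
#' @param stages character subset of
#'   \code{c("expression", "methylation", "clinical")}
#' @param sim a \linkS4class{SimulationConfig}; default
#'   \code{simulationConfig(seed = seed)}
#' @return named list understood by [runPipeline()]
#' @export
pipelineConfig <- function(out_dir, seed = 1L, fdr_alpha = 0.05,
                           interaction_alpha = 0.05,
                           stages = c("expression", "methylation", "clinical"),
                           sim = NULL) {
  if (fdr_alpha <= 0 || fdr_alpha >= 1 ||
      interaction_alpha <= 0 || interaction_alpha >= 1)
    stop("thresholds must lie in (0, 1)")
  bad <- setdiff(stages, c("expression", "methylation", "clinical"))
  if (length(bad)) stop(sprintf("unknown stage '%s'", bad[1]))
  list(out_dir = out_dir, seed = as.integer(seed), fdr_alpha = fdr_alpha,
       interaction_alpha = interaction_alpha, stages = stages,
       sim = if (is.null(sim)) simulationConfig(seed = seed) else sim)
}

#' Read a pipeline configuration from JSON
#'
#' Scalar fields of [pipelineConfig()] (\code{out_dir}, \code{seed},
#' \code{fdr_alpha}, \code{interaction_alpha}, \code{stages}) may be
#' given; unknown keys are a validation error before any compute.
#'
#' @param path path to a JSON file
#' @return named list understood by [runPipeline()]
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("out_dir", "seed", "fdr_alpha", "interaction_alpha", "stages")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown configuration key '%s'", bad[1]))
  if (is.null(cfg$out_dir)) stop("configuration requires out_dir")
  do.call(pipelineConfig, cfg)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the toggled stages in order and writes every result table
#' under \code{config$out_dir}:
#' \itemize{
#'   \item expression: simulated matrix -> quantile normalization ->
#'     per-probe paired ANOVA (\code{expression_fits.tsv}) -> gene-set
#'     mixed ANOVA with interaction (\code{geneset_fits.tsv}) ->
#'     chi-square enrichment of FDR-significant genes per set
#'     (\code{enrichment.tsv})
#'   \item methylation: simulated beta matrix -> DML calling, Venn
#'     classification (\code{dml.tsv}) and partition summary
#'     (\code{dml_summary.tsv}, \code{class_iv_loci.tsv})
#'   \item clinical: simulated sheet -> covariate x onset chi-square
#'     screen (\code{clinical.tsv}) and stage-stratified LVI/PNI tests
#'     (\code{clinical_stratified.tsv})
#' }
#' A \code{manifest.json} maps every artifact to its md5 content hash;
#' \code{pipeline.log} gets one line per stage (name, input shape,
#' elapsed). Identical seeds give identical hashes.
#'
#' @param config list from [pipelineConfig()] or [readPipelineConfig()]
#' @return invisibly, the manifest as a named list of md5 hashes
#' @export
runPipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "pipeline.log")
  if (file.exists(logfile)) file.remove(logfile)
  outputs <- character(0)
  timed <- function(stage, shape, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    stage_log(logfile, stage, shape, proc.time()[["elapsed"]] - t0)
    res
  }
  emit <- function(df, name, ...) {
    path <- file.path(config$out_dir, name)
    writeResultsTable(df, path, ...)
    outputs <<- c(outputs, path)
    path
  }

  if ("expression" %in% config$stages) {
    sim <- timed("simulate_expression", "config", simulateExpression(config$sim))
    norm <- timed("quantile_normalize",
                  paste(dim(sim$matrix), collapse = "x"),
                  quantileNormalize(sim$matrix))
    fits <- timed("paired_anova", paste(dim(norm), collapse = "x"),
                  fitPairedMatrix(norm, sim$design, fold_change = TRUE))
    fits$fdr <- bhFdr(fits$p)
    emit(fits, "expression_fits.tsv")
    gs <- timed("geneset_anova", sprintf("%d sets", length(sim$sets)),
                fitGeneSets(norm, sim$design, sim$sets))
    emit(gs, "geneset_fits.tsv")

    ann <- featureAnnotation(sim$matrix)
    chip_genes <- unique(ann$gene_symbol)
    sig_genes <- unique(ann$gene_symbol[match(
      fits$feature_id[!is.na(fits$fdr) & fits$fdr <= config$fdr_alpha],
      ann$feature_id)])
    enr <- do.call(rbind, lapply(names(geneSets(sim$sets)), function(nm)
      enrichmentScore(sig_genes, geneSets(sim$sets)[[nm]], chip_genes,
                      category = nm)))
    emit(timed("enrichment", sprintf("%d categories", nrow(enr)), enr),
         "enrichment.tsv")
  }

  if ("methylation" %in% config$stages) {
    sim <- timed("simulate_methylation", "config",
                 simulateMethylation(config$sim))
    rec <- timed("call_dml", paste(dim(sim$matrix), collapse = "x"),
                 callDml(sim$matrix, sim$design, sim$manifest,
                         fdr_alpha = config$fdr_alpha))
    rec <- classifyVenn(rec, interaction_alpha = config$interaction_alpha)
    emit(rec, "dml.tsv")
    summ <- summarizePartition(rec)
    emit(summ$by_class, "dml_summary.tsv")
    emit(summ$class_iv_export, "class_iv_loci.tsv")
  }

  if ("clinical" %in% config$stages) {
    clin <- timed("simulate_clinical", "config", simulateClinical(config$sim))
    emit(clinicalAssociations(clin), "clinical.tsv")
    strat <- rbind(stratifiedTests(clin, "lvi", "onset_group", "stage"),
                   stratifiedTests(clin, "pni", "onset_group", "stage"))
    strat$outcome <- rep(c("lvi", "pni"), each = nrow(strat) / 2)
    emit(strat, "clinical_stratified.tsv")
  }

  manifest <- as.list(tools::md5sum(outputs))
  names(manifest) <- basename(names(manifest))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
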