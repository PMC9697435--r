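# Gene-set level mixed ANOVA and chi-square enrichment scoring.
#
# The set model is Y = mu + T + P + G + S(T*P) + e with tissue T and gene
# G fixed, person P random and the sample effect S nested in tissue x
# person random. The analysis runs at the gene level (probes of a gene are
# averaged per sample first) and the result is expressed at the set level
# by averaging the member genes' results; algebraically, on a balanced
# design, that collapse makes the set-level tissue test identical to the
# paired ANOVA on the per-sample mean over member genes, with the sample
# variance as the error stratum (see the methods vignette).

#' Restrict a PairedDesign to one onset group
#' @param design a \linkS4class{PairedDesign}
#' @param onset \code{"EOCRC"} or \code{"LOCRC"}
#' @return a \linkS4class{PairedDesign} containing only that group
#' @export
subsetDesign <- function(design, onset) {
  sh <- designSheet(design)
  sh <- sh[sh$onset_group %in% onset, , drop = FALSE]
  if (!nrow(sh)) stop(sprintf("no samples in onset group '%s'", onset))
  PairedDesign(sh)
}

#' EMS coefficients of the balanced gene-set model
#'
#' For g genes, 2 tissues and a balanced paired design:
#' E[MS_person] = sigma2_e + g sigma2_sample + 2 g sigma2_person;
#' E[MS_sample(TxP)] = sigma2_e + g sigma2_sample;
#' E[MS_error] = sigma2_e.
#'
#' @param n_genes number of member genes g
#' @return 3x3 coefficient matrix for [momVarianceComponents()]
#' @export
emsGeneSetBalanced <- function(n_genes) {
  g <- n_genes
  matrix(c(2 * g, g, 1,
           0,     g, 1,
           0,     0, 1), 3, 3, byrow = TRUE,
         dimnames = list(c("person", "sample", "error"),
                         c("sigma2_person", "sigma2_sample", "sigma2_error")))
}

# probe -> gene summarization: average probes of one gene per sample
# (log2 scale). Features with empty gene_symbol are dropped.
summarizeProbesToGenes <- function(values, gene_symbols) {
  keep <- !is.na(gene_symbols) & nzchar(gene_symbols)
  values <- values[keep, , drop = FALSE]
  gene_symbols <- toupper(gene_symbols[keep])
  if (!nrow(values)) stop("no features carry a gene symbol")
  g <- rowsum(values, gene_symbols, na.rm = TRUE)
  cnt <- rowsum((!is.na(values)) * 1, gene_symbols)
  out <- g / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Gene-set mixed ANOVA
#'
#' Fits the set-level mixed model (see the package description) for one
#' gene set: probes are averaged per gene, genes stacked, and the
#' tumor-normal contrast tested with the sample-to-sample variance as the
#' error stratum. Reported per set: overall and per-onset-group signed
#' fold changes with 95 percent CIs and p-values (tumor vs normal within
#' LOCRC and within EOCRC), the tissue x onset interaction p when
#' requested, and method-of-moments variance components (person, sample,
#' residual) from the balanced complete-pair decomposition.
#'
#' @param x an \linkS4class{OmicsMatrix} whose \code{rowData} carries
#'   \code{gene_symbol}
#' @param design a \linkS4class{PairedDesign}
#' @param genes character vector of member gene symbols (case-insensitive)
#' @param set_name label carried into the result
#' @param with_interaction also fit tissue x onset and report
#'   \code{interaction_p} plus per-group fold changes
#' @param conf confidence level
#' @return one-row data.frame: \code{set_name}, \code{n_genes},
#'   \code{n_probes}, \code{n_genes_missing}, \code{effect},
#'   \code{fold_change}, \code{ci_low}, \code{ci_high}, \code{p},
#'   per-group columns (\code{fold_change_locrc}, \code{ci_low_locrc},
#'   \code{ci_high_locrc}, \code{p_locrc} and \code{_eocrc}
#'   counterparts), \code{interaction_p}, \code{sigma2_person},
#'   \code{sigma2_sample}, \code{sigma2_error}
#' @export
fitGeneSet <- function(x, design, genes, set_name = "set",
                       with_interaction = TRUE, conf = 0.95) {
  genes <- unique(toupper(genes))
  ann <- featureAnnotation(x)
  if (!"gene_symbol" %in% names(ann))
    stop("matrix rowData lacks gene_symbol annotation")
  ann$gene_symbol <- toupper(ann$gene_symbol)
  hit <- ann$gene_symbol %in% genes
  found <- unique(ann$gene_symbol[hit])
  missing <- setdiff(genes, found)
  if (!length(found))
    stop(sprintf("no member gene of '%s' found on the chip; missing: %s",
                 set_name, paste(missing, collapse = ", ")))
  sub <- omicsValues(x)[hit, , drop = FALSE]
  gmat <- summarizeProbesToGenes(sub, ann$gene_symbol[hit])

  # set-level response: per-sample mean over member genes
  y <- colMeans(gmat, na.rm = FALSE)
  if (anyNA(y)) y <- colMeans(gmat, na.rm = TRUE)
  overall <- fitPaired(y, design, feature_id = set_name, conf = conf)
  if (overall$flag == "too_few_pairs")
    stop(sprintf("gene set '%s' is inestimable: fewer than 2 complete pairs",
                 set_name))

  out <- data.frame(set_name = set_name, n_genes = length(found),
                    n_probes = nrow(sub), n_genes_missing = length(missing),
                    effect = overall$effect, fold_change = overall$fold_change,
                    ci_low = overall$ci_low, ci_high = overall$ci_high,
                    p = overall$p,
                    fold_change_locrc = NA_real_, ci_low_locrc = NA_real_,
                    ci_high_locrc = NA_real_, p_locrc = NA_real_,
                    fold_change_eocrc = NA_real_, ci_low_eocrc = NA_real_,
                    ci_high_eocrc = NA_real_, p_eocrc = NA_real_,
                    interaction_p = NA_real_,
                    sigma2_person = NA_real_, sigma2_sample = NA_real_,
                    sigma2_error = NA_real_, stringsAsFactors = FALSE)

  # variance components from the full balanced decomposition over the
  # complete pairs with no missing gene values
  cp <- completePairs(design)
  gm <- gmat[, c(cp$tumor, cp$normal), drop = FALSE]
  if (!anyNA(gm) && nrow(cp) >= 2) {
    vc <- geneset_varcomp(gm, cp)
    out$sigma2_person <- vc[["sigma2_person"]]
    out$sigma2_sample <- vc[["sigma2_sample"]]
    out$sigma2_error  <- vc[["sigma2_error"]]
  }

  if (with_interaction) {
    for (g in ONSET_LEVELS) {
      fitg <- fitPaired(y, subsetDesign(design, g), feature_id = set_name,
                        conf = conf)
      suf <- tolower(g)
      out[[paste0("fold_change_", substr(suf, 1, 5))]] <- fitg$fold_change
      out[[paste0("ci_low_", substr(suf, 1, 5))]] <- fitg$ci_low
      out[[paste0("ci_high_", substr(suf, 1, 5))]] <- fitg$ci_high
      out[[paste0("p_", substr(suf, 1, 5))]] <- fitg$p
    }
    inter <- fitInteraction(y, design, feature_id = set_name, conf = conf)
    out$interaction_p <- inter$interaction_p
  }
  out
}

# sums-of-squares decomposition of the balanced gene x sample grid and
# MoM solve; gm is genes x (tumor samples, normal samples) ordered by cp
geneset_varcomp <- function(gm, cp) {
  g <- nrow(gm); n <- nrow(cp)
  grand <- mean(gm)
  samp_mean <- colMeans(gm)
  gene_mean <- rowMeans(gm)
  tiss <- rep(c("tumor", "normal"), each = n)
  pers <- rep(cp$person_id, 2)
  t_mean <- tapply(samp_mean, tiss, mean)
  p_mean <- tapply(samp_mean, pers, mean)
  ss_t <- g * n * sum((t_mean - grand)^2)
  ss_p <- g * 2 * sum((p_mean - grand)^2)
  ss_samp_tot <- g * sum((samp_mean - grand)^2)
  ss_s <- ss_samp_tot - ss_t - ss_p
  ss_g <- 2 * n * sum((gene_mean - grand)^2)
  ss_tot <- sum((gm - grand)^2)
  ss_e <- ss_tot - ss_samp_tot - ss_g
  df_p <- n - 1; df_s <- n - 1
  df_e <- (g - 1) * (2 * n - 1)
  ms <- c(person = ss_p / df_p, sample = ss_s / df_s, error = ss_e / df_e)
  momVarianceComponents(ms, emsGeneSetBalanced(g))$components
}

#' Fit every set of a GeneSetLibrary
#'
#' @param x an \linkS4class{OmicsMatrix} with \code{gene_symbol} rowData
#' @param design a \linkS4class{PairedDesign}
#' @param library a \linkS4class{GeneSetLibrary}
#' @param with_interaction report interaction and per-group columns
#' @return data.frame, one row per set (see [fitGeneSet()]); sets with no
#'   gene on the chip are skipped with a warning
#' @export
fitGeneSets <- function(x, design, library, with_interaction = TRUE) {
  res <- lapply(names(geneSets(library)), function(nm) {
    tryCatch(fitGeneSet(x, design, geneSets(library)[[nm]], set_name = nm,
                        with_interaction = with_interaction),
             error = function(e) { warning(conditionMessage(e)); NULL })
  })
  do.call(rbind, res)
}

#' Chi-square enrichment score of a gene category
#'
#' Compares "significant genes in the category / all significant genes"
#' against "chip genes in the category / all chip genes" with a 2x2
#' Pearson chi-square (no continuity correction): rows are in-category vs
#' not, columns are significant genes vs the rest of the chip. The
#' enrichment score is -log10(p), so a high score marks a lead functional
#' group. With no significant genes, or a category spanning the whole
#' chip, the test is degenerate and the score is 0 with a flag.
#'
#' @param sig_genes character vector of significant gene symbols
#' @param category_genes character vector of the category's gene symbols
#' @param chip_genes character vector of all gene symbols on the chip
#' @param category label carried into the result
#' @return one-row data.frame: \code{category}, \code{k_sig_in_cat},
#'   \code{k_sig_total}, \code{n_chip_in_cat}, \code{n_chip_total},
#'   \code{chi2}, \code{p}, \code{enrichment_score}, \code{flag}
#' @export
enrichmentScore <- function(sig_genes, category_genes, chip_genes,
                            category = "category") {
  chip <- unique(toupper(chip_genes))
  sig <- intersect(unique(toupper(sig_genes)), chip)
  cat_g <- intersect(unique(toupper(category_genes)), chip)
  k_in <- length(intersect(sig, cat_g))
  out <- data.frame(category = category, k_sig_in_cat = k_in,
                    k_sig_total = length(sig),
                    n_chip_in_cat = length(cat_g),
                    n_chip_total = length(chip),
                    chi2 = NA_real_, p = NA_real_, enrichment_score = 0,
                    flag = "", stringsAsFactors = FALSE)
  if (!length(sig)) { out$flag <- "no_significant_genes"; return(out) }
  rest <- setdiff(chip, sig)
  r_in <- length(intersect(rest, cat_g))
  tab <- matrix(c(k_in, length(sig) - k_in,
                  r_in, length(rest) - r_in), 2, 2,
                dimnames = list(c("in_category", "not_in_category"),
                                c("significant", "rest_of_chip")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    out$flag <- "degenerate_margin"
    return(out)
  }
  ct <- chiSquareTest(tab)
  out$chi2 <- ct$chi2; out$p <- ct$p
  out$enrichment_score <- -log10(ct$p)
  out
}
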