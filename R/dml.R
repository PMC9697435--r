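# Differentially methylated locus (DML) calling per onset group and the
# five-class interaction/Venn partition.
#
# A DML is a locus whose paired tumor-vs-normal test survives BH FDR <=
# 0.05 within an onset group; deep-sea loci (> 4 kb from any CpG island)
# are excluded before testing. Crossing group membership (both / EOCRC
# only / LOCRC only) with the tissue x onset interaction test (p < alpha
# vs not) yields classes I-V plus the unnamed LOCRC-only/interaction-ns
# group retained so the classes partition.

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Classic step-up: sort the m p-values ascending, take q_(i) =
#' min over j >= i of p_(j) m / j (capped at 1), and map back to the input
#' order. Never produces q < p and is non-decreasing in sorted-p order.
#'
#' @param pvalues numeric vector of p-values in (0, 1]; NAs propagate
#' @return q-values in input order
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(pvalues) {
  m <- sum(!is.na(pvalues))
  if (!m) return(pvalues)
  q <- rep(NA_real_, length(pvalues))
  idx <- order(pvalues, na.last = NA)
  p <- pvalues[idx]
  stepup <- rev(cummin(rev(p * m / seq_len(m))))
  q[idx] <- pmin(stepup, 1)
  q
}

#' Call differentially methylated loci per onset group
#'
#' Excludes deep-sea loci, then within each onset group applies the paired
#' model ([fitPairedMatrix()]) per locus over that group's complete pairs.
#' Delta beta is the mean of within-person (tumor - normal) differences,
#' so unpaired samples never contribute. BH FDR is computed within each
#' group across its tested loci (separately, not pooled) and a locus is a
#' DML in a group when q <= \code{fdr_alpha}. The tissue x onset
#' interaction p comes from [fitInteractionMatrix()] (fixed-effects model,
#' no person term).
#'
#' @param x an \linkS4class{OmicsMatrix} of kind \code{methylation_beta}
#' @param design a \linkS4class{PairedDesign} with both onset groups
#' @param manifest feature annotation data.frame (\code{feature_id},
#'   \code{region_class}); must cover every locus. May be omitted when the
#'   matrix itself carries \code{region_class} rowData.
#' @param fdr_alpha FDR threshold defining a DML, default 0.05
#' @return data.frame, one row per tested (non-deep-sea) locus:
#'   \code{locus_id}, \code{region_class}, \code{delta_beta_locrc},
#'   \code{delta_beta_eocrc}, \code{p_locrc}, \code{p_eocrc},
#'   \code{fdr_locrc}, \code{fdr_eocrc}, \code{dml_locrc},
#'   \code{dml_eocrc}, \code{interaction_p}
#' @export
callDml <- function(x, design, manifest = NULL, fdr_alpha = 0.05) {
  v <- omicsValues(x)
  if (is.null(manifest)) {
    manifest <- featureAnnotation(x)
    if (!"region_class" %in% names(manifest))
      stop("no manifest given and matrix rowData lacks region_class")
  }
  idx <- match(rownames(v), manifest$feature_id)
  if (anyNA(idx))
    stop(sprintf("locus '%s' missing from the manifest",
                 rownames(v)[which(is.na(idx))[1]]))
  region <- manifest$region_class[idx]
  keep <- region != "deep_sea"
  v <- v[keep, , drop = FALSE]
  region <- region[keep]
  if (!nrow(v)) stop("no loci left after deep-sea exclusion")

  for (g in ONSET_LEVELS)
    if (nrow(completePairs(design, g)) < 2)
      stop(sprintf("onset group '%s' has fewer than 2 complete pairs", g))

  fe <- fitPairedMatrix(v, design, onset = "EOCRC")
  fl <- fitPairedMatrix(v, design, onset = "LOCRC")
  inter <- fitInteractionMatrix(v, design)

  out <- data.frame(locus_id = rownames(v), region_class = region,
                    delta_beta_locrc = fl$effect, delta_beta_eocrc = fe$effect,
                    p_locrc = fl$p, p_eocrc = fe$p,
                    fdr_locrc = bhFdr(fl$p), fdr_eocrc = bhFdr(fe$p),
                    interaction_p = inter$interaction_p,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$dml_locrc <- !is.na(out$fdr_locrc) & out$fdr_locrc <= fdr_alpha
  out$dml_eocrc <- !is.na(out$fdr_eocrc) & out$fdr_eocrc <= fdr_alpha
  out
}

#' Assign the five-class interaction/Venn partition
#'
#' Crosses per-group DML status with the interaction test at
#' \code{interaction_alpha}:
#' \describe{
#'   \item{I}{DML in both groups, interaction p >= alpha (shared, same
#'     magnitude of delta beta)}
#'   \item{II}{DML in both groups, interaction p < alpha (shared, different
#'     magnitude)}
#'   \item{III}{DML in EOCRC only, interaction p >= alpha}
#'   \item{IV}{DML in EOCRC only, interaction p < alpha (EOCRC specific)}
#'   \item{V}{DML in LOCRC only, interaction p < alpha (LOCRC specific)}
#'   \item{locrc_only_ns}{DML in LOCRC only, interaction p >= alpha
#'     (unnamed in the partition's usual presentation; retained so every
#'     locus gets exactly one class)}
#'   \item{not_dml}{DML in neither group}
#' }
#'
#' @param records data.frame from [callDml()] (needs \code{dml_locrc},
#'   \code{dml_eocrc}, \code{interaction_p})
#' @param interaction_alpha threshold on the interaction p, default 0.05
#' @return the records with a \code{venn_class} column added
#' @export
classifyVenn <- function(records, interaction_alpha = 0.05) {
  req <- c("dml_locrc", "dml_eocrc", "interaction_p")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop(paste("records lack column(s):", paste(miss, collapse = ", ")))
  if (anyNA(records$interaction_p))
    stop("interaction_p must be populated for every record")
  both <- records$dml_locrc & records$dml_eocrc
  eo   <- records$dml_eocrc & !records$dml_locrc
  lo   <- records$dml_locrc & !records$dml_eocrc
  sig  <- records$interaction_p < interaction_alpha
  cls <- rep("not_dml", nrow(records))
  cls[both & !sig] <- "I"
  cls[both &  sig] <- "II"
  cls[eo   & !sig] <- "III"
  cls[eo   &  sig] <- "IV"
  cls[lo   &  sig] <- "V"
  cls[lo   & !sig] <- "locrc_only_ns"
  records$venn_class <- cls
  records
}

#' Summarize the Venn partition
#'
#' Per-class bookkeeping: counts, delta-beta extrema per group, and how
#' many loci exceed the 0.1 and 0.2 absolute delta-beta bins (the 10
#' percent / 20 percent differential-methylation magnitudes used to judge
#' robustness). By construction |I| + |II| equals the common-DML count and
#' |III| + |IV| the EOCRC-only count.
#'
#' @param records classified records from [classifyVenn()]
#' @return list with \code{by_class} (data.frame, one row per class),
#'   \code{n_dml_locrc}, \code{n_dml_eocrc}, \code{n_common},
#'   \code{n_eocrc_only}, \code{n_locrc_only},
#'   \code{n_interaction_sig}, and \code{class_iv_export} (data.frame of
#'   class-IV loci with per-group delta betas, scatter/PCA-ready)
#' @export
summarizePartition <- function(records) {
  if (!"venn_class" %in% names(records))
    stop("records are not classified; run classifyVenn() first")
  classes <- c("I", "II", "III", "IV", "V", "locrc_only_ns", "not_dml")
  rows <- lapply(classes, function(cl) {
    r <- records[records$venn_class == cl, , drop = FALSE]
    adb <- pmax(abs(r$delta_beta_locrc), abs(r$delta_beta_eocrc))
    data.frame(venn_class = cl, n = nrow(r),
               delta_beta_locrc_min = suppressWarnings(min(r$delta_beta_locrc)),
               delta_beta_locrc_max = suppressWarnings(max(r$delta_beta_locrc)),
               delta_beta_eocrc_min = suppressWarnings(min(r$delta_beta_eocrc)),
               delta_beta_eocrc_max = suppressWarnings(max(r$delta_beta_eocrc)),
               n_delta_ge_0.1 = sum(adb >= 0.1, na.rm = TRUE),
               n_delta_ge_0.2 = sum(adb >= 0.2, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  by_class <- do.call(rbind, rows)
  iv <- records[records$venn_class == "IV",
                c("locus_id", "delta_beta_locrc", "delta_beta_eocrc",
                  "fdr_eocrc", "interaction_p"), drop = FALSE]
  list(by_class = by_class,
       n_dml_locrc = sum(records$dml_locrc),
       n_dml_eocrc = sum(records$dml_eocrc),
       n_common = sum(records$dml_locrc & records$dml_eocrc),
       n_eocrc_only = sum(records$dml_eocrc & !records$dml_locrc),
       n_locrc_only = sum(records$dml_locrc & !records$dml_eocrc),
       n_interaction_sig = sum(records$interaction_p < 0.05, na.rm = TRUE),
       class_iv_export = iv)
}
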