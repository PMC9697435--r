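# Per-feature inference engine: paired mixed ANOVA with a random person
# effect (method-of-moments variance components via expected mean squares),
# the tissue x onset-group interaction model, and the signed fold-change
# convention used throughout microarray reporting.

#' Signed fold change with confidence interval from a log2 effect
#'
#' The CI is computed on the log2 scale as effect +/- t(0.975, df) * se and
#' each endpoint e is mapped to a signed ratio: 2^e for e >= 0, and
#' -2^(-e) for e < 0 (the "-1/x for down-regulation" convention, so a 12
#' percent decrease prints as -1.12). Ordering of the endpoints is
#' preserved. With df <= 0 the CI is reported missing and the point
#' estimate kept.
#'
#' @param effect log2-scale difference (e.g. mean tumor - normal)
#' @param se standard error of the effect, >= 0
#' @param df residual degrees of freedom for the t quantile
#' @param conf confidence level, default 0.95
#' @return list with \code{fold_change}, \code{ci_low}, \code{ci_high}
#' @examples
#' foldChangeFromLog2(log2(1.46), 0.01, 70)$fold_change  # 1.46
#' foldChangeFromLog2(-log2(1.12), 0.01, 70)$fold_change # -1.12
#' @export
foldChangeFromLog2 <- function(effect, se, df, conf = 0.95) {
  if (any(se < 0, na.rm = TRUE)) stop("se must be >= 0")
  fc <- signed_ratio(effect)
  if (is.na(df) || df <= 0)
    return(list(fold_change = fc, ci_low = NA_real_, ci_high = NA_real_))
  half <- stats::qt(1 - (1 - conf) / 2, df) * se
  list(fold_change = fc,
       ci_low  = signed_ratio(effect - half),
       ci_high = signed_ratio(effect + half))
}

# log2 difference -> signed ratio in (-Inf,-1] U [1,Inf)
signed_ratio <- function(e) ifelse(e >= 0, 2^e, -(2^(-e)))

#' Method-of-moments variance components from mean squares
#'
#' Solves the expected-mean-squares linear system E[MS] = C sigma2 for the
#' variance components of a mixed ANOVA. Any negative solution is clamped
#' to zero and flagged (\code{negative_clamped}); a singular system is an
#' error naming the confounded terms.
#'
#' @param mean_squares named numeric vector of observed mean squares, one
#'   per estimating equation (e.g. \code{c(person = ..., error = ...)})
#' @param ems square numeric matrix of EMS coefficients; rows follow
#'   \code{mean_squares}, columns are the variance components (named)
#' @return list with \code{components} (named, clamped at 0),
#'   \code{raw} (unclamped solution) and \code{negative_clamped} (named
#'   logical)
#' @examples
#' # balanced paired design, 2 observations per person:
#' # E[MS_person] = sigma2_e + 2 sigma2_p ; E[MS_error] = sigma2_e
#' momVarianceComponents(c(person = 3.1, error = 0.9),
#'                       emsPairedBalanced())
#' @export
momVarianceComponents <- function(mean_squares, ems) {
  if (length(mean_squares) != nrow(ems))
    stop("one mean square per EMS equation is required")
  if (abs(det(ems)) < 1e-12)
    stop(sprintf("singular EMS system: terms {%s} are confounded",
                 paste(rownames(ems), collapse = ", ")))
  raw <- drop(solve(ems, mean_squares))
  names(raw) <- colnames(ems)
  clamped <- raw < 0
  comp <- pmax(raw, 0)
  list(components = comp, raw = raw, negative_clamped = clamped)
}

#' EMS coefficients of the balanced paired design
#'
#' Two observations (tumor, normal) per person:
#' E[MS_person] = sigma2_error + 2 sigma2_person;
#' E[MS_error] = sigma2_error. Hence
#' sigma2_person = (MS_person - MS_error) / 2.
#'
#' @return 2x2 coefficient matrix for [momVarianceComponents()]
#' @export
emsPairedBalanced <- function() {
  matrix(c(2, 1, 0, 1), 2, 2, byrow = TRUE,
         dimnames = list(c("person", "error"),
                         c("sigma2_person", "sigma2_error")))
}

# extract tumor/normal value matrix-pair for the complete pairs of a design
paired_values <- function(values, design, onset = NULL) {
  cp <- completePairs(design, onset)
  list(pairs = cp,
       tumor = values[cp$tumor], normal = values[cp$normal])
}

#' Paired mixed-model ANOVA for one feature
#'
#' Fits Y = mu + tissue + person + error with person random, on the
#' complete tumor/normal pairs of the design (unpaired samples and pairs
#' with a missing value are excluded; their count is returned). Variance
#' components are estimated by method of moments from the expected mean
#' squares; the tissue F-test uses the residual mean square after person
#' as denominator, so on this balanced design the tissue p equals the
#' two-sided paired t-test p and F = t^2.
#'
#' @param values named numeric vector of the feature's values; names are
#'   sample ids
#' @param design a \linkS4class{PairedDesign}
#' @param feature_id label carried into the result
#' @param fold_change compute the signed fold change and 95 percent CI
#'   (meaningful for log2 responses)
#' @param conf confidence level for the CI
#' @return one-row data.frame: \code{feature_id}, \code{n_pairs},
#'   \code{n_excluded}, \code{effect} (mean tumor - normal), \code{se},
#'   \code{F}, \code{df_num}, \code{df_den}, \code{p}, \code{fold_change},
#'   \code{ci_low}, \code{ci_high}, \code{sigma2_person},
#'   \code{sigma2_error}, \code{person_clamped}, \code{flag}
#' @export
fitPaired <- function(values, design, feature_id = "feature",
                      fold_change = TRUE, conf = 0.95) {
  pv <- paired_values(values, design)
  ok <- !is.na(pv$tumor) & !is.na(pv$normal)
  n_total <- length(unique(designSheet(design)$person_id))
  tum <- pv$tumor[ok]; nor <- pv$normal[ok]
  n <- length(tum)
  base <- data.frame(feature_id = feature_id, n_pairs = n,
                     n_excluded = n_total - n,
                     effect = NA_real_, se = NA_real_, F = NA_real_,
                     df_num = 1, df_den = NA_real_, p = NA_real_,
                     fold_change = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, sigma2_person = NA_real_,
                     sigma2_error = NA_real_, person_clamped = FALSE,
                     flag = "", stringsAsFactors = FALSE)
  if (n < 2) { base$flag <- "too_few_pairs"; return(base) }

  d <- tum - nor
  eff <- mean(d)
  # randomized-block decomposition with 2 treatments:
  # MS_error = sum((d - dbar)^2) / (2 (n-1)); MS_tissue = n dbar^2 / 2
  ms_error  <- sum((d - eff)^2) / (2 * (n - 1))
  ms_tissue <- n * eff^2 / 2
  pm <- (tum + nor) / 2
  ms_person <- 2 * sum((pm - mean(pm))^2) / (n - 1)
  vc <- momVarianceComponents(c(person = ms_person, error = ms_error),
                              emsPairedBalanced())

  base$effect <- eff
  base$se <- sqrt(2 * ms_error / n)      # = sd(d)/sqrt(n)
  base$df_den <- n - 1
  base$sigma2_person <- vc$components[["sigma2_person"]]
  base$sigma2_error  <- vc$components[["sigma2_error"]]
  base$person_clamped <- vc$negative_clamped[["sigma2_person"]]
  if (ms_error == 0) {
    base$F <- if (eff == 0) 0 else Inf
    base$p <- if (eff == 0) 1 else .Machine$double.xmin
    base$flag <- "degenerate_zero_residual"
  } else {
    base$F <- ms_tissue / ms_error
    base$p <- stats::pf(base$F, 1, n - 1, lower.tail = FALSE)
  }
  if (fold_change) {
    fc <- foldChangeFromLog2(eff, base$se, base$df_den, conf)
    base$fold_change <- fc$fold_change
    base$ci_low <- fc$ci_low; base$ci_high <- fc$ci_high
  }
  base
}

#' Tissue x age-of-onset interaction ANOVA for one feature
#'
#' Fits the fixed-effects model Y = mu + tissue + onset + tissue x onset +
#' error over all samples of both onset groups (the interaction equation
#' has no person term; see the methods vignette for the rationale). The
#' interaction contrast is (tumor - normal in EOCRC) - (tumor - normal in
#' LOCRC), tested against the pooled within-cell mean square; per-group
#' tissue effects, fold changes and p-values are also reported for
#' two-column (late/early) table output.
#'
#' @param values named numeric vector (names = sample ids)
#' @param design a \linkS4class{PairedDesign}
#' @param feature_id label carried into the result
#' @param fold_change compute signed fold changes for the group effects
#' @param conf confidence level
#' @return one-row data.frame with per-group columns (\code{effect_eocrc},
#'   \code{se_eocrc}, \code{p_eocrc}, \code{fold_change_eocrc},
#'   \code{ci_low_eocrc}, \code{ci_high_eocrc}, and the \code{_locrc}
#'   counterparts), plus \code{interaction_effect}, \code{interaction_se},
#'   \code{interaction_F}, \code{interaction_p}, \code{df_den},
#'   \code{n_samples}, \code{flag}
#' @export
fitInteraction <- function(values, design, feature_id = "feature",
                           fold_change = TRUE, conf = 0.95) {
  sh <- designSheet(design)
  v <- values[sh$sample_id]
  keep <- !is.na(v)
  sh <- sh[keep, , drop = FALSE]; v <- v[keep]
  for (g in ONSET_LEVELS) {
    if (nrow(completePairs(design, g)) < 2)
      stop(sprintf("onset group '%s' needs >= 2 complete pairs", g))
  }
  cell <- interaction(sh$tissue, sh$onset_group, drop = FALSE)
  want <- c("tumor.EOCRC", "normal.EOCRC", "tumor.LOCRC", "normal.LOCRC")
  ncell <- table(factor(cell, want))
  if (any(ncell == 0))
    stop(sprintf("empty design cell '%s'", want[ncell == 0][1]))
  mu <- tapply(v, factor(cell, want), mean)
  ssw <- tapply(v, factor(cell, want), function(x) sum((x - mean(x))^2))
  N <- sum(ncell); df_den <- N - 4
  mse <- sum(ssw) / df_den
  inv_n <- 1 / as.numeric(ncell)

  d_e <- mu[["tumor.EOCRC"]] - mu[["normal.EOCRC"]]
  d_l <- mu[["tumor.LOCRC"]] - mu[["normal.LOCRC"]]
  est <- d_e - d_l
  se_int <- sqrt(mse * sum(inv_n))
  se_e <- sqrt(mse * (inv_n[1] + inv_n[2]))
  se_l <- sqrt(mse * (inv_n[3] + inv_n[4]))

  tstat <- function(e, s) {
    if (s > 0) return(e / s)
    if (e == 0) 0 else Inf * sign(e)     # degenerate: exact zero vs certain
  }
  pt2 <- function(t) if (!is.finite(t)) .Machine$double.xmin else
    2 * stats::pt(-abs(t), df_den)
  out <- data.frame(feature_id = feature_id, n_samples = N,
                    effect_eocrc = d_e, se_eocrc = se_e, p_eocrc = pt2(tstat(d_e, se_e)),
                    effect_locrc = d_l, se_locrc = se_l, p_locrc = pt2(tstat(d_l, se_l)),
                    fold_change_eocrc = NA_real_, ci_low_eocrc = NA_real_,
                    ci_high_eocrc = NA_real_, fold_change_locrc = NA_real_,
                    ci_low_locrc = NA_real_, ci_high_locrc = NA_real_,
                    interaction_effect = est, interaction_se = se_int,
                    interaction_F = tstat(est, se_int)^2,
                    interaction_p = pt2(tstat(est, se_int)),
                    df_den = df_den, flag = if (mse == 0) "degenerate_zero_residual" else "",
                    stringsAsFactors = FALSE)
  if (fold_change) {
    fe <- foldChangeFromLog2(d_e, se_e, df_den, conf)
    fl <- foldChangeFromLog2(d_l, se_l, df_den, conf)
    out$fold_change_eocrc <- fe$fold_change
    out$ci_low_eocrc <- fe$ci_low; out$ci_high_eocrc <- fe$ci_high
    out$fold_change_locrc <- fl$fold_change
    out$ci_low_locrc <- fl$ci_low; out$ci_high_locrc <- fl$ci_high
  }
  out
}

#' Paired ANOVA across all features of a matrix (vectorised)
#'
#' Matrix counterpart of [fitPaired()]: one paired test per feature on the
#' design's complete pairs, with per-feature exclusion of pairs carrying a
#' missing value. Identical inference to [fitPaired()] (F = t^2 of the
#' paired t-test).
#'
#' @param x an \linkS4class{OmicsMatrix} (or numeric matrix with sample
#'   columns)
#' @param design a \linkS4class{PairedDesign}
#' @param onset optional onset group to restrict the pairs to
#' @param fold_change compute signed fold changes (use for log2 data)
#' @return data.frame, one row per feature: \code{feature_id},
#'   \code{n_pairs}, \code{effect}, \code{se}, \code{F}, \code{df_den},
#'   \code{p}, optional fold-change columns, \code{flag}
#' @export
fitPairedMatrix <- function(x, design, onset = NULL, fold_change = FALSE) {
  m <- if (is(x, "OmicsMatrix")) omicsValues(x) else as.matrix(x)
  cp <- completePairs(design, onset)
  if (nrow(cp) < 2) stop("need >= 2 complete pairs")
  D <- m[, cp$tumor, drop = FALSE] - m[, cp$normal, drop = FALSE]
  n <- rowSums(!is.na(D))
  eff <- rowMeans(D, na.rm = TRUE)
  ss <- rowSums((D - eff)^2, na.rm = TRUE)
  vard <- ifelse(n > 1, ss / (n - 1), NA_real_)
  se <- sqrt(vard / n)
  tt <- eff / se
  df <- n - 1
  p <- 2 * stats::pt(-abs(tt), df)
  flag <- rep("", nrow(m))
  flag[n < 2] <- "too_few_pairs"
  deg <- n >= 2 & vard == 0
  flag[deg] <- "degenerate_zero_residual"
  p[deg] <- ifelse(eff[deg] == 0, 1, .Machine$double.xmin)
  tt[deg] <- ifelse(eff[deg] == 0, 0, Inf)
  p[n < 2] <- NA_real_
  out <- data.frame(feature_id = rownames(m), n_pairs = n, effect = eff,
                    se = se, F = tt^2, df_den = df, p = p, flag = flag,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (fold_change) {
    q <- stats::qt(0.975, df)
    out$fold_change <- signed_ratio(eff)
    out$ci_low  <- signed_ratio(eff - q * se)
    out$ci_high <- signed_ratio(eff + q * se)
  }
  out
}

#' Tissue x onset interaction ANOVA across all features (vectorised)
#'
#' Matrix counterpart of [fitInteraction()]: the fixed-effects cell-means
#' model per feature, pooled within-cell error, interaction contrast
#' (tumor - normal in EOCRC) - (tumor - normal in LOCRC).
#'
#' @param x an \linkS4class{OmicsMatrix} or numeric matrix
#' @param design a \linkS4class{PairedDesign}
#' @return data.frame, one row per feature: per-group effects and p-values,
#'   \code{interaction_effect}, \code{interaction_p}, \code{df_den}
#' @export
fitInteractionMatrix <- function(x, design) {
  m <- if (is(x, "OmicsMatrix")) omicsValues(x) else as.matrix(x)
  sh <- designSheet(design)
  sh <- sh[sh$sample_id %in% colnames(m), , drop = FALSE]
  cells <- list(te = sh$sample_id[sh$tissue == "tumor"  & sh$onset_group == "EOCRC"],
                ne = sh$sample_id[sh$tissue == "normal" & sh$onset_group == "EOCRC"],
                tl = sh$sample_id[sh$tissue == "tumor"  & sh$onset_group == "LOCRC"],
                nl = sh$sample_id[sh$tissue == "normal" & sh$onset_group == "LOCRC"])
  if (any(lengths(cells) == 0))
    stop(sprintf("empty design cell '%s'",
                 names(cells)[lengths(cells) == 0][1]))
  st <- lapply(cells, function(cols) {
    sub <- m[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    ss <- rowSums((sub - mu)^2, na.rm = TRUE)
    list(n = n, mu = mu, ss = ss)
  })
  N <- st$te$n + st$ne$n + st$tl$n + st$nl$n
  df <- N - 4
  mse <- (st$te$ss + st$ne$ss + st$tl$ss + st$nl$ss) / df
  d_e <- st$te$mu - st$ne$mu
  d_l <- st$tl$mu - st$nl$mu
  est <- d_e - d_l
  inv <- 1 / st$te$n + 1 / st$ne$n + 1 / st$tl$n + 1 / st$nl$n
  se <- sqrt(mse * inv)
  tt <- est / se
  p <- 2 * stats::pt(-abs(tt), df)
  deg <- is.finite(est) & se == 0
  p[deg] <- ifelse(est[deg] == 0, 1, .Machine$double.xmin)
  data.frame(feature_id = rownames(m), n_samples = N,
             effect_eocrc = d_e, effect_locrc = d_l,
             interaction_effect = est, interaction_se = se,
             interaction_p = p, df_den = df,
             row.names = NULL, stringsAsFactors = FALSE)
}
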