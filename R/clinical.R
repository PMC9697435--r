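# Clinical/histological association analyses: contingency chi-square
# tests (uncorrected Pearson -- the convention that reproduces published
# clinical tables), stage-stratified tests, and two-sample t-tests from
# summary statistics.

#' Pearson chi-square test of a contingency table
#'
#' Uncorrected Pearson chi-square with the asymptotic p-value on
#' (rows - 1)(cols - 1) degrees of freedom. No Yates continuity
#' correction and no Fisher fallback; the smallest expected cell count is
#' reported so the caller can judge validity. A zero row or column margin
#' leaves the test undefined and is an error.
#'
#' @param table integer matrix of counts (>= 2 rows and >= 2 columns), or
#'   a data.frame coercible to one
#' @return one-row data.frame: \code{chi2}, \code{df}, \code{p},
#'   \code{expected_min}, \code{n}
#' @examples
#' # onset group x stage cross-tabulation
#' chiSquareTest(rbind(late = c(30, 26, 42), early = c(7, 16, 44)))
#' @export
chiSquareTest <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("counts must be numeric")
  if (any(m < 0) || any(is.na(m))) stop("counts must be non-negative and complete")
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("contingency table needs >= 2 rows and >= 2 columns")
  if (sum(m) <= 0) stop("grand total must be positive")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row/column margin: chi-square test undefined")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  data.frame(chi2 = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value, expected_min = min(ct$expected), n = sum(m))
}

#' Cross-tabulate two covariates of a design
#'
#' One row per person (clinical covariates are person-level; the tumor
#' row of each person is used, falling back to any row for unpaired
#' persons). Missing categories are dropped.
#'
#' @param design a \linkS4class{PairedDesign}
#' @param row_var,col_var clinical covariate names (or
#'   \code{"onset_group"})
#' @return contingency matrix of person counts
#' @export
crossTab <- function(design, row_var, col_var) {
  pp <- person_table(design)
  for (v in c(row_var, col_var))
    if (!v %in% names(pp))
      stop(sprintf("covariate '%s' not present in the design", v))
  table(pp[[row_var]], pp[[col_var]], dnn = c(row_var, col_var))
}

# one row per person; tumor-sample row preferred as covariate source
person_table <- function(design) {
  sh <- designSheet(design)
  sh <- sh[order(sh$person_id, match(sh$tissue, TISSUE_LEVELS)), , drop = FALSE]
  sh[!duplicated(sh$person_id), , drop = FALSE]
}

#' Stratified chi-square tests
#'
#' One uncorrected Pearson chi-square per stratum level on the
#' outcome-by-exposure cross-tabulation (e.g. LVI by onset group within
#' each stage). A stratum whose table has a zero margin or fewer than two
#' categories on either axis is reported untestable; the other strata are
#' still computed.
#'
#' @param design a \linkS4class{PairedDesign}
#' @param outcome,exposure,stratum clinical covariate names
#' @return data.frame, one row per stratum level: \code{stratum},
#'   \code{level}, \code{chi2}, \code{df}, \code{p}, \code{expected_min},
#'   \code{n}, \code{testable}
#' @export
stratifiedTests <- function(design, outcome, exposure, stratum) {
  pp <- person_table(design)
  for (v in c(outcome, exposure, stratum))
    if (!v %in% names(pp))
      stop(sprintf("covariate '%s' not present in the design", v))
  levels <- sort(unique(stats::na.omit(pp[[stratum]])))
  rows <- lapply(levels, function(lv) {
    sub <- pp[!is.na(pp[[stratum]]) & pp[[stratum]] == lv, , drop = FALSE]
    tab <- table(sub[[outcome]], sub[[exposure]])
    base <- data.frame(stratum = stratum, level = as.character(lv),
                       chi2 = NA_real_, df = NA_real_, p = NA_real_,
                       expected_min = NA_real_, n = sum(tab),
                       testable = FALSE, stringsAsFactors = FALSE)
    res <- tryCatch(chiSquareTest(tab), error = function(e) NULL)
    if (!is.null(res)) {
      base[c("chi2", "df", "p", "expected_min", "n")] <-
        res[c("chi2", "df", "p", "expected_min", "n")]
      base$testable <- TRUE
    }
    base
  })
  do.call(rbind, rows)
}

#' Two-sample t-test from summary statistics
#'
#' Two-sided t-test computed from group means, SDs and sizes only (for
#' published-table verification where raw values are unavailable). Welch
#' (unequal variances, Welch-Satterthwaite df) is the default; the pooled
#' equal-variance variant is available.
#'
#' @param mean1,sd1,n1 summary statistics of group 1
#' @param mean2,sd2,n2 summary statistics of group 2
#' @param var_equal use the pooled equal-variance formula instead of Welch
#' @return one-row data.frame: \code{t}, \code{df}, \code{p},
#'   \code{mean_diff}, \code{method}
#' @export
tTestFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2,
                             var_equal = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "pooled"
  } else {
    a <- sd1^2 / n1; b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
    method <- "welch"
  }
  t <- (mean1 - mean2) / se
  data.frame(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
             mean_diff = mean1 - mean2, method = method,
             stringsAsFactors = FALSE)
}

#' Clinical association screen of a design
#'
#' Convenience wrapper reproducing a clinical comparison table: for each
#' requested covariate, the covariate x onset-group cross-tabulation and
#' its uncorrected Pearson chi-square p.
#'
#' @param design a \linkS4class{PairedDesign}
#' @param covariates covariate names; default: every clinical covariate
#' @return data.frame, one row per covariate: \code{covariate},
#'   \code{chi2}, \code{df}, \code{p}, \code{expected_min}, \code{n},
#'   \code{testable}
#' @export
clinicalAssociations <- function(design, covariates = NULL) {
  if (is.null(covariates)) covariates <- clinicalCovariates(design)
  rows <- lapply(covariates, function(cv) {
    base <- data.frame(covariate = cv, chi2 = NA_real_, df = NA_real_,
                       p = NA_real_, expected_min = NA_real_, n = NA_real_,
                       testable = FALSE, stringsAsFactors = FALSE)
    res <- tryCatch(chiSquareTest(crossTab(design, cv, "onset_group")),
                    error = function(e) NULL)
    if (!is.null(res)) {
      base[c("chi2", "df", "p", "expected_min", "n")] <-
        res[c("chi2", "df", "p", "expected_min", "n")]
      base$testable <- TRUE
    }
    base
  })
  do.call(rbind, rows)
}
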