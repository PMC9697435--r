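# Readers/writers for the plain-text formats the pipeline touches.
# Canonical dialect: TAB separated, no quoting, "NA" is the missing token.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = "NA", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read a sample sheet into a PairedDesign
#'
#' Expects a TSV with header and at least the columns \code{sample_id},
#' \code{person_id}, \code{tissue} (\code{tumor}/\code{normal}) and
#' \code{onset_group} (\code{EOCRC}/\code{LOCRC}). Unknown columns are
#' preserved as clinical covariates. Validation (duplicate samples, a
#' person with two tumors, inconsistent onset group) fails fast with the
#' offending row named. Persons lacking one tissue are loaded but reported
#' by [unpairedPersons()] and excluded later by the paired models.
#'
#' @param path path to the TSV sample sheet
#' @return a \linkS4class{PairedDesign}
#' @export
readSampleSheet <- function(path) {
  sh <- read_tsv_strict(path)
  req <- c("sample_id", "person_id", "tissue", "onset_group")
  miss <- setdiff(req, names(sh))
  if (length(miss))
    stop(sprintf("sample sheet '%s' lacks required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  PairedDesign(sh)
}

#' Read a feature-by-sample matrix into an OmicsMatrix
#'
#' First column is the feature id; remaining columns are samples. Missing
#' cells must be the literal token \code{NA} and are kept missing, never
#' zero-filled. Non-numeric cells and (for \code{methylation_beta}) beta
#' values outside [0, 1] are errors reported with their coordinates.
#'
#' @param path path to the TSV matrix
#' @param kind \code{"expression_log2"} or \code{"methylation_beta"}
#' @param annotation optional feature annotation data.frame passed to
#'   [OmicsMatrix()]
#' @return an \linkS4class{OmicsMatrix}
#' @export
readOmicsMatrix <- function(path, kind = c("expression_log2", "methylation_beta"),
                            annotation = NULL) {
  kind <- match.arg(kind)
  df <- read_tsv_strict(path)
  if (ncol(df) < 2)
    stop(sprintf("matrix '%s' needs a feature_id column plus >=1 sample", path))
  fid <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                     col[bad[1]], fid[bad[1]], names(vals)[j]))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- fid
  OmicsMatrix(m, kind = kind, annotation = annotation)
}

#' Write an OmicsMatrix to TSV
#'
#' Inverse of [readOmicsMatrix()]: feature_id first column, one column per
#' sample, \code{NA} for missing, full \code{\%.17g} precision so that a
#' write/read round trip reproduces values to the declared precision.
#'
#' @param x an \linkS4class{OmicsMatrix}
#' @param path output path
#' @export
writeOmicsMatrix <- function(x, path) {
  v <- omicsValues(x)
  df <- data.frame(feature_id = rownames(v), stringsAsFactors = FALSE)
  for (s in colnames(v)) df[[s]] <- format_num(v[, s])
  write_tsv_strict(df, path)
}

#' Read a CpG manifest / probe annotation table
#'
#' TSV with columns \code{feature_id}, \code{gene_symbol} and (for
#' methylation manifests) \code{region_class} in \{island, shore, shelf,
#' deep_sea, na\}. Gene symbols are uppercased so GMT sets match. The
#' \code{na} region class is only meaningful for expression features.
#'
#' @param path path to the TSV
#' @return data.frame with columns \code{feature_id}, \code{gene_symbol},
#'   \code{region_class}
#' @export
readFeatureAnnotation <- function(path) {
  df <- read_tsv_strict(path)
  if (!"feature_id" %in% names(df))
    stop(sprintf("annotation '%s' lacks a feature_id column", path))
  if (anyDuplicated(df$feature_id))
    stop(sprintf("duplicate feature_id '%s' in annotation",
                 df$feature_id[duplicated(df$feature_id)][1]))
  if (!"gene_symbol" %in% names(df)) df$gene_symbol <- ""
  df$gene_symbol <- toupper(ifelse(is.na(df$gene_symbol), "", df$gene_symbol))
  if (!"region_class" %in% names(df)) df$region_class <- "na"
  bad <- setdiff(unique(df$region_class), REGION_LEVELS)
  if (length(bad))
    stop(sprintf("unknown region_class '%s'", bad[1]))
  df
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, \code{set_name TAB description
#' TAB gene1 TAB gene2 ...}. Symbols are uppercased and de-duplicated
#' within a set; a line with fewer than three columns (i.e. no members) is
#' a format error.
#'
#' @param path path to the GMT file
#' @return a \linkS4class{GeneSetLibrary}
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop(sprintf("GMT line %d ('%s'): expected set_name, description, >=1 gene",
                   i, substr(lines[i], 1, 40)))
    sets[[f[1]]] <- f[-(1:2)]
  }
  GeneSetLibrary(sets)
}

#' Write a GeneSetLibrary to GMT
#' @param x a \linkS4class{GeneSetLibrary}
#' @param path output path
#' @param descriptions optional named character vector of set descriptions
#' @export
writeGeneSets <- function(x, path, descriptions = NULL) {
  s <- geneSets(x)
  desc <- if (is.null(descriptions)) rep("na", length(s)) else
    ifelse(names(s) %in% names(descriptions), descriptions[names(s)], "na")
  lines <- vapply(seq_along(s), function(i)
    paste(c(names(s)[i], desc[i], s[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

format_num <- function(x) {
  out <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  out
}

write_tsv_strict <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("cannot write '%s': no such directory", path))
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
}

#' Write a results table to TSV
#'
#' Serialises any list of homogeneous result records (or a data.frame) with
#' a stable column order. Numeric columns are written at full precision
#' (\code{\%.17g}, round-trip exact for doubles); each p-value
#' column additionally gets a \code{<name>_display} companion rounded to 3
#' decimals to mirror clinical-table style reporting.
#'
#' @param records data.frame or list of one-row data.frames sharing a schema
#' @param path output path
#' @param display_p names of p-value columns to add display companions for;
#'   default: every column named \code{p} or ending in \code{_p} or
#'   starting with \code{p_}
#' @export
writeResultsTable <- function(records, path, display_p = NULL) {
  if (is.data.frame(records)) df <- records
  else if (length(records) == 0) df <- data.frame()
  else df <- do.call(rbind, lapply(records, as.data.frame))
  if (is.null(display_p) && ncol(df))
    display_p <- grep("(^p$)|(_p$)|(^p_)|(^fdr)", names(df), value = TRUE)
  for (pc in intersect(display_p, names(df)))
    df[[paste0(pc, "_display")]] <- round(df[[pc]], 3)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) {
    if (grepl("_display$", names(df)[j])) next
    out[[j]] <- format_num(df[[j]])
  }
  write_tsv_strict(out, path)
}

#' Read back a results table written by writeResultsTable
#' @param path path to the TSV
#' @return data.frame with numeric columns restored
#' @export
readResultsTable <- function(path) {
  df <- read_tsv_strict(path)
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      num <- suppressWarnings(as.numeric(df[[j]]))
      if (!any(!is.na(df[[j]]) & is.na(num))) df[[j]] <- num
    }
  }
  df
}

# one line per pipeline stage: name, input shape, elapsed seconds
stage_log <- function(logfile, stage, shape, elapsed) {
  line <- sprintf("%s\tstage=%s\tshape=%s\telapsed=%.2fs",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, shape, elapsed)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}
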