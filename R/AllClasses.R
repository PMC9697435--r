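#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData rowData<- colData
NULL

TISSUE_LEVELS <- c("tumor", "normal")
ONSET_LEVELS  <- c("EOCRC", "LOCRC")
REGION_LEVELS <- c("island", "shore", "shelf", "deep_sea", "na")
MATRIX_KINDS  <- c("expression_log2", "methylation_beta")

#' Paired tumor-normal study design
#'
#' Holds the sample sheet of a paired tumor-normal study: one row per
#' sample, mapping each sample to a person, a tissue (tumor or adjacent
#' normal), an age-of-onset group (EOCRC, onset at or below 40 years;
#' LOCRC, onset above 40 years) and any clinical covariates (stage, LVI,
#' PNI, MSI status, ...). The validity method enforces the pairing
#' contract every downstream model relies on: unique sample ids, at most
#' one tumor and one normal sample per person, and a constant onset group
#' within a person.
#'
#' @slot sheet a \code{data.frame} with columns \code{sample_id},
#'   \code{person_id}, \code{tissue}, \code{onset_group}; any further
#'   columns are treated as clinical covariates.
#'
#' @seealso [readSampleSheet()], [completePairs()]
#' @export
setClass("PairedDesign", representation(sheet = "data.frame"))

setValidity("PairedDesign", function(object) {
  sh <- object@sheet
  req <- c("sample_id", "person_id", "tissue", "onset_group")
  miss <- setdiff(req, names(sh))
  if (length(miss))
    return(paste("missing required columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(sh$sample_id)) {
    d <- sh$sample_id[duplicated(sh$sample_id)][1]
    return(paste0("duplicate sample_id '", d, "'"))
  }
  bad <- setdiff(unique(sh$tissue), TISSUE_LEVELS)
  if (length(bad))
    return(paste0("tissue must be one of {tumor, normal}; found '", bad[1], "'"))
  bad <- setdiff(unique(sh$onset_group), ONSET_LEVELS)
  if (length(bad))
    return(paste0("onset_group must be one of {EOCRC, LOCRC}; found '", bad[1], "'"))
  tab <- table(sh$person_id, sh$tissue)
  if (any(tab > 1)) {
    w <- which(tab > 1, arr.ind = TRUE)[1, ]
    return(paste0("person '", rownames(tab)[w[1]], "' has more than one ",
                  colnames(tab)[w[2]], " sample"))
  }
  og <- tapply(sh$onset_group, sh$person_id, function(x) length(unique(x)))
  if (any(og > 1))
    return(paste0("person '", names(og)[og > 1][1],
                  "' appears in more than one onset group"))
  TRUE
})

#' Construct a PairedDesign from a sample sheet data.frame
#'
#' @param sheet data.frame with columns \code{sample_id}, \code{person_id},
#'   \code{tissue} (\code{tumor}/\code{normal}), \code{onset_group}
#'   (\code{EOCRC}/\code{LOCRC}) plus optional clinical covariates.
#' @return a validated \linkS4class{PairedDesign}
#' @examples
#' pd <- PairedDesign(data.frame(
#'   sample_id = c("p1T", "p1N"), person_id = "p1",
#'   tissue = c("tumor", "normal"), onset_group = "EOCRC"))
#' completePairs(pd)
#' @export
PairedDesign <- function(sheet) {
  sheet <- as.data.frame(sheet, stringsAsFactors = FALSE)
  for (col in intersect(c("sample_id", "person_id", "tissue", "onset_group"),
                        names(sheet)))
    sheet[[col]] <- as.character(sheet[[col]])
  rownames(sheet) <- NULL
  new("PairedDesign", sheet = sheet)
}

#' Feature-by-sample omics matrix
#'
#' A thin extension of \linkS4class{SummarizedExperiment} carrying one
#' assay (\code{"values"}): log2 expression intensities or methylation
#' beta values in [0, 1]. Feature annotation (gene symbol, CpG region
#' class) lives in \code{rowData}. The validity method rejects duplicate
#' feature ids and out-of-range beta values.
#'
#' @slot kind \code{"expression_log2"} or \code{"methylation_beta"}
#' @seealso [OmicsMatrix()], [omicsKind()], [featureAnnotation()]
#' @export
setClass("OmicsMatrix", contains = "SummarizedExperiment",
         representation(kind = "character"))

setValidity("OmicsMatrix", function(object) {
  if (length(object@kind) != 1L || !object@kind %in% MATRIX_KINDS)
    return(paste("kind must be one of:", paste(MATRIX_KINDS, collapse = ", ")))
  if (is.null(rownames(object)))
    return("feature ids (rownames) are required")
  if (anyDuplicated(rownames(object)))
    return(paste0("duplicate feature_id '",
                  rownames(object)[duplicated(rownames(object))][1], "'"))
  v <- assay(object, "values")
  if (object@kind == "methylation_beta") {
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(v))
      return(sprintf("beta value %g outside [0,1] at feature '%s', sample '%s'",
                     v[bad[1]], rownames(v)[rc[1]], colnames(v)[rc[2]]))
    }
  }
  TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids); missing cells as NA.
#' @param kind \code{"expression_log2"} or \code{"methylation_beta"}.
#' @param annotation optional data.frame of per-feature annotation with a
#'   \code{feature_id} column (plus e.g. \code{gene_symbol},
#'   \code{region_class}); matched to rows by \code{feature_id}.
#' @return an \linkS4class{OmicsMatrix}
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' om <- OmicsMatrix(m, "methylation_beta")
#' omicsKind(om)
#' @export
OmicsMatrix <- function(values, kind = c("expression_log2", "methylation_beta"),
                        annotation = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rd <- NULL
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
    if (!"feature_id" %in% names(annotation))
      stop("annotation must have a 'feature_id' column")
    idx <- match(rownames(values), annotation$feature_id)
    if (anyNA(idx))
      stop(sprintf("feature '%s' missing from annotation",
                   rownames(values)[which(is.na(idx))[1]]))
    rd <- DataFrame(annotation[idx, setdiff(names(annotation), "feature_id"),
                               drop = FALSE])
    rownames(rd) <- rownames(values)
  }
  se <- SummarizedExperiment(assays = list(values = values))
  if (!is.null(rd)) rowData(se) <- rd
  new("OmicsMatrix", se, kind = kind)
}

#' Collection of named gene sets
#'
#' Wraps the named-list representation of a GMT file. Gene symbols are
#' stored uppercased and de-duplicated; empty sets are invalid.
#'
#' @slot sets named list of character vectors of gene symbols
#' @seealso [readGeneSets()], [geneSets()]
#' @export
setClass("GeneSetLibrary", representation(sets = "list"))

setValidity("GeneSetLibrary", function(object) {
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      return("every gene set must be named")
    if (anyDuplicated(names(s)))
      return(paste0("duplicate set name '", names(s)[duplicated(names(s))][1], "'"))
    n <- lengths(s)
    if (any(n == 0))
      return(paste0("gene set '", names(s)[n == 0][1], "' is empty"))
  }
  TRUE
})

#' Construct a GeneSetLibrary from a named list
#' @param sets named list of character vectors of gene symbols; symbols are
#'   uppercased and de-duplicated per set.
#' @return a \code{GeneSetLibrary}
#' @export
GeneSetLibrary <- function(sets) {
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  new("GeneSetLibrary", sets = sets)
}

#' @describeIn GeneSetLibrary-class the named list of member symbols
#' @param x a \code{GeneSetLibrary}
#' @export
geneSets <- function(x) x@sets

setMethod("length", "GeneSetLibrary", function(x) length(x@sets))

setMethod("show", "GeneSetLibrary", function(object) {
  cat("GeneSetLibrary with", length(object@sets), "set(s)\n")
  n <- head(names(object@sets), 5)
  for (nm in n)
    cat("  ", nm, ": ", length(object@sets[[nm]]), " genes\n", sep = "")
  if (length(object@sets) > 5) cat("  ...\n")
})

# ---- accessors ----

#' Sample sheet of a PairedDesign
#' @param x a \linkS4class{PairedDesign}
#' @return data.frame, one row per sample
#' @export
designSheet <- function(x) x@sheet

#' Clinical covariate columns of a PairedDesign
#' @param x a \linkS4class{PairedDesign}
#' @return character vector of covariate column names
#' @export
clinicalCovariates <- function(x)
  setdiff(names(x@sheet), c("sample_id", "person_id", "tissue", "onset_group"))

#' Persons with both a tumor and a normal sample
#'
#' @param x a \linkS4class{PairedDesign}
#' @param onset optional onset group (\code{"EOCRC"} or \code{"LOCRC"}) to
#'   restrict to
#' @return data.frame with columns \code{person_id}, \code{onset_group},
#'   \code{tumor} and \code{normal} (the two sample ids), one row per
#'   complete pair
#' @export
completePairs <- function(x, onset = NULL) {
  sh <- x@sheet
  if (!is.null(onset)) sh <- sh[sh$onset_group %in% onset, , drop = FALSE]
  tum <- sh[sh$tissue == "tumor", c("person_id", "onset_group", "sample_id")]
  nor <- sh[sh$tissue == "normal", c("person_id", "sample_id")]
  m <- merge(tum, nor, by = "person_id", suffixes = c("_t", "_n"))
  out <- data.frame(person_id = m$person_id, onset_group = m$onset_group,
                    tumor = m$sample_id_t, normal = m$sample_id_n,
                    stringsAsFactors = FALSE)
  out[order(out$person_id), , drop = FALSE]
}

#' Persons lacking either the tumor or the normal sample
#' @param x a \linkS4class{PairedDesign}
#' @return character vector of unpaired person ids
#' @export
unpairedPersons <- function(x) {
  tab <- table(x@sheet$person_id, factor(x@sheet$tissue, TISSUE_LEVELS))
  rownames(tab)[rowSums(tab > 0) < 2]
}

setMethod("show", "PairedDesign", function(object) {
  sh <- object@sheet
  np <- length(unique(sh$person_id))
  cp <- completePairs(object)
  cat("PairedDesign:", nrow(sh), "samples,", np, "persons,",
      nrow(cp), "complete pairs\n")
  og <- table(sh[!duplicated(sh$person_id), "onset_group"])
  cat("  onset groups:",
      paste(names(og), as.integer(og), sep = "=", collapse = ", "), "\n")
  cc <- clinicalCovariates(object)
  if (length(cc)) cat("  clinical covariates:", paste(cc, collapse = ", "), "\n")
})

#' Matrix kind of an OmicsMatrix
#' @param x an \linkS4class{OmicsMatrix}
#' @return \code{"expression_log2"} or \code{"methylation_beta"}
#' @export
omicsKind <- function(x) x@kind

#' Feature annotation of an OmicsMatrix as a data.frame
#' @param x an \linkS4class{OmicsMatrix}
#' @return data.frame with a \code{feature_id} column plus any annotation
#'   columns stored in \code{rowData}
#' @export
featureAnnotation <- function(x) {
  rd <- as.data.frame(rowData(x))
  cbind(data.frame(feature_id = rownames(x), stringsAsFactors = FALSE), rd)
}

#' Assay values of an OmicsMatrix
#' @param x an \linkS4class{OmicsMatrix}
#' @return the numeric feature-by-sample matrix
#' @export
omicsValues <- function(x) assay(x, "values")

setMethod("show", "OmicsMatrix", function(object) {
  cat("OmicsMatrix [", object@kind, "]: ", nrow(object), " features x ",
      ncol(object), " samples\n", sep = "")
  callNextMethod()
})

# Align matrix columns to the design; every design sample must be present.
# Extra matrix columns are dropped with a message.
alignToDesign <- function(om, design) {
  sh <- designSheet(design)
  miss <- setdiff(sh$sample_id, colnames(om))
  if (length(miss))
    stop(sprintf("sample '%s' in the design is missing from the matrix", miss[1]))
  om[, sh$sample_id]
}
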