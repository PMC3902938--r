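#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", U = "U",
  R = "AG", Y = "CU", S = "CG", W = "AU", K = "GU", M = "AC",
  B = "CGU", D = "AGU", H = "ACU", V = "ACG", N = "ACGU"
)

#' PolysomeSet: log2 intensities across condition x fraction x replicate
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `log2intensity` assay (genes x arrays) whose `colData` carries the
#' factors `condition` (control/stress), `fraction` (total/monosome/polysome)
#' and `replicate`.
#'
#' @slot incomplete character vector of gene ids lacking at least one
#'   required (condition, fraction) cell.
#' @export
setClass("PolysomeSet",
  contains = "SummarizedExperiment",
  slots = c(incomplete = "character")
)

setValidity("PolysomeSet", function(object) {
  cd <- colData(object)
  need <- c("condition", "fraction", "replicate")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (!all(cd$condition %in% c("control", "stress")))
    return("condition must be 'control' or 'stress'")
  if (!all(cd$fraction %in% c("total", "monosome", "polysome")))
    return("fraction must be one of total/monosome/polysome")
  if (!"log2intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'log2intensity' is required")
  a <- assay(object, "log2intensity")
  if (any(!is.finite(a[!is.na(a)])))
    return("log2 intensities must be finite where present")
  key <- paste(cd$condition, cd$fraction, cd$replicate)
  if (anyDuplicated(key))
    return("duplicated (condition, fraction, replicate) column")
  TRUE
})

#' Construct a PolysomeSet
#'
#' @param log2intensity numeric matrix, genes x arrays, with rownames.
#' @param condition,fraction,replicate per-column design factors.
#' @return A [PolysomeSet-class] object. Genes with any missing
#'   (condition, fraction) cell are recorded in `incompleteGenes()`.
#' @export
PolysomeSet <- function(log2intensity, condition, fraction, replicate) {
  cd <- DataFrame(condition = as.character(condition),
                  fraction = as.character(fraction),
                  replicate = as.integer(replicate))
  se <- SummarizedExperiment(assays = list(log2intensity = log2intensity),
                             colData = cd)
  ps <- new("PolysomeSet", se, incomplete = character(0))
  ps@incomplete <- .findIncomplete(ps)
  validObject(ps)
  ps
}

.findIncomplete <- function(ps) {
  a <- assay(ps, "log2intensity")
  cd <- colData(ps)
  cells <- expand.grid(condition = c("control", "stress"),
                       fraction = c("total", "monosome", "polysome"),
                       stringsAsFactors = FALSE)
  bad <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(cells))) {
    sel <- cd$condition == cells$condition[i] & cd$fraction == cells$fraction[i]
    if (!any(sel)) { bad <- bad | TRUE; next }
    bad <- bad | apply(is.na(a[, sel, drop = FALSE]), 1L, all)
  }
  rownames(a)[bad]
}

#' @describeIn PolysomeSet-class gene ids flagged incomplete on construction
#' @param x a `PolysomeSet`
#' @export
incompleteGenes <- function(x) x@incomplete

setMethod("show", "PolysomeSet", function(object) {
  cat("PolysomeSet:", nrow(object), "genes x", ncol(object), "arrays\n")
  cd <- colData(object)
  cat("  conditions:", paste(unique(cd$condition), collapse = ", "), "\n")
  cat("  fractions: ", paste(unique(cd$fraction), collapse = ", "), "\n")
  cat("  incomplete genes:", length(object@incomplete), "\n")
})

#' TranscriptSet: mRNAs partitioned into 5'UTR / ORF / 3'UTR
#'
#' Holds one [Biostrings::RNAStringSet] per region, all indexed by the same
#' transcript ids in the same order. ORFs start with AUG, end with a stop
#' codon, and have length divisible by 3 (enforced at assembly).
#'
#' @slot utr5,orf,utr3 RNAStringSet, parallel over transcripts.
#' @export
setClass("TranscriptSet",
  slots = c(utr5 = "RNAStringSet", orf = "RNAStringSet", utr3 = "RNAStringSet")
)

setValidity("TranscriptSet", function(object) {
  n5 <- names(object@utr5); no <- names(object@orf); n3 <- names(object@utr3)
  if (is.null(no) || anyDuplicated(no)) return("orf names must be unique")
  if (!identical(n5, no) || !identical(n3, no))
    return("utr5/orf/utr3 must share identical names and order")
  if (any(Biostrings::width(object@orf) %% 3L != 0L))
    return("ORF lengths must be divisible by 3")
  TRUE
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet:", length(object@orf), "transcripts\n")
  cat("  median widths (nt): 5'UTR",
      stats::median(Biostrings::width(object@utr5)), "| ORF",
      stats::median(Biostrings::width(object@orf)), "| 3'UTR",
      stats::median(Biostrings::width(object@utr3)), "\n")
})

#' @describeIn TranscriptSet-class number of transcripts
#' @param x a `TranscriptSet`
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@orf))

#' @describeIn TranscriptSet-class transcript identifiers
#' @export
setMethod("names", "TranscriptSet", function(x) names(x@orf))

#' Extract one region of a TranscriptSet
#' @param x a `TranscriptSet`
#' @param region one of `"utr5"`, `"orf"`, `"utr3"`
#' @return an `RNAStringSet`
#' @export
transcriptRegion <- function(x, region = c("utr5", "orf", "utr3")) {
  region <- match.arg(region)
  slot(x, region)
}

#' MotifModel: an RNA-binding-protein binding-site model
#'
#' Either an IUPAC consensus or a position weight matrix (4 x L, columns
#' summing to 1), with a target region and a scoring mode.
#'
#' @slot name motif name (e.g. `"Puf3_3utr"`).
#' @slot consensus IUPAC consensus string, or `NA_character_` when a PWM
#'   is supplied.
#' @slot pwm 4 x L probability matrix (rows A, C, G, U) or a 0 x 0 matrix.
#' @slot region one of utr5/orf/utr3/any.
#' @slot scoring `"count"` (number of matching windows) or
#'   `"max_log_odds"` (best window log2 likelihood ratio vs uniform).
#' @export
setClass("MotifModel",
  slots = c(name = "character", consensus = "character", pwm = "matrix",
            region = "character", scoring = "character")
)

setValidity("MotifModel", function(object) {
  if (!nzchar(object@name)) return("name must be non-empty")
  if (!object@region %in% c("utr5", "orf", "utr3", "any"))
    return("region must be utr5/orf/utr3/any")
  if (!object@scoring %in% c("count", "max_log_odds"))
    return("scoring must be count or max_log_odds")
  has_pwm <- length(object@pwm) > 0L
  if (!has_pwm) {
    if (is.na(object@consensus)) return("need a consensus or a PWM")
    if (nchar(object@consensus) < 4L) return("motif length must be >= 4")
    bad <- setdiff(strsplit(object@consensus, "")[[1]], names(IUPAC_CODES))
    if (length(bad)) return(paste("non-IUPAC code:", bad[1]))
  } else {
    if (nrow(object@pwm) != 4L) return("PWM must have 4 rows (A,C,G,U)")
    if (ncol(object@pwm) < 4L) return("motif length must be >= 4")
    cs <- colSums(object@pwm)
    if (any(abs(cs - 1) > 1e-9)) return("PWM columns must sum to 1 (+/- 1e-9)")
  }
  TRUE
})

#' Construct a MotifModel
#' @param name motif name
#' @param consensus IUPAC consensus (ignored when `pwm` given)
#' @param pwm optional 4 x L probability matrix, rows A,C,G,U
#' @param region target region
#' @param scoring scoring mode
#' @export
MotifModel <- function(name, consensus = NA_character_, pwm = NULL,
                       region = c("utr3", "utr5", "orf", "any"),
                       scoring = c("count", "max_log_odds")) {
  region <- match.arg(region)
  scoring <- match.arg(scoring)
  if (is.null(pwm)) pwm <- matrix(numeric(0), 0, 0)
  if (!is.na(consensus)) consensus <- toupper(gsub("T", "U", consensus))
  new("MotifModel", name = name, consensus = consensus, pwm = pwm,
      region = region, scoring = scoring)
}

setMethod("show", "MotifModel", function(object) {
  rep <- if (length(object@pwm)) sprintf("PWM[4x%d]", ncol(object@pwm))
         else object@consensus
  cat(sprintf("MotifModel %s: %s @ %s (%s)\n",
              object@name, rep, object@region, object@scoring))
})

#' @describeIn MotifModel-class motif width in nt
#' @param x a `MotifModel`
#' @export
motifWidth <- function(x) {
  if (length(x@pwm)) ncol(x@pwm) else nchar(x@consensus)
}

#' GeneSets: a named collection of gene sets over a universe
#'
#' @slot sets named list of character vectors.
#' @slot universe character vector; when non-empty every member must belong.
#' @export
setClass("GeneSets", slots = c(sets = "list", universe = "character"))

setValidity("GeneSets", function(object) {
  if (anyDuplicated(names(object@sets))) return("set names must be unique")
  if (length(object@sets) && is.null(names(object@sets)))
    return("sets must be named")
  if (length(object@universe)) {
    out <- vapply(object@sets, function(s) any(!s %in% object@universe), logical(1))
    if (any(out)) return(paste("set outside universe:", names(object@sets)[out][1]))
  }
  TRUE
})

#' Construct a GeneSets collection
#' @param sets named list of character vectors
#' @param universe optional universe of gene ids
#' @export
GeneSets <- function(sets, universe = character(0)) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  new("GeneSets", sets = sets, universe = as.character(universe))
}

setMethod("show", "GeneSets", function(object) {
  cat("GeneSets:", length(object@sets), "sets; universe",
      if (length(object@universe)) length(object@universe) else "undeclared", "\n")
})

#' @describeIn GeneSets-class number of sets
#' @param x a `GeneSets`
#' @export
setMethod("length", "GeneSets", function(x) length(x@sets))

#' @describeIn GeneSets-class set names
#' @export
setMethod("names", "GeneSets", function(x) names(x@sets))

#' @describeIn GeneSets-class extract one member set
#' @param i set name or index
#' @export
setMethod("[[", "GeneSets", function(x, i) x@sets[[i]])

#' @describeIn GeneSets-class declared (or inferred) universe
#' @export
geneUniverse <- function(x) {
  if (length(x@universe)) x@universe else unique(unlist(x@sets, use.names = FALSE))
}

#' FeatureSchema: the ordered feature definition of a FeatureMatrix
#'
#' @slot entries data.frame with columns name, op, region, param.
#' @slot version schema version tag.
#' @export
setClass("FeatureSchema",
  slots = c(entries = "data.frame", version = "character"))

setValidity("FeatureSchema", function(object) {
  need <- c("name", "op", "region", "param")
  if (!all(need %in% colnames(object@entries)))
    return("entries needs columns name, op, region, param")
  if (anyDuplicated(object@entries$name)) return("feature names must be unique")
  TRUE
})

setMethod("show", "FeatureSchema", function(object) {
  cat("FeatureSchema", object@version, "-", nrow(object@entries), "features\n")
  print(table(object@entries$op))
})

#' @describeIn FeatureSchema-class number of features
#' @param x a `FeatureSchema`
#' @export
setMethod("length", "FeatureSchema", function(x) nrow(x@entries))

#' @describeIn FeatureSchema-class feature names in schema order
#' @export
featureNames <- function(x) x@entries$name

#' FeatureMatrix: gene x feature values under a declared schema
#'
#' @slot values numeric matrix, genes x features, no NA after imputation.
#' @slot imputed logical matrix marking cells filled by median imputation.
#' @slot schema the [FeatureSchema-class] that produced the columns.
#' @export
setClass("FeatureMatrix",
  slots = c(values = "matrix", imputed = "matrix", schema = "FeatureSchema"))

setValidity("FeatureMatrix", function(object) {
  if (!identical(colnames(object@values), object@schema@entries$name))
    return("column order must match schema order")
  if (anyNA(object@values)) return("values must contain no NA after imputation")
  TRUE
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "features (schema", object@schema@version, ")\n")
  cat("  imputed cells:", sum(object@imputed), "\n")
})

#' @describeIn FeatureMatrix-class the numeric gene x feature matrix
#' @param x a `FeatureMatrix`
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureMatrix-class the schema behind the columns
#' @export
featureSchema <- function(x) x@schema
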