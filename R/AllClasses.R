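#' SmallRNAPool: collapsed multi-dataset small RNA pool
#'
#' A \linkS4class{SummarizedExperiment} whose rows are unique read sequences
#' and whose columns are datasets. The single assay \code{"counts"} holds the
#' per-dataset copy number of each sequence; \code{rowData} carries the
#' prevalence (number of datasets in which the sequence was observed) and
#' \code{colData} the post-preprocessing dataset totals.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("SmallRNAPool", contains = "SummarizedExperiment")

setValidity("SmallRNAPool", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (!"prevalence" %in% colnames(SummarizedExperiment::rowData(object)))
      msg <- c(msg, "rowData column 'prevalence' is required")
    else {
      prev <- SummarizedExperiment::rowData(object)$prevalence
      obs <- as.integer(rowSums(cnt > 0))
      if (!isTRUE(all(prev == obs)))
        msg <- c(msg, "prevalence must equal the number of datasets with count > 0")
      if (nrow(object) > 0L && any(prev < 1L))
        msg <- c(msg, "every retained sequence must occur in at least one dataset")
    }
    if (is.null(rownames(object)) && nrow(object) > 0L)
      msg <- c(msg, "rownames (the sequences) are required")
  }
  if (length(msg)) msg else TRUE
})

#' SecondaryStructure: a folded RNA secondary structure
#'
#' Minimum-energy non-crossing structure of a single sequence under the
#' package's simplified nearest-neighbour model. \code{pairMap[i]} gives the
#' 1-based partner of position i, or NA when unpaired. \code{bifurcated}
#' reports whether the unconstrained optimum contains two or more disjoint
#' stem-loops.
#'
#' @slot sequence character. Folded sequence (as supplied).
#' @slot dotBracket character. Vienna dot-bracket string.
#' @slot energy numeric. Energy in kcal/mol (<= 0).
#' @slot pairMap integer. Partner positions, NA when unpaired.
#' @slot bifurcated logical. TRUE when the unconstrained minimum-energy
#'   structure has more than one terminal loop.
#' @slot unconstrainedEnergy numeric. Energy of the unconstrained optimum.
#' @export
setClass("SecondaryStructure", representation(
  sequence = "character",
  dotBracket = "character",
  energy = "numeric",
  pairMap = "integer",
  bifurcated = "logical",
  unconstrainedEnergy = "numeric"
))

setValidity("SecondaryStructure", function(object) {
  db <- strsplit(object@dotBracket, "")[[1]]
  msg <- character()
  if (nchar(object@dotBracket) != length(object@pairMap))
    msg <- c(msg, "dotBracket and pairMap lengths differ")
  depth <- cumsum((db == "(") - (db == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0))
    msg <- c(msg, "dot-bracket string is unbalanced")
  pm <- object@pairMap
  paired <- which(!is.na(pm))
  if (any(pm[paired] < 1 | pm[paired] > length(pm)) ||
      !all(pm[pm[paired]] == paired))
    msg <- c(msg, "pairMap is not an involution")
  if (length(msg)) msg else TRUE
})

#' DuplexHybrid: an intermolecular miRNA:site duplex
#'
#' Result of hybridising a miRNA against a target site with intramolecular
#' pairing forbidden.
#'
#' @slot mirna character. The miRNA strand.
#' @slot site character. The target site strand.
#' @slot energy numeric. Duplex energy in kcal/mol; 0 when no pair forms.
#' @slot mirnaPaired logical. Per-position pairing flags on the miRNA.
#' @slot mirnaWatsonCrick logical. TRUE where the pair is Watson-Crick
#'   (i.e. not a GU wobble).
#' @slot sitePartner integer. 1-based partner position on the site, NA when
#'   the miRNA position is unpaired.
#' @export
setClass("DuplexHybrid", representation(
  mirna = "character",
  site = "character",
  energy = "numeric",
  mirnaPaired = "logical",
  mirnaWatsonCrick = "logical",
  sitePartner = "integer"
))

setValidity("DuplexHybrid", function(object) {
  msg <- character()
  if (length(object@mirnaPaired) != nchar(object@mirna))
    msg <- c(msg, "mirnaPaired length must equal miRNA length")
  if (object@energy > 0)
    msg <- c(msg, "duplex energy cannot be positive")
  if (!any(object@mirnaPaired) && object@energy != 0)
    msg <- c(msg, "energy must be 0 when no position pairs")
  if (length(msg)) msg else TRUE
})

# ---- generics ---------------------------------------------------------------

#' @rdname SmallRNAPool-class
#' @param x,object a \code{SmallRNAPool}
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))

#' @rdname SmallRNAPool-class
#' @export
setGeneric("poolSequences", function(x) standardGeneric("poolSequences"))

#' @rdname SmallRNAPool-class
#' @export
setGeneric("datasetTotals", function(x) standardGeneric("datasetTotals"))

#' @rdname SecondaryStructure-class
#' @param x,object a \code{SecondaryStructure} or \code{DuplexHybrid}
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("foldEnergy", function(x) standardGeneric("foldEnergy"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("pairMap", function(x) standardGeneric("pairMap"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("isBifurcated", function(x) standardGeneric("isBifurcated"))

# ---- methods ----------------------------------------------------------------

#' @rdname SmallRNAPool-class
#' @export
setMethod("prevalence", "SmallRNAPool", function(x)
  SummarizedExperiment::rowData(x)$prevalence)

#' @rdname SmallRNAPool-class
#' @export
setMethod("poolSequences", "SmallRNAPool", function(x) rownames(x))

#' @rdname SmallRNAPool-class
#' @export
setMethod("datasetTotals", "SmallRNAPool", function(x)
  setNames(SummarizedExperiment::colData(x)$total_reads, colnames(x)))

#' @rdname SecondaryStructure-class
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) x@dotBracket)

#' @rdname SecondaryStructure-class
#' @export
setMethod("foldEnergy", "SecondaryStructure", function(x) x@energy)

#' @rdname SecondaryStructure-class
#' @export
setMethod("foldEnergy", "DuplexHybrid", function(x) x@energy)

#' @rdname SecondaryStructure-class
#' @export
setMethod("pairMap", "SecondaryStructure", function(x) x@pairMap)

#' @rdname SecondaryStructure-class
#' @export
setMethod("isBifurcated", "SecondaryStructure", function(x) x@bifurcated)

setMethod("show", "SmallRNAPool", function(object) {
  cat("SmallRNAPool with", nrow(object), "unique sequences across",
      ncol(object), "datasets\n")
  if (nrow(object) > 0) {
    prev <- prevalence(object)
    cat("  prevalence: min", min(prev), "/ median", stats::median(prev),
        "/ max", max(prev), "\n")
  }
  cat("  total reads:", sum(SummarizedExperiment::assay(object, "counts")), "\n")
})

setMethod("show", "SecondaryStructure", function(object) {
  cat("SecondaryStructure (", nchar(object@sequence), " nt, ",
      sprintf("%.1f", object@energy), " kcal/mol",
      if (object@bifurcated) ", bifurcated" else "", ")\n", sep = "")
  cat(" ", object@sequence, "\n ", object@dotBracket, "\n")
})

setMethod("show", "DuplexHybrid", function(object) {
  cat("DuplexHybrid (", sprintf("%.1f", object@energy), " kcal/mol, ",
      sum(object@mirnaPaired), "/", nchar(object@mirna),
      " miRNA positions paired)\n", sep = "")
})
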