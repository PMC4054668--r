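#' Evaluate a candidate homolog of a human miRNA hairpin
#'
#' A gap-stripped aligned sequence is called a genuine homologous miRNA
#' hairpin when it folds into a single (no-bifurcation) hairpin with at
#' least \code{minPairs} base pairs between the two strands and a fold
#' energy of \code{maxEnergy} kcal/mol or lower, and at least one of the
#' human seed sequences (positions 2-8 of either strand) occurs in it as an
#' exact substring (T and U treated as equivalent).
#'
#' @param candidateSeq gap-stripped candidate sequence.
#' @param humanSeeds character vector of human 7-nt seeds (both strands).
#' @param minPairs minimum base pairs in the stem (default 14).
#' @param maxEnergy maximum fold energy (default -14 kcal/mol).
#' @return list with \code{present} (logical) and the individual criteria.
#' @export
evaluateHomolog <- function(candidateSeq, humanSeeds, minPairs = 14L,
                            maxEnergy = -14) {
  toU <- function(x) chartr("Tt", "Uu", toupper(x))
  str <- foldHairpin(candidateSeq, TRUE, reportUnconstrained = FALSE)
  nPairs <- sum(!is.na(pairMap(str))) %/% 2L
  seedHit <- any(vapply(humanSeeds, function(s)
    grepl(toU(s), toU(candidateSeq), fixed = TRUE), logical(1)))
  structureOK <- nPairs >= minPairs && foldEnergy(str) <= maxEnergy
  list(present = structureOK && seedHit,
       n_pairs = nPairs, energy = foldEnergy(str), seed_found = seedHit)
}

#' Assign the evolutionary origin of a miRNA by parsimony
#'
#' Over the branch points on the human lineage, chooses the one that
#' minimises one gain at that branch plus the losses needed to explain
#' absences among its non-missing descendants (no regain within the clade);
#' species that are present outside the candidate clade are charged one
#' independent gain each. Ties are broken toward the more recent branch
#' point. Species missing from the alignment are excluded from loss
#' counting.
#'
#' @param presence named logical vector over the tree's leaves: TRUE
#'   (homolog present), FALSE (absent), NA (species missing from the
#'   alignment). The human leaf is treated as present.
#' @param tree a rooted \code{phylo} (ape) with leaf labels and, ideally,
#'   internal node labels naming the clades.
#' @param humanLeaf name of the human leaf (default \code{"human"}).
#' @return list with \code{node} (internal ape node number, or the leaf),
#'   \code{label} (clade label; the human leaf label when human-specific)
#'   and \code{cost}.
#' @export
assignOrigin <- function(presence, tree, humanLeaf = "human") {
  stopifnot(inherits(tree, "phylo"), humanLeaf %in% tree$tip.label)
  ntip <- length(tree$tip.label)
  pres <- presence[tree$tip.label]
  names(pres) <- tree$tip.label
  pres[humanLeaf] <- TRUE

  children <- split(tree$edge[, 2], tree$edge[, 1])
  humanTip <- match(humanLeaf, tree$tip.label)
  # path from human to root (most recent first)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- humanTip
  node <- humanTip
  root <- ntip + 1L
  while (node != root) { node <- parent[node]; path <- c(path, node) }

  tipState <- function(tip) pres[[tree$tip.label[tip]]]
  # post-order Dollo loss count below `node`, given presence at `node`:
  # returns c(losses, hasData, anyPresent)
  lossRec <- function(node) {
    if (node <= ntip) {
      st <- tipState(node)
      if (is.na(st)) return(c(losses = 0, hasData = 0, anyPresent = 0))
      return(c(losses = 0, hasData = 1, anyPresent = as.numeric(st)))
    }
    kids <- lapply(children[[as.character(node)]], lossRec)
    perKid <- vapply(kids, function(k) {
      if (k[["hasData"]] == 0) 0          # no information: no event charged
      else if (k[["anyPresent"]] == 0) 1  # whole child subtree lost: one event
      else k[["losses"]]                  # presence persists: recurse
    }, numeric(1))
    c(losses = sum(perKid),
      hasData = as.numeric(any(vapply(kids, `[[`, numeric(1), "hasData") > 0)),
      anyPresent = as.numeric(any(vapply(kids, `[[`, numeric(1), "anyPresent") > 0)))
  }
  cladeTips <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(children[[as.character(node)]], cladeTips))
  }

  presentTips <- which(!is.na(pres) & pres)
  best <- NULL
  for (node in path) {
    inClade <- cladeTips(node)
    losses <- if (node <= ntip) 0 else lossRec(node)[["losses"]]
    outside <- setdiff(presentTips, inClade)
    cost <- 1 + losses + length(outside)
    if (is.null(best) || cost < best$cost) {
      lab <- if (node <= ntip) tree$tip.label[node]
      else if (!is.null(tree$node.label) &&
               nzchar(tree$node.label[node - ntip])) tree$node.label[node - ntip]
      else paste0("node", node)
      best <- list(node = node, label = lab, cost = cost)
    }
  }
  best
}

#' The default annotation confidence hierarchy
#'
#' Highest-confidence class first: mitochondrion, snoRNA, rRNA, tRNA,
#' miscellaneous RNA (incl. snRNA), long non-coding RNA, pseudogene,
#' protein_coding, repeat, intergenic.
#'
#' @return ordered character vector of class names.
#' @export
annotationHierarchy <- function() {
  c("mitochondrion", "snoRNA", "rRNA", "tRNA", "misc_RNA", "lncRNA",
    "pseudogene", "protein_coding", "repeat", "intergenic")
}

#' Resolve annotation class per position
#'
#' Assigns every queried (position, strand) exactly one class: the
#' highest-ranked class in the floating hierarchy whose intervals cover it,
#' else \code{"intergenic"}.
#'
#' @param positions \code{GRanges} of queried positions (typically width 1).
#' @param tracks named list of \code{GRanges}, one per annotation class;
#'   names must appear in the hierarchy.
#' @param hierarchy ordered class vector (default
#'   \code{\link{annotationHierarchy}}).
#' @return character vector of class labels, one per queried position.
#' @export
resolveAnnotation <- function(positions, tracks,
                              hierarchy = annotationHierarchy()) {
  unknown <- setdiff(names(tracks), hierarchy)
  if (length(unknown))
    stop("unknown annotation class(es): ", paste(unknown, collapse = ", "))
  labels <- rep("intergenic", length(positions))
  assigned <- logical(length(positions))
  for (cls in hierarchy) {
    if (!cls %in% names(tracks)) next
    ov <- suppressWarnings(GenomicRanges::findOverlaps(
      positions, tracks[[cls]], ignore.strand = FALSE))
    hit <- unique(S4Vectors::queryHits(ov))
    hit <- hit[!assigned[hit]]
    labels[hit] <- cls
    assigned[hit] <- TRUE
  }
  labels
}

#' Attribute hairpins to genomic source classes
#'
#' Each genome mapping contributes weight 1 / n_mappings to the class of
#' the nucleotide at its center (center = floor((start + end - 1) / 2) in
#' 0-based half-open coordinates, on the mapped strand). With gene and exon
#' tracks supplied, protein_coding is subdivided into
#' \code{protein_coding_exon} and \code{protein_coding_intron} (a position
#' inside a gene but not an exon is intronic).
#'
#' @param mappings \code{GRanges} with an \code{n_mappings} metadata column.
#' @param tracks named list of class \code{GRanges}.
#' @param hierarchy ordered class vector.
#' @param exons optional \code{GRanges} of exons used to subdivide
#'   protein_coding.
#' @return named numeric vector of per-class weighted fractions (sums to 1).
#' @export
assignGenomicSource <- function(mappings, tracks,
                                hierarchy = annotationHierarchy(),
                                exons = NULL) {
  if (length(mappings) == 0L) return(setNames(numeric(), character()))
  start0 <- BiocGenerics::start(mappings) - 1L
  end0 <- BiocGenerics::end(mappings)
  center1 <- floor((start0 + end0 - 1) / 2) + 1L
  centers <- GenomicRanges::GRanges(GenomicRanges::seqnames(mappings),
                                    IRanges::IRanges(center1, width = 1L),
                                    strand = BiocGenerics::strand(mappings))
  cls <- resolveAnnotation(centers, tracks, hierarchy)
  if (!is.null(exons)) {
    pc <- which(cls == "protein_coding")
    if (length(pc)) {
      ov <- suppressWarnings(GenomicRanges::findOverlaps(
        centers[pc], exons, ignore.strand = FALSE))
      inExon <- seq_along(pc) %in% S4Vectors::queryHits(ov)
      cls[pc] <- ifelse(inExon, "protein_coding_exon", "protein_coding_intron")
    }
  }
  w <- 1 / S4Vectors::mcols(mappings)$n_mappings
  agg <- tapply(w, cls, sum)
  out <- as.numeric(agg) / sum(w)
  names(out) <- names(agg)
  out
}

#' Expression prevalence of a mature sequence
#'
#' Number of datasets in which the exact sequence occurs, with no
#' mismatches or length variation.
#'
#' @param matureSeq the exact mature sequence.
#' @param datasets named list of read vectors, or a
#'   \linkS4class{SmallRNAPool}.
#' @return integer dataset count.
#' @export
prevalenceProfile <- function(matureSeq, datasets) {
  if (is(datasets, "SmallRNAPool")) {
    i <- match(matureSeq, rownames(datasets))
    if (is.na(i)) return(0L)
    return(sum(SummarizedExperiment::assay(datasets, "counts")[i, ] > 0L))
  }
  sum(vapply(datasets, function(r) matureSeq %in% r, logical(1)))
}

#' Transcripts-per-million normalization
#'
#' count / total reads in the dataset (after preprocessing) x 10^6.
#'
#' @param count exact-match read count.
#' @param totalReads post-preprocessing dataset total (> 0).
#' @return TPM value.
#' @examples
#' tpm(5, 1e6)  # 5.0
#' @export
tpm <- function(count, totalReads) {
  if (any(totalReads <= 0)) stop("totalReads must be positive")
  count / totalReads * 1e6
}

#' Processing precision of a hairpin end
#'
#' The consensus end is the modal (weight-summed) end coordinate, ties
#' resolved toward the 5'-most coordinate; the precision is the weighted
#' fraction of reads whose end equals the consensus. An end is called
#' precisely processed when at least nine out of ten derived RNAs map to
#' the consensus position (fraction >= 0.9).
#'
#' @param reads data.frame of reads on the hairpin product with columns
#'   \code{start}, \code{width} and optionally \code{weight} (default 1).
#' @param end \code{"5p"} (read start) or \code{"3p"} (read end).
#' @param cutoff precision cutoff (default 0.9).
#' @return list with \code{consensus}, \code{fraction_at_consensus},
#'   \code{precise}.
#' @export
processingPrecision <- function(reads, end = c("5p", "3p"), cutoff = 0.9) {
  end <- match.arg(end)
  if (is.null(reads) || nrow(reads) == 0L)
    return(list(consensus = NA_integer_, fraction_at_consensus = NA_real_,
                precise = NA))
  w <- if ("weight" %in% colnames(reads)) reads$weight else rep(1, nrow(reads))
  coord <- if (end == "5p") reads$start else reads$start + reads$width - 1L
  agg <- tapply(w, coord, sum)
  pos <- as.integer(names(agg))
  best <- max(agg)
  consensus <- min(pos[agg == best])  # tie: 5'-most coordinate
  frac <- sum(w[coord == consensus]) / sum(w)
  list(consensus = consensus, fraction_at_consensus = frac,
       precise = frac >= cutoff)
}
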