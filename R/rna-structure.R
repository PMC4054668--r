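#' Fold a candidate hairpin
#'
#' Computes the minimum-energy non-crossing secondary structure of a
#' candidate precursor under the package's simplified nearest-neighbour
#' energy model (Watson-Crick and GU wobble pairs, stacking bonuses, linear
#' loop penalties, minimum hairpin loop 3 nt). With
#' \code{forbidBifurcation = TRUE} (the default used throughout discovery and
#' homolog evaluation) the search is constrained to structures with a single
#' terminal loop; the unconstrained optimum is additionally reported through
#' \code{isBifurcated} and the \code{unconstrainedEnergy} slot.
#'
#' @param seq nucleotide string (A/C/G/U/T/N; T and U are equivalent).
#' @param forbidBifurcation logical; constrain to a single stem-loop.
#' @param reportUnconstrained also solve the unconstrained problem so the
#'   bifurcation flag and unconstrained energy are available (default TRUE;
#'   high-throughput callers that only need the constrained fold can turn
#'   this off).
#' @return a \linkS4class{SecondaryStructure}.
#' @examples
#' stem <- "GGGCGCAUGCAUGCAUGGCC"
#' hp <- paste0(stem, "GCUUCGGC", revcompRNA(stem))
#' foldHairpin(hp)
#' @export
foldHairpin <- function(seq, forbidBifurcation = TRUE,
                        reportUnconstrained = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  res <- .foldCpp(seq, forbidBifurcation, reportUnconstrained)
  new("SecondaryStructure",
      sequence = seq,
      dotBracket = res$dot_bracket,
      energy = res$energy,
      pairMap = as.integer(res$partner),
      bifurcated = res$unconstrained_bifurcated,
      unconstrainedEnergy = res$unconstrained_energy)
}

#' Brute-force folding energy reference
#'
#' Exhaustively enumerates every non-crossing pairing (minimum hairpin loop
#' 3 nt) and scores each with the standalone loop-decomposition scorer,
#' returning the minimum energy. Shares only the energy parameter table with
#' \code{\link{foldHairpin}}; the search is entirely independent of the
#' dynamic program and is meant for validating it on short sequences.
#'
#' @param seq nucleotide string, recommended at most ~40 nt.
#' @param maxStructures abort beyond this many enumerated structures.
#' @return minimum energy (kcal/mol).
#' @export
foldEnergyBruteForce <- function(seq, maxStructures = 5e7) {
  .enumFoldMFECpp(seq, maxStructures)
}

#' Score an explicit structure
#'
#' Energy of a given dot-bracket structure for a sequence under the package
#' energy model, by loop decomposition. Returns \code{NA} for structures that
#' the model disallows (loops below the minimum size, non-pairable bases).
#'
#' @param seq nucleotide string.
#' @param dotBracket matching dot-bracket string.
#' @return energy in kcal/mol, or NA.
#' @export
scoreDotBracket <- function(seq, dotBracket) {
  stopifnot(nchar(seq) == nchar(dotBracket))
  .scorePairingCpp(seq, dotBracketToPairMap(dotBracket))
}

#' Convert a dot-bracket string to a pair map
#'
#' @param dotBracket dot-bracket string over \code{( . )}.
#' @return integer vector of 1-based partners, NA when unpaired.
#' @export
dotBracketToPairMap <- function(dotBracket) {
  ch <- strsplit(dotBracket, "")[[1]]
  if (!all(ch %in% c("(", ".", ")"))) stop("invalid dot-bracket character")
  pm <- rep(NA_integer_, length(ch))
  stack <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pm[i] <- j; pm[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pm
}

#' Count base pairs between two spans of a hairpin
#'
#' Number of base pairs with one partner inside \code{spanA} and the other
#' inside \code{spanB}; used for the minimum-duplex-pairing filter
#' (at least 14 nt paired between the two miRNA strands).
#'
#' @param structure a \linkS4class{SecondaryStructure}.
#' @param spanA,spanB disjoint 1-based inclusive \code{c(start, end)}
#'   intervals on the folded sequence.
#' @return integer pair count.
#' @export
countInterstrandPairs <- function(structure, spanA, spanB) {
  stopifnot(is(structure, "SecondaryStructure"),
            length(spanA) == 2L, length(spanB) == 2L)
  if (spanA[1] > spanA[2] || spanB[1] > spanB[2])
    stop("spans must be c(start, end) with start <= end")
  if (max(spanA[1], spanB[1]) <= min(spanA[2], spanB[2]))
    stop("spans overlap")
  n <- length(pairMap(structure))
  if (spanA[1] < 1 || spanB[1] < 1 || spanA[2] > n || spanB[2] > n)
    stop("span outside the folded sequence")
  pm <- pairMap(structure)
  i <- seq(spanA[1], spanA[2])
  j <- pm[i]
  sum(!is.na(j) & j >= spanB[1] & j <= spanB[2])
}

#' Extract the seed sequence of a mature miRNA
#'
#' The seed is defined as positions two to eight from the 5' end of the
#' mature strand (a 7-mer).
#'
#' @param mature mature sequence, length >= 8.
#' @return 7-nt character string.
#' @examples
#' seedOf("UGAGGUAGUAGGUUGUAUAGUU")  # "GAGGUAG"
#' @export
seedOf <- function(mature) {
  stopifnot(is.character(mature))
  if (any(nchar(mature) < 8L)) stop("mature sequence must be at least 8 nt")
  substr(mature, 2L, 8L)
}

#' Minimum-energy intermolecular duplex
#'
#' Hybridises a miRNA against a target site, forbidding intramolecular
#' pairs, in the style of hybrid-min. Deterministic for fixed inputs.
#'
#' @param mirna,site nucleotide strings (8-60 nt each recommended).
#' @return a \linkS4class{DuplexHybrid}.
#' @export
duplexMFE <- function(mirna, site) {
  stopifnot(is.character(mirna), is.character(site),
            length(mirna) == 1L, length(site) == 1L)
  res <- .duplexCpp(mirna, site)
  new("DuplexHybrid",
      mirna = mirna, site = site,
      energy = res$energy,
      mirnaPaired = res$mirna_paired,
      mirnaWatsonCrick = res$mirna_wc,
      sitePartner = as.integer(res$site_partner))
}

#' Brute-force duplex energy reference
#'
#' Exhaustive enumeration of all co-linear intermolecular pair sets; for
#' validating \code{\link{duplexMFE}} on short strands.
#'
#' @param mirna,site nucleotide strings (keep each at most ~15 nt).
#' @return minimum duplex energy (kcal/mol).
#' @export
duplexEnergyBruteForce <- function(mirna, site) {
  .enumDuplexMFECpp(mirna, site)
}

#' Reverse complement (RNA or DNA alphabet preserved)
#'
#' @param x character vector of nucleotide strings.
#' @return reverse complements, keeping U for RNA input and T for DNA input.
#' @export
revcompRNA <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "")[[1]])
    comp <- c(A = "U", C = "G", G = "C", U = "A", T = "A", N = "N",
              a = "u", c = "g", g = "c", u = "a", t = "a", n = "n")
    out <- comp[ch]
    if (!grepl("[Uu]", s) && grepl("[Tt]", s)) out[ch %in% c("A", "a")] <- "T"
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
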