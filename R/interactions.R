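#' Overlap CLIP tags with miRNA hairpins
#'
#' A hairpin is supported when at least one same-strand tag overlaps it or
#' lies within \code{window} nt of it. For each supported hairpin exactly
#' one uniformly-random supporting tag is chosen as the representative (one
#' RNG draw per hairpin, in hairpin-sorted order, so results are
#' reproducible under the seed) and its offset is reported: tag 5' end
#' minus hairpin 5' end, in hairpin orientation.
#'
#' @param hairpins \code{GRanges} of hairpin loci (names used as ids).
#' @param tags \code{GRanges} of CLIP tags.
#' @param window maximum distance in nt (default 20).
#' @param seed RNG seed for the representative draw.
#' @return data.frame with columns \code{hairpin_id}, \code{offset},
#'   \code{n_supporting_tags}; one row per supported hairpin.
#' @export
overlapClipTags <- function(hairpins, tags, window = 20L, seed = 1L) {
  if (is.null(names(hairpins)))
    names(hairpins) <- sprintf("hairpin%d", seq_along(hairpins))
  o <- order(as.character(GenomicRanges::seqnames(hairpins)),
             BiocGenerics::start(hairpins), names(hairpins))
  hairpins <- hairpins[o]
  ov <- GenomicRanges::findOverlaps(hairpins, tags, maxgap = window,
                                    ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  set.seed(seed)
  rows <- lapply(seq_along(hairpins), function(i) {
    tagIdx <- sh[qh == i]
    if (!length(tagIdx)) return(NULL)
    pick <- tagIdx[sample.int(length(tagIdx), 1L)]
    hp <- hairpins[i]; tg <- tags[pick]
    offset <- if (as.character(BiocGenerics::strand(hp)) == "-")
      BiocGenerics::end(hp) - BiocGenerics::end(tg)
    else BiocGenerics::start(tg) - BiocGenerics::start(hp)
    data.frame(hairpin_id = names(hairpins)[i], offset = offset,
               n_supporting_tags = length(tagIdx), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(hairpin_id = character(), offset = integer(),
                      n_supporting_tags = integer()))
  do.call(rbind, rows)
}

#' Sample genomic control regions for CLIP overlap
#'
#' Samples \code{nPerMapping} positions per candidate-hairpin genome
#' mapping, uniformly over nucleotides and strands; the 80 nucleotides
#' bracketing each position (40 on each side) form a control region.
#' Control regions are overlapped with the tags like hairpins and the
#' supported count is scaled by (number of hairpin mappings) / (number of
#' control regions), i.e. divided by \code{nPerMapping}.
#'
#' @param genome named \code{DNAStringSet} or character vector.
#' @param nMappings number of candidate-hairpin genome mappings.
#' @param tags \code{GRanges} of CLIP tags (may be empty/NULL to only
#'   sample regions).
#' @param nPerMapping control positions per mapping (default 100).
#' @param flankTotal total bracketing window size in nt (default 80).
#' @param window overlap window as in \code{\link{overlapClipTags}}.
#' @param seed RNG seed.
#' @return list with \code{regions} (\code{GRanges} of length
#'   \code{nMappings * nPerMapping}), \code{n_supported} and
#'   \code{scaled_support}.
#' @export
sampleGenomicControls <- function(genome, nMappings, tags = NULL,
                                  nPerMapping = 100L, flankTotal = 80L,
                                  window = 20L, seed = 1L) {
  genome <- .asGenome(genome)
  lens <- Biostrings::width(genome)
  if (sum(lens) == 0L) stop("empty genome")
  n <- as.integer(nMappings) * as.integer(nPerMapping)
  set.seed(seed)
  chrIdx <- sample.int(length(lens), n, replace = TRUE, prob = lens / sum(lens))
  pos <- floor(runif(n) * lens[chrIdx]) + 1L
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  half <- flankTotal %/% 2L
  start <- pmax(1L, pos - half)
  end <- pmin(lens[chrIdx], pos + half)
  regions <- GenomicRanges::GRanges(names(genome)[chrIdx],
                                    IRanges::IRanges(start, end),
                                    strand = strand)
  nSupported <- 0L
  if (!is.null(tags) && length(tags)) {
    ov <- GenomicRanges::findOverlaps(regions, tags, maxgap = window,
                                      ignore.strand = FALSE)
    nSupported <- length(unique(S4Vectors::queryHits(ov)))
  }
  list(regions = regions, n_supported = nSupported,
       scaled_support = nSupported / nPerMapping)
}

#' Match sequencing tags against mature miRNAs with 3' tolerance
#'
#' A tag matches a mature sequence when their 5' ends coincide, every shared
#' position is identical, and the length difference (in either direction,
#' confined to the 3' end) is at most \code{tol} nucleotides.
#'
#' @param tagSequences character vector of tag sequences.
#' @param matureSet named character vector of mature sequences.
#' @param tol maximum 3' length difference (default 3).
#' @return character vector of matched mature ids (unique); the per-tag
#'   match lists are in the \code{"per_tag"} attribute.
#' @export
matchMatureTags <- function(tagSequences, matureSet, tol = 3L) {
  if (is.null(names(matureSet)))
    names(matureSet) <- sprintf("mature%d", seq_along(matureSet))
  tagLen <- nchar(tagSequences)
  perTag <- lapply(seq_along(tagSequences), function(i) {
    t <- tagSequences[i]
    hits <- character()
    for (j in seq_along(matureSet)) {
      m <- matureSet[[j]]
      dl <- abs(nchar(m) - tagLen[i])
      if (dl > tol) next
      L <- min(nchar(m), tagLen[i])
      if (substr(t, 1L, L) == substr(m, 1L, L)) hits <- c(hits, names(matureSet)[j])
    }
    hits
  })
  out <- unique(unlist(perTag))
  if (is.null(out)) out <- character()
  attr(out, "per_tag") <- perTag
  out
}

#' Fraction of detected references present in IP data
#'
#' For each reference class: of the references detected in either library
#' (count > 0 anywhere), the fraction also detected in the
#' immunoprecipitation sample.
#'
#' @param ipCounts,inputCounts named numeric count vectors over the same
#'   reference ids.
#' @param classes named character vector mapping reference id to class; when
#'   NULL a single overall fraction is returned.
#' @return named numeric vector of per-class fractions.
#' @export
ipPresenceSummary <- function(ipCounts, inputCounts, classes = NULL) {
  ids <- union(names(ipCounts), names(inputCounts))
  ip <- setNames(rep(0, length(ids)), ids); ip[names(ipCounts)] <- ipCounts
  inp <- setNames(rep(0, length(ids)), ids); inp[names(inputCounts)] <- inputCounts
  detected <- ip > 0 | inp > 0
  if (is.null(classes)) classes <- setNames(rep("all", length(ids)), ids)
  cls <- classes[ids]
  out <- vapply(split(seq_along(ids), cls), function(idx) {
    det <- idx[detected[idx]]
    if (!length(det)) return(NA_real_)
    mean(ip[det] > 0)
  }, numeric(1))
  out
}

#' Call miRNA-target chimeric reads
#'
#' A read is a chimera when a prefix of at least \code{minArmLen} nt
#' exactly matches a mature miRNA (with up to \code{tol} nt missing at the
#' miRNA 3' end) and the remaining suffix, also at least \code{minArmLen}
#' nt, exactly matches a transcript. Chimeras of the same miRNA and
#' transcript whose sites lie within \code{clusterTol} nt are clustered
#' into one interaction. Duplex energy is computed between the full mature
#' sequence and the matched site extended by \code{context} nt on each
#' side.
#'
#' @param reads named character vector of read sequences.
#' @param mirnaSet named character vector of mature miRNAs.
#' @param transcripts named character vector (or \code{DNAStringSet}) of
#'   transcript sequences.
#' @param minArmLen minimum arm length (default 17).
#' @param tol 3' tolerance on the miRNA arm (default 3).
#' @param clusterTol site clustering tolerance in nt (default 4).
#' @param context site context for the duplex in nt (default 25).
#' @return data.frame with one row per chimera: \code{read_id},
#'   \code{mirna_id}, \code{mirna_span_end} (the miRNA arm is read
#'   positions 1..span_end), \code{transcript_id}, \code{site_start},
#'   \code{site_end} (0-based half-open on the transcript),
#'   \code{energy}, \code{seed_class}, \code{ambiguous},
#'   \code{interaction_id}.
#' @export
callChimeras <- function(reads, mirnaSet, transcripts, minArmLen = 17L,
                         tol = 3L, clusterTol = 4L, context = 25L) {
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  if (is.null(names(mirnaSet)))
    names(mirnaSet) <- sprintf("mir%d", seq_along(mirnaSet))
  if (is(transcripts, "DNAStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  rows <- list()
  for (r in seq_along(reads)) {
    read <- reads[[r]]
    bestL <- 0L; bestMir <- NA_character_
    for (j in seq_along(mirnaSet)) {
      m <- mirnaSet[[j]]
      Lmax <- min(nchar(m), nchar(read))
      Lmin <- max(minArmLen, nchar(m) - tol)
      if (Lmax < Lmin) next
      for (L in seq(Lmax, Lmin)) {
        if (substr(read, 1L, L) == substr(m, 1L, L)) {
          if (L > bestL) { bestL <- L; bestMir <- names(mirnaSet)[j] }
          break
        }
      }
    }
    if (bestL == 0L) next
    suffix <- substr(read, bestL + 1L, nchar(read))
    if (nchar(suffix) < minArmLen) next
    hitTx <- list()
    for (tx in names(transcripts)) {
      mt <- Biostrings::matchPattern(suffix, transcripts[[tx]])
      if (length(mt))
        hitTx[[tx]] <- BiocGenerics::start(mt)
    }
    if (!length(hitTx)) next
    ambiguous <- length(hitTx) > 1L
    for (tx in names(hitTx)) {
      for (st in hitTx[[tx]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = names(reads)[r], mirna_id = bestMir,
          mirna_span_end = bestL, transcript_id = tx,
          site_start = st - 1L, site_end = st - 1L + nchar(suffix),
          ambiguous = ambiguous, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(read_id = character(), mirna_id = character(),
                      mirna_span_end = integer(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      energy = numeric(), seed_class = character(),
                      ambiguous = logical(), interaction_id = integer()))
  df <- do.call(rbind, rows)
  # cluster by (mirna, transcript, site within clusterTol)
  df <- df[order(df$mirna_id, df$transcript_id, df$site_start), , drop = FALSE]
  df$interaction_id <- NA_integer_
  nextId <- 1L
  key <- paste(df$mirna_id, df$transcript_id)
  for (k in unique(key)) {
    idx <- which(key == k)
    anchor <- df$site_start[idx[1L]]
    id <- nextId; nextId <- nextId + 1L
    for (i in idx) {
      if (abs(df$site_start[i] - anchor) > clusterTol) {
        anchor <- df$site_start[i]
        id <- nextId; nextId <- nextId + 1L
      }
      df$interaction_id[i] <- id
    }
  }
  # duplex energy and seed class against site +/- context
  df$energy <- NA_real_; df$seed_class <- NA_character_
  for (i in seq_len(nrow(df))) {
    tx <- transcripts[[df$transcript_id[i]]]
    s <- max(1L, df$site_start[i] + 1L - context)
    e <- min(nchar(tx), df$site_end[i] + context)
    site <- substr(tx, s, e)
    dup <- duplexMFE(mirnaSet[[df$mirna_id[i]]], site)
    df$energy[i] <- foldEnergy(dup)
    df$seed_class[i] <- classifySeedInteraction(dup)
  }
  rownames(df) <- NULL
  df
}

#' Classify a chimera's seed pairing
#'
#' \code{canonical_7mer_seed} when all of miRNA positions 2-8 are
#' Watson-Crick paired in the duplex; \code{seed_with_imperfections} when
#' at least 5 of positions 2-8 are paired (GU wobble allowed); otherwise
#' \code{non_seed}.
#'
#' @param duplex a \linkS4class{DuplexHybrid} of the full mature sequence
#'   against the target site.
#' @return one of the three class labels.
#' @export
classifySeedInteraction <- function(duplex) {
  stopifnot(is(duplex, "DuplexHybrid"))
  seedIdx <- 2:8
  paired <- duplex@mirnaPaired[seedIdx]
  wc <- duplex@mirnaWatsonCrick[seedIdx]
  if (all(paired & wc)) "canonical_7mer_seed"
  else if (sum(paired) >= 5L) "seed_with_imperfections"
  else "non_seed"
}

#' Shuffled-miRNA duplex energy control
#'
#' Shuffles the miRNA (preserving mononucleotide composition), recomputes
#' the duplex energy against the same site, and reports the add-one
#' corrected empirical p-value of the observed energy.
#'
#' @param mirna,site nucleotide strings.
#' @param nShuffles number of shuffles (>= 1).
#' @param seed RNG seed.
#' @return list with \code{observed}, \code{shuffled} (energies) and
#'   \code{p}.
#' @export
shuffledEnergyControl <- function(mirna, site, nShuffles = 1000L, seed = 1L) {
  if (nShuffles < 1L) stop("nShuffles must be at least 1")
  obs <- foldEnergy(duplexMFE(mirna, site))
  ch <- strsplit(mirna, "")[[1]]
  set.seed(seed)
  shuf <- vapply(seq_len(nShuffles), function(b) {
    foldEnergy(duplexMFE(paste(sample(ch), collapse = ""), site))
  }, numeric(1))
  list(observed = obs, shuffled = shuf,
       p = (1 + sum(shuf <= obs)) / (1 + nShuffles))
}
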