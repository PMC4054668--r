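#' Default discovery parameters
#'
#' All thresholds of the pooled discovery pipeline, with their defaults:
#' at most 5 genome mappings, prevalence >= 2, hairpin flanks 10/70 nt,
#' at most 10 percent Dicer-inconsistent weighted reads, >= 14 base pairs
#' between the mature span and the rest of the hairpin, fold energy
#' <= -14 kcal/mol, minimum read length 18 nt.
#'
#' @param ... named overrides of any default.
#' @return named list of parameters.
#' @export
discoveryParams <- function(...) {
  p <- list(maxLoci = 5L, minPrevalence = 2L, flankShort = 10L, flankLong = 70L,
            maxInconsistent = 0.10, minPairs = 14L, maxEnergy = -14,
            minReadLen = 18L, consistencyTol = 2L, overhang = 2L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p
}

#' Map sequences to a genome by exact matching
#'
#' Strand-aware exact (perfect-match) mapping; sequences mapping to more
#' than \code{maxLoci} genomic locations contribute no mappings.
#'
#' @param sequences character vector of unique sequences.
#' @param genome a named \code{DNAStringSet} (or named character vector).
#' @param maxLoci discard sequences with more than this many loci (default 5).
#' @return a \code{GRanges} (0-based half-open converted to 1-based GRanges
#'   convention) with metadata columns \code{sequence} and \code{n_mappings}.
#' @export
mapExact <- function(sequences, genome, maxLoci = 5L) {
  genome <- .asGenome(genome)
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome")
  sequences <- unique(sequences)
  hits <- list()
  for (w in sort(unique(nchar(sequences)))) {
    seqw <- sequences[nchar(sequences) == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqw))
    for (chr in names(genome)) {
      subj <- genome[[chr]]
      L <- length(subj)
      fwd <- Biostrings::matchPDict(pd, subj)
      n <- S4Vectors::elementNROWS(fwd)
      if (any(n > 0)) {
        st <- unlist(BiocGenerics::start(fwd), use.names = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          sequence = rep(seqw, n), chrom = chr, start = st, width = w,
          strand = "+", stringsAsFactors = FALSE)
      }
      rev <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj))
      n <- S4Vectors::elementNROWS(rev)
      if (any(n > 0)) {
        st <- unlist(BiocGenerics::start(rev), use.names = FALSE)
        en <- st + w - 1L
        hits[[length(hits) + 1L]] <- data.frame(
          sequence = rep(seqw, n), chrom = chr, start = L - en + 1L, width = w,
          strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(.emptyMappings())
  df <- do.call(rbind, hits)
  nmap <- table(df$sequence)
  df$n_mappings <- as.integer(nmap[df$sequence])
  df <- df[df$n_mappings <= maxLoci, , drop = FALSE]
  if (!nrow(df)) return(.emptyMappings())
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, width = df$width),
    strand = df$strand)
  S4Vectors::mcols(gr)$sequence <- df$sequence
  S4Vectors::mcols(gr)$n_mappings <- df$n_mappings
  gr
}

.asGenome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (length(genome) > 0L && is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  genome
}

.emptyMappings <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$sequence <- character()
  S4Vectors::mcols(gr)$n_mappings <- integer()
  gr
}

#' Drop sequences below a prevalence threshold
#'
#' Sequences not detected in at least \code{minPrevalence} distinct datasets
#' are discarded.
#'
#' @param pool a \linkS4class{SmallRNAPool}.
#' @param minPrevalence minimum prevalence (default 2).
#' @return the filtered pool.
#' @export
dropLowPrevalence <- function(pool, minPrevalence = 2L) {
  pool[prevalence(pool) >= minPrevalence, ]
}

# deterministic priority order over per-sequence summaries:
# weight desc, prevalence desc, chrom asc, start asc, sequence asc
.priorityOrder <- function(weight, prev, chrom, start, sequence) {
  order(-weight, -prev, chrom, start, sequence, method = "radix")
}

#' Resolve same-strand overlaps by weight
#'
#' Greedy selection by descending weight (prevalence divided by the number
#' of genome mappings): a sequence is removed if any of its mappings
#' overlaps, on the same strand, a mapping of an already-retained sequence.
#' Ties break by higher prevalence, then leftmost mapping (chromosome name,
#' then start), then sequence lexicographic order.
#'
#' @param mappings a \code{GRanges} from \code{\link{mapExact}} with
#'   metadata columns \code{sequence} and \code{n_mappings}.
#' @param prevalence named integer vector: prevalence per sequence.
#' @return the mappings of retained sequences, with a \code{weight} column.
#' @export
resolveOverlaps <- function(mappings, prevalence) {
  if (length(mappings) == 0L) return(mappings)
  seqv <- S4Vectors::mcols(mappings)$sequence
  prev <- prevalence[seqv]
  if (any(is.na(prev))) stop("prevalence missing for some mapped sequences")
  weight <- as.numeric(prev) / S4Vectors::mcols(mappings)$n_mappings
  S4Vectors::mcols(mappings)$weight <- weight

  useq <- unique(seqv)
  first <- match(useq, seqv)
  # leftmost mapping per sequence (chrom lexicographic, then start) for ties
  o <- order(seqv, as.character(GenomicRanges::seqnames(mappings)),
             BiocGenerics::start(mappings), method = "radix")
  lead <- o[!duplicated(seqv[o])]
  chromLeft <- setNames(as.character(GenomicRanges::seqnames(mappings))[lead],
                        seqv[lead])[useq]
  startLeft <- setNames(BiocGenerics::start(mappings)[lead], seqv[lead])[useq]
  ord <- .priorityOrder(weight[first], prev[first], chromLeft, startLeft, useq)

  ov <- GenomicRanges::findOverlaps(mappings, mappings, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  keepEdge <- seqv[qh] != seqv[sh]
  edges <- data.table::data.table(a = match(seqv[qh[keepEdge]], useq),
                                  b = match(seqv[sh[keepEdge]], useq))
  adj <- split(edges$b, edges$a)

  kept <- logical(length(useq))
  for (i in ord) {
    nb <- adj[[as.character(i)]]
    if (is.null(nb) || !any(kept[nb])) kept[i] <- TRUE
  }
  mappings[seqv %in% useq[kept]]
}

#' Remove sequences overlapping annotated RNAs
#'
#' Sequences with at least one same-strand 1-nt overlap between any of their
#' mappings and any exclusion interval (known miRNA hairpins, tRNA, rRNA)
#' are discarded.
#'
#' @param mappings a \code{GRanges} with a \code{sequence} metadata column.
#' @param exclusionTracks a \code{GRanges}, or list of \code{GRanges}, of
#'   intervals to exclude.
#' @return the mappings of retained sequences.
#' @export
excludeAnnotated <- function(mappings, exclusionTracks) {
  if (length(mappings) == 0L) return(mappings)
  if (is.list(exclusionTracks) || is(exclusionTracks, "GRangesList"))
    exclusionTracks <- suppressWarnings(do.call(c, unname(as.list(exclusionTracks))))
  if (is.null(exclusionTracks) || length(exclusionTracks) == 0L) return(mappings)
  shared <- intersect(as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(mappings))),
                      unique(as.character(GenomicRanges::seqnames(exclusionTracks))))
  if (length(shared) == 0L) {
    warning("no shared chromosome names between mappings and exclusion tracks; ",
            "treating as no overlap")
    return(mappings)
  }
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(mappings, exclusionTracks,
                                minoverlap = 1L, ignore.strand = FALSE))
  bad <- unique(S4Vectors::mcols(mappings)$sequence[S4Vectors::queryHits(ov)])
  mappings[!(S4Vectors::mcols(mappings)$sequence %in% bad)]
}

#' Excise candidate hairpins around a mapping
#'
#' Each mapping is excised twice, in transcript orientation: once with 10 nt
#' upstream and 70 nt downstream (the sequence as the 5' arm) and once with
#' 70 nt upstream and 10 nt downstream (3' arm). Hypotheses whose flank runs
#' off the contig are omitted with a reason.
#'
#' @param mappings a \code{GRanges} with \code{sequence} metadata.
#' @param genome named \code{DNAStringSet} or character vector.
#' @param flankShort,flankLong flank lengths (defaults 10 and 70).
#' @return a \code{GRanges} of hairpin loci with metadata columns
#'   \code{arm} ("5p"/"3p"), \code{hairpin_seq}, \code{seed_start} (1-based
#'   position of the seeding sequence on the hairpin), \code{seed_len},
#'   \code{sequence}, \code{n_mappings} and, when present on the input,
#'   \code{weight}. Omitted hypotheses are recorded in the
#'   \code{"skipped"} attribute.
#' @export
exciseCandidateHairpins <- function(mappings, genome, flankShort = 10L,
                                    flankLong = 70L) {
  genome <- .asGenome(genome)
  chrLen <- setNames(Biostrings::width(genome), names(genome))
  n <- length(mappings)
  chr <- as.character(GenomicRanges::seqnames(mappings))
  st <- BiocGenerics::start(mappings); en <- BiocGenerics::end(mappings)
  neg <- as.character(BiocGenerics::strand(mappings)) == "-"
  mc <- S4Vectors::mcols(mappings)
  wgt <- if ("weight" %in% names(mc)) mc$weight else rep(NA_real_, n)

  parts <- list(); skipped <- character()
  for (arm in c("5p", "3p")) {
    up <- if (arm == "5p") flankShort else flankLong
    down <- if (arm == "5p") flankLong else flankShort
    gup <- ifelse(neg, down, up); gdown <- ifelse(neg, up, down)
    hs <- st - gup; he <- en + gdown
    ok <- hs >= 1L & he <= chrLen[chr]
    if (any(!ok))
      skipped <- c(skipped, sprintf("%s:%d-%d(%s) %s-arm: flank beyond contig",
                                    chr[!ok], st[!ok], en[!ok],
                                    ifelse(neg[!ok], "-", "+"), arm))
    if (!any(ok)) next
    seqchar <- character(sum(ok))
    okIdx <- which(ok)
    for (ch in unique(chr[okIdx])) {
      sel <- okIdx[chr[okIdx] == ch]
      chStr <- as.character(genome[[ch]])
      seqchar[match(sel, okIdx)] <- substring(chStr, hs[sel], he[sel])
    }
    if (any(neg[okIdx])) {
      ni <- which(neg[okIdx])
      seqchar[ni] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqchar[ni])))
    }
    parts[[arm]] <- data.frame(
      chrom = chr[okIdx], start = hs[okIdx], end = he[okIdx],
      strand = ifelse(neg[okIdx], "-", "+"), arm = arm,
      hairpin_seq = seqchar, seed_start = up + 1L,
      seed_len = (en - st + 1L)[okIdx], sequence = mc$sequence[okIdx],
      n_mappings = mc$n_mappings[okIdx], weight = wgt[okIdx],
      stringsAsFactors = FALSE)
  }
  if (!length(parts)) {
    out <- GenomicRanges::GRanges()
    attr(out, "skipped") <- skipped
    return(out)
  }
  df <- do.call(rbind, parts)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  for (col in c("arm", "hairpin_seq", "seed_start", "seed_len", "sequence",
                "n_mappings", "weight"))
    S4Vectors::mcols(gr)[[col]] <- df[[col]]
  attr(gr, "skipped") <- skipped
  gr
}

#' Evaluate Dicer-processing consistency of a hairpin
#'
#' The mature window is placed at the highest-weight read; the star window
#' is the duplex partner implied by the constrained fold with a 2-nt 3'
#' overhang on each strand; the loop window lies between them. A read is
#' consistent when its 5' end lies within \code{tol} nt of the 5' end of
#' the mature, star or loop window and the read lies entirely within the
#' hairpin. Candidates whose weighted inconsistent fraction exceeds
#' \code{maxInconsistent} fail.
#'
#' @param hairpinSeq hairpin sequence (transcript orientation).
#' @param reads data.frame of reads mapped on the hairpin with columns
#'   \code{start} (1-based 5' position), \code{width}, \code{weight}.
#' @param structure optional precomputed constrained
#'   \linkS4class{SecondaryStructure} of the hairpin.
#' @param maxInconsistent maximum weighted inconsistent fraction
#'   (default 0.10; the boundary passes).
#' @param tol 5'-end tolerance in nt (default 2).
#' @param overhang 3' duplex overhang in nt (default 2).
#' @param minDuplexPairs minimum base pairs between the mature and star
#'   windows under the fold (default 14); windows that do not form a
#'   genuine duplex fail with reason "weak duplex".
#' @return list with elements \code{pass}, \code{reason},
#'   \code{consistent_fraction}, \code{star_supported}, \code{mature_window},
#'   \code{star_window}, \code{loop_window}, \code{overhang_3p}.
#' @export
evaluateDicerConsistency <- function(hairpinSeq, reads, structure = NULL,
                                     maxInconsistent = 0.10, tol = 2L,
                                     overhang = 2L, minDuplexPairs = 14L) {
  n <- nchar(hairpinSeq)
  if (is.null(reads) || nrow(reads) == 0L)
    return(list(pass = FALSE, reason = "no support",
                consistent_fraction = NA_real_, star_supported = FALSE,
                mature_window = NULL, star_window = NULL, loop_window = NULL,
                overhang_3p = overhang))
  if (is.null(structure)) structure <- foldHairpin(hairpinSeq, TRUE)
  pm <- pairMap(structure)

  # anchor the mature window at the most abundant read (pooled copy count
  # when available, weight otherwise); ties toward the leftmost start
  rank <- if ("count" %in% colnames(reads)) reads$count else reads$weight
  agg <- stats::aggregate(rank, by = list(start = reads$start,
                                          width = reads$width), FUN = sum)
  agg <- agg[order(-agg$x, agg$start, agg$width), , drop = FALSE]
  mStart <- agg$start[1L]; mEnd <- mStart + agg$width[1L] - 1L

  partnerNear <- function(pos) {
    for (d in c(0L, 1L, -1L, 2L, -2L, 3L, -3L)) {
      p <- pos + d
      if (p >= 1L && p <= n && !is.na(pm[p])) return(c(pm[p], d))
    }
    NULL
  }
  p5 <- partnerNear(mStart)           # partner of mature 5' end
  p3 <- partnerNear(mEnd - overhang)  # partner of mature (3' end - overhang)
  if (is.null(p5) || is.null(p3))
    return(list(pass = FALSE, reason = "no duplex",
                consistent_fraction = NA_real_, star_supported = FALSE,
                mature_window = c(mStart, mEnd), star_window = NULL,
                loop_window = NULL, overhang_3p = overhang))
  sEnd <- min(n, p5[1L] + p5[2L] + overhang)
  sStart <- max(1L, p3[1L] + p3[2L])
  if (sStart > sEnd)
    return(list(pass = FALSE, reason = "no duplex",
                consistent_fraction = NA_real_, star_supported = FALSE,
                mature_window = c(mStart, mEnd), star_window = NULL,
                loop_window = NULL, overhang_3p = overhang))
  # the mature and star windows must form a genuine duplex under the fold
  matureIdx <- seq(max(1L, mStart), min(n, mEnd))
  duplexPairs <- sum(!is.na(pm[matureIdx]) &
                       pm[matureIdx] >= sStart & pm[matureIdx] <= sEnd)
  if (duplexPairs < minDuplexPairs)
    return(list(pass = FALSE, reason = "weak duplex",
                consistent_fraction = NA_real_, star_supported = FALSE,
                mature_window = c(mStart, mEnd), star_window = c(sStart, sEnd),
                loop_window = NULL, overhang_3p = overhang))
  if (sStart > mEnd) loop <- c(mEnd + 1L, sStart - 1L)
  else if (sEnd < mStart) loop <- c(sEnd + 1L, mStart - 1L)
  else loop <- NULL
  if (!is.null(loop) && loop[1L] > loop[2L]) loop <- NULL

  starts5 <- c(mStart, sStart, if (!is.null(loop)) loop[1L])
  nearWindow <- vapply(reads$start, function(s)
    any(abs(s - starts5) <= tol), logical(1))
  inside <- reads$start >= 1L & (reads$start + reads$width - 1L) <= n
  consistent <- nearWindow & inside
  w <- reads$weight
  fracInconsistent <- sum(w[!consistent]) / sum(w)
  starSupported <- any(abs(reads$start - sStart) <= tol & inside)
  list(pass = fracInconsistent <= maxInconsistent,
       reason = if (fracInconsistent <= maxInconsistent) ""
                else "inconsistent reads",
       consistent_fraction = 1 - fracInconsistent,
       star_supported = starSupported,
       mature_window = c(mStart, mEnd),
       star_window = c(sStart, sEnd),
       loop_window = loop,
       overhang_3p = overhang)
}

#' Resolve overlapping passing hairpins to one per locus
#'
#' When two passing hairpins overlap on the same genome strand only the one
#' whose seeding sequence is the most prevalent is retained (ties break as
#' in \code{\link{resolveOverlaps}}: leftmost, then sequence).
#'
#' @param hairpins a \code{GRanges} with metadata columns \code{prevalence}
#'   and \code{sequence}.
#' @return the retained hairpins.
#' @export
resolveHairpinLoci <- function(hairpins) {
  if (length(hairpins) <= 1L) return(hairpins)
  prev <- S4Vectors::mcols(hairpins)$prevalence
  ord <- .priorityOrder(prev, prev,
                        as.character(GenomicRanges::seqnames(hairpins)),
                        BiocGenerics::start(hairpins),
                        S4Vectors::mcols(hairpins)$sequence)
  ov <- GenomicRanges::findOverlaps(hairpins, hairpins, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  edges <- split(sh[qh != sh], qh[qh != sh])
  kept <- logical(length(hairpins))
  for (i in ord) {
    nb <- edges[[as.character(i)]]
    if (is.null(nb) || !any(kept[nb])) kept[i] <- TRUE
  }
  hairpins[kept]
}

#' Run the pooled miRNA discovery pipeline
#'
#' Executes the full chain: collapse, prevalence filter, exact genome
#' mapping with the multi-mapping cap, weight-based same-strand overlap
#' resolution, annotation exclusion, dual hairpin excision, structure
#' filtering (single stem-loop, minimum duplex pairing, maximum energy) and
#' Dicer-consistency evaluation, ending with one reported hairpin per locus.
#'
#' @param datasets named list of read vectors (or a
#'   \linkS4class{SmallRNAPool}).
#' @param genome named \code{DNAStringSet} or character vector.
#' @param exclusionTracks optional \code{GRanges} (or list) of annotated
#'   miRNA/tRNA/rRNA intervals to exclude.
#' @param params parameter list from \code{\link{discoveryParams}}.
#' @return a \code{GRanges} of candidate hairpins with metadata columns
#'   \code{arm}, \code{hairpin_seq}, \code{structure} (dot-bracket),
#'   \code{energy}, \code{consistent_fraction}, \code{sequence} (the seeding
#'   mature sequence), \code{prevalence}, \code{star_supported},
#'   \code{mature_start}, \code{mature_end}, \code{star_start},
#'   \code{star_end} (hairpin-local, 1-based) and \code{stratum}. Stage
#'   counts are in the \code{"stages"} attribute.
#' @export
runDiscovery <- function(datasets, genome, exclusionTracks = NULL,
                         params = discoveryParams()) {
  pool <- if (is(datasets, "SmallRNAPool")) datasets else collapsePool(datasets)
  stages <- c(collapsed = nrow(pool))
  pool <- pool[nchar(rownames(pool)) >= params$minReadLen, ]
  prevAll <- setNames(prevalence(pool), rownames(pool))

  retained <- dropLowPrevalence(pool, params$minPrevalence)
  stages["prevalence_filtered"] <- nrow(retained)
  if (nrow(retained) == 0L) return(.emptyCandidates(stages))

  genome <- .asGenome(genome)
  mapped <- mapExact(rownames(retained), genome, params$maxLoci)
  stages["mapped_sequences"] <- length(unique(S4Vectors::mcols(mapped)$sequence))
  if (length(mapped) == 0L) return(.emptyCandidates(stages))

  prevMap <- setNames(prevalence(retained), rownames(retained))
  resolved <- resolveOverlaps(mapped, prevMap)
  stages["overlap_resolved"] <- length(unique(S4Vectors::mcols(resolved)$sequence))

  resolved <- excludeAnnotated(resolved, exclusionTracks)
  stages["annotation_filtered"] <- length(unique(S4Vectors::mcols(resolved)$sequence))
  if (length(resolved) == 0L) return(.emptyCandidates(stages))

  hairpins <- exciseCandidateHairpins(resolved, genome,
                                      params$flankShort, params$flankLong)
  stages["excised"] <- length(hairpins)
  if (length(hairpins) == 0L) return(.emptyCandidates(stages))

  # structure filter: single stem-loop fold, enough pairing of the seeding
  # span, low enough energy
  mcAll <- S4Vectors::mcols(hairpins)
  hseqs <- mcAll$hairpin_seq
  seedStarts <- mcAll$seed_start
  seedLens <- mcAll$seed_len
  keep <- logical(length(hairpins))
  structures <- vector("list", length(hairpins))
  for (i in seq_along(hairpins)) {
    str <- foldHairpin(hseqs[i], TRUE, reportUnconstrained = FALSE)
    structures[[i]] <- str
    if (foldEnergy(str) > params$maxEnergy) next
    span <- c(seedStarts[i], seedStarts[i] + seedLens[i] - 1L)
    pm <- pairMap(str)
    idx <- seq(span[1L], span[2L])
    partners <- pm[idx]
    pairsOut <- sum(!is.na(partners) & (partners < span[1L] | partners > span[2L]))
    if (pairsOut < params$minPairs) next
    keep[i] <- TRUE
  }
  hairpins <- hairpins[keep]
  structures <- structures[keep]
  hseqs <- hseqs[keep]
  stages["structure_passed"] <- length(hairpins)
  if (length(hairpins) == 0L) return(.emptyCandidates(stages))

  # Dicer-consistency: locate all pool reads on each hairpin by exact
  # sense-strand substring lookup, weighted by prevalence / n_mappings
  poolDT <- data.table::data.table(
    sequence = rownames(pool),
    prevalence = prevalence(pool),
    count = as.integer(rowSums(SummarizedExperiment::assay(pool, "counts"))))
  data.table::setkey(poolDT, sequence)
  lens <- sort(unique(nchar(poolDT$sequence)))
  hits <- .hairpinReadHits(hseqs, poolDT, lens)
  if (nrow(hits)) {
    nmap <- .genomeMatchCounts(unique(hits$sequence), genome)
    nmapDT <- data.table::data.table(sequence = names(nmap),
                                     nmap = pmax(1L, as.integer(nmap)))
    hits <- nmapDT[hits, on = "sequence"]
    # weighted-copy counting: every read copy counts, weighted by the
    # prevalence / n_mappings of its sequence
    hits[, weight := count * prevalence / nmap]
  }
  readHits <- vector("list", length(hairpins))
  if (nrow(hits)) {
    hdf <- as.data.frame(hits[, c("hairpin", "sequence", "start", "width",
                                  "prevalence", "count", "weight")])
    for (grp in split(seq_len(nrow(hdf)), hdf$hairpin))
      readHits[[hdf$hairpin[grp[1L]]]] <- hdf[grp, -1L]
  }

  results <- vector("list", length(hairpins))
  pass <- logical(length(hairpins))
  for (i in seq_along(hairpins)) {
    res <- evaluateDicerConsistency(
      hseqs[i], readHits[[i]],
      structure = structures[[i]],
      maxInconsistent = params$maxInconsistent,
      tol = params$consistencyTol, overhang = params$overhang,
      minDuplexPairs = params$minPairs)
    results[[i]] <- res
    pass[i] <- res$pass
  }
  hairpins <- hairpins[pass]
  structures <- structures[pass]
  results <- results[pass]
  stages["dicer_passed"] <- length(hairpins)
  if (length(hairpins) == 0L) return(.emptyCandidates(stages))

  mc <- S4Vectors::mcols(hairpins)
  mc$structure <- vapply(structures, dotBracket, character(1))
  mc$energy <- vapply(structures, foldEnergy, numeric(1))
  mc$consistent_fraction <- vapply(results, function(r) r$consistent_fraction,
                                   numeric(1))
  mc$star_supported <- vapply(results, function(r) r$star_supported, logical(1))
  mc$mature_start <- vapply(results, function(r) r$mature_window[1L], numeric(1))
  mc$mature_end <- vapply(results, function(r) r$mature_window[2L], numeric(1))
  mc$star_start <- vapply(results, function(r)
    if (is.null(r$star_window)) NA_real_ else r$star_window[1L], numeric(1))
  mc$star_end <- vapply(results, function(r)
    if (is.null(r$star_window)) NA_real_ else r$star_window[2L], numeric(1))
  mc$prevalence <- as.integer(prevAll[mc$sequence])
  S4Vectors::mcols(hairpins) <- mc

  final <- resolveHairpinLoci(hairpins)
  stages["final"] <- length(final)
  S4Vectors::mcols(final)$stratum <-
    1L + as.integer(S4Vectors::mcols(final)$star_supported)
  attr(final, "stages") <- stages
  final
}

.emptyCandidates <- function(stages) {
  gr <- GenomicRanges::GRanges()
  for (col in c("arm", "hairpin_seq", "sequence"))
    S4Vectors::mcols(gr)[[col]] <- character()
  for (col in c("energy", "consistent_fraction"))
    S4Vectors::mcols(gr)[[col]] <- numeric()
  S4Vectors::mcols(gr)$prevalence <- integer()
  S4Vectors::mcols(gr)$stratum <- integer()
  attr(gr, "stages") <- stages
  gr
}

# exact sense-strand placement of pool reads on each hairpin sequence;
# batched: one keyed join per read length over all hairpins at once.
# Returns one data.table (hairpin, sequence, start, width, prevalence, count).
.hairpinReadHits <- function(hairpinSeqs, poolDT, lens) {
  hlen <- nchar(hairpinSeqs)
  parts <- list()
  for (L in lens) {
    ok <- which(hlen >= L)
    if (!length(ok)) next
    nstart <- hlen[ok] - L + 1L
    hidx <- rep(ok, nstart)
    starts <- unlist(lapply(nstart, seq_len), use.names = FALSE)
    idt <- data.table::data.table(
      sequence = substring(hairpinSeqs[hidx], starts, starts + L - 1L),
      hairpin = hidx, start = starts)
    m <- poolDT[idt, on = "sequence", nomatch = NULL]
    if (nrow(m)) { m[, width := L]; parts[[length(parts) + 1L]] <- m }
  }
  if (!length(parts))
    return(data.table::data.table(hairpin = integer(), sequence = character(),
                                  start = integer(), width = integer(),
                                  prevalence = integer(), count = integer()))
  unique(data.table::rbindlist(parts))
}

# genome-wide exact occurrence counts (both strands) for a set of sequences
.genomeMatchCounts <- function(sequences, genome) {
  if (!length(sequences)) return(setNames(integer(), character()))
  counts <- setNames(integer(length(sequences)), sequences)
  for (w in sort(unique(nchar(sequences)))) {
    seqw <- sequences[nchar(sequences) == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqw))
    for (chr in names(genome)) {
      counts[seqw] <- counts[seqw] +
        Biostrings::countPDict(pd, genome[[chr]]) +
        Biostrings::countPDict(pd, Biostrings::reverseComplement(genome[[chr]]))
    }
  }
  counts
}

#' Subsampled saturation analysis of discovery
#'
#' Subsamples the pooled input (per-read Bernoulli retention, or retention
#' of whole datasets constrained to within one dataset of the expected
#' mean), reruns the discovery pipeline and reports the candidate count per
#' retention fraction.
#'
#' @param datasets named list of read vectors.
#' @param genome,exclusionTracks,params as in \code{\link{runDiscovery}}.
#' @param mode \code{"reads"} or \code{"datasets"}.
#' @param fractions retention fractions in (0, 1].
#' @param seed RNG seed; results are reproducible under it.
#' @return data.frame with columns \code{fraction}, \code{n_candidates},
#'   \code{n_retained_datasets}.
#' @export
saturationSimulation <- function(datasets, genome, exclusionTracks = NULL,
                                 params = discoveryParams(),
                                 mode = c("reads", "datasets"),
                                 fractions = seq(0.1, 1, by = 0.1),
                                 seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(fractions > 0 & fractions <= 1))
  out <- data.frame(fraction = fractions, n_candidates = NA_integer_,
                    n_retained_datasets = NA_integer_)
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    set.seed(seed + i)
    if (f == 1) sub <- datasets
    else if (mode == "reads") {
      sub <- lapply(datasets, function(r) r[runif(length(r)) < f])
    } else {
      nd <- length(datasets)
      repeat {
        keep <- runif(nd) < f
        if (abs(sum(keep) - nd * f) <= 1) break
      }
      sub <- datasets[keep]
    }
    sub <- sub[vapply(sub, length, integer(1)) > 0L]
    out$n_retained_datasets[i] <- length(sub)
    out$n_candidates[i] <- if (length(sub))
      length(runDiscovery(sub, genome, exclusionTracks, params)) else 0L
  }
  out
}

#' Add validation-based confidence strata to candidates
#'
#' Stratum 1 is the base pipeline pass; one level is added for each
#' supplied line of evidence a candidate has: star-duplex read support,
#' knock-down response, protein-interaction (CLIP) support, chimera
#' support.
#'
#' @param candidates \code{GRanges} from \code{\link{runDiscovery}}.
#' @param knockdownHits,clipSupported,chimeraSupported optional character
#'   vectors of supported seeding sequences.
#' @return the candidates with an updated \code{stratum} column.
#' @export
assignConfidenceStrata <- function(candidates, knockdownHits = NULL,
                                   clipSupported = NULL,
                                   chimeraSupported = NULL) {
  if (length(candidates) == 0L) return(candidates)
  seqs <- S4Vectors::mcols(candidates)$sequence
  stratum <- 1L + as.integer(S4Vectors::mcols(candidates)$star_supported)
  if (!is.null(knockdownHits)) stratum <- stratum + (seqs %in% knockdownHits)
  if (!is.null(clipSupported)) stratum <- stratum + (seqs %in% clipSupported)
  if (!is.null(chimeraSupported)) stratum <- stratum + (seqs %in% chimeraSupported)
  S4Vectors::mcols(candidates)$stratum <- as.integer(stratum)
  candidates
}

#' Write discovery candidates as GFF3 and TSV
#'
#' GFF3 uses 1-based inclusive coordinates with hairpin, mature and star
#' features; the TSV carries sequence, structure, energy, consistency,
#' prevalence and stratum.
#'
#' @param candidates \code{GRanges} from \code{\link{runDiscovery}}.
#' @param gff3Path,tsvPath output paths (either may be NULL).
#' @export
writeCandidates <- function(candidates, gff3Path = NULL, tsvPath = NULL) {
  mc <- S4Vectors::mcols(candidates)
  if (!is.null(gff3Path)) {
    con <- file(gff3Path, "w")
    writeLines("##gff-version 3", con)
    for (i in seq_along(candidates)) {
      chr <- as.character(GenomicRanges::seqnames(candidates))[i]
      st <- BiocGenerics::start(candidates)[i]
      strand <- as.character(BiocGenerics::strand(candidates))[i]
      en <- BiocGenerics::end(candidates)[i]
      id <- sprintf("cand%03d", i)
      writeLines(sprintf("%s\tmiRpool\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s",
                         chr, st, en, strand, id), con)
      hp2g <- function(p) if (strand == "-") en - p + 1L else st + p - 1L
      m1 <- hp2g(mc$mature_start[i]); m2 <- hp2g(mc$mature_end[i])
      writeLines(sprintf("%s\tmiRpool\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s.mature;Parent=%s",
                         chr, min(m1, m2), max(m1, m2), strand, id, id), con)
      if (!is.na(mc$star_start[i])) {
        s1 <- hp2g(mc$star_start[i]); s2 <- hp2g(mc$star_end[i])
        writeLines(sprintf("%s\tmiRpool\tmiRNA_star\t%d\t%d\t.\t%s\t.\tID=%s.star;Parent=%s",
                           chr, min(s1, s2), max(s1, s2), strand, id, id), con)
      }
    }
    close(con)
  }
  if (!is.null(tsvPath)) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(candidates)),
      start0 = BiocGenerics::start(candidates) - 1L,
      end0 = BiocGenerics::end(candidates),
      strand = as.character(BiocGenerics::strand(candidates)),
      arm = mc$arm, sequence = mc$sequence,
      structure = mc$structure,
      energy = round(mc$energy, 1),
      consistent_fraction = mc$consistent_fraction,
      prevalence = mc$prevalence, stratum = mc$stratum,
      stringsAsFactors = FALSE)
    write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(candidates)
}
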