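#' Simulation configuration
#'
#' Study conditions for the synthetic pooled small RNA experiment: a 500-kb
#' genome at 42 percent GC, 10 datasets of 200,000 reads each, a 30 percent
#' uniform degradation background, and mature-strand 5' fidelity 0.9.
#'
#' @param ... named overrides of any default.
#' @return named list of simulation parameters.
#' @export
simulationConfig <- function(...) {
  p <- list(genomeLength = 500000L, gc = 0.42, nDatasets = 10L,
            depth = 200000L, backgroundFraction = 0.3,
            fivePrimeFidelity = 0.9, starFraction = 0.10,
            loopFraction = 0.02, inconsistentFraction = 0.02,
            matureLen = 22L, loopLen = 15L, seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p
}

.randomSeq <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.revcompDNA <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substitute the bases at `positions` with a different random base
.mutateBases <- function(seq, positions) {
  for (p in positions) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  seq
}

#' Generate a synthetic genome with planted miRNA loci
#'
#' Plants \code{nMirna} precursor hairpins (mature:star stems with a
#' terminal loop and central stem mismatches, verified to pass the
#' discovery structure thresholds after the 10/70 excision) and \code{nDecoy} decoy loci (expressed but
#' unstructured regions emulating abundant degradation fragments) at
#' non-overlapping, well-separated positions. All loci sit on the + strand
#' of a single contig; reads, tags and knock-down counts are derived from
#' the returned truth table.
#'
#' @param config from \code{\link{simulationConfig}}.
#' @param nMirna number of planted miRNA loci (default 20).
#' @param nDecoy number of decoy loci (default 20).
#' @return list with \code{genome} (named \code{DNAStringSet}) and
#'   \code{truth} (data.frame; one row per planted locus with coordinates,
#'   mature/star/loop sequences, class, fidelity and the per-dataset
#'   expected read counts as a matrix column \code{expression}).
#' @export
generateGenomeWithHairpins <- function(config = simulationConfig(),
                                       nMirna = 20L, nDecoy = 20L) {
  nLoci <- nMirna + nDecoy
  if (config$genomeLength < nLoci * 300L)
    stop("genome too short for the requested number of loci")
  set.seed(config$seed)
  genome <- .randomSeq(config$genomeLength, config$gc)

  # evenly spaced, jittered locus anchors with >= 300 nt separation
  slot <- config$genomeLength %/% (nLoci + 1L)
  anchors <- slot * seq_len(nLoci) + sample.int(slot %/% 4L, nLoci, replace = TRUE)
  classes <- sample(rep(c("mirna", "degradation_only"), c(nMirna, nDecoy)))

  mLen <- config$matureLen; lLen <- config$loopLen
  rows <- vector("list", nLoci)
  for (i in seq_len(nLoci)) {
    a <- anchors[i]
    if (classes[i] == "mirna") {
      # precursor: mature + loop + imperfect star; resample until the
      # excised 10/70 candidate passes the structure thresholds
      repeat {
        mature <- .randomSeq(mLen, 0.5)
        loop <- .randomSeq(lLen, 0.4)
        # the star arm carries mismatches spread along the stem, as in real
        # precursors; this also keeps the mature from mapping antisense onto
        # its own star block
        starArm <- .mutateBases(.revcompDNA(mature), c(7L, 11L, 15L))
        pre <- paste0(mature, loop, starArm)
        left <- substr(genome, a - 10L, a - 1L)
        right <- substr(genome, a + nchar(pre), a + nchar(pre) + 70L)
        # the 10/70 excision the pipeline will evaluate (mature as 5' arm)
        hp <- substr(paste0(left, pre, right), 1L, mLen + 80L)
        str <- foldHairpin(hp, TRUE, reportUnconstrained = FALSE)
        pm <- pairMap(str)
        idx <- 11L:(10L + mLen)
        pairsOut <- sum(!is.na(pm[idx]) &
                          (pm[idx] < idx[1L] | pm[idx] > idx[mLen]))
        if (foldEnergy(str) <= -14 && pairsOut >= 14L) break
      }
      substr(genome, a, a + nchar(pre) - 1L) <- pre
      matureStart <- a
      starStart <- a + mLen + lLen
      # star read: duplex partner with 2-nt 3' overhang extends 2 nt past
      # the paired block
      starSeq <- substr(genome, starStart + 2L, starStart + mLen + 1L)
      loopSeq <- loop
      arm <- "5p"
    } else {
      mature <- substr(genome, a, a + mLen - 1L)
      starSeq <- NA_character_
      loopSeq <- NA_character_
      matureStart <- a
      starStart <- NA_integer_
      arm <- NA_character_
    }
    rows[[i]] <- data.frame(
      locus_id = sprintf("locus%02d", i), class = classes[i],
      chrom = "chr1", mature_start = matureStart,
      mature_seq = mature, star_start = starStart, star_seq = starSeq,
      loop_seq = loopSeq, arm = arm,
      five_prime_fidelity = config$fivePrimeFidelity,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)

  # per-dataset expected reads: every locus expressed in >= 2 datasets,
  # log-normal depth
  expr <- matrix(0, nrow = nLoci, ncol = config$nDatasets,
                 dimnames = list(truth$locus_id,
                                 sprintf("ds%02d", seq_len(config$nDatasets))))
  fgPerDataset <- config$depth * (1 - config$backgroundFraction)
  for (i in seq_len(nLoci)) {
    k <- sample(2:config$nDatasets, 1L)
    sets <- sample.int(config$nDatasets, k)
    expr[i, sets] <- exp(rnorm(k, 0, 0.5))
  }
  expr <- sweep(expr, 2L, pmax(colSums(expr), 1e-9), "/") * fgPerDataset
  truth$expression <- expr

  list(genome = Biostrings::DNAStringSet(setNames(genome, "chr1")),
       truth = truth, config = config)
}

# draw 5' jitter offsets for a fidelity level: fraction `fid` at consensus,
# the remainder split evenly between +/-1 and +/-2 (linear interpolation of
# the 90/5/5 scheme)
.jitter5p <- function(n, fid) {
  probs <- c(fid, rep((1 - fid) / 4, 4))
  sample(c(0L, -1L, 1L, -2L, 2L), n, replace = TRUE, prob = probs)
}

.jitter3p <- function(n) {
  sample(0:3, n, replace = TRUE, prob = c(0.55, 0.25, 0.15, 0.05))
}

#' Simulate pooled small RNA datasets from a truth table
#'
#' Mature, star and loop reads are drawn around the planted positions with
#' 5' jitter per the locus fidelity and up to 3 nt of 3' jitter; a small
#' fraction of locus reads is placed at inconsistent offsets; decoy-locus
#' reads are scattered uniformly across the locus; the degradation
#' background is uniform over the genome. Per-dataset presence follows the
#' truth expression matrix.
#'
#' @param sim result of \code{\link{generateGenomeWithHairpins}}.
#' @param seed RNG seed (defaults to the config seed + 1).
#' @return named list of read vectors, one per dataset.
#' @export
simulatePooledDatasets <- function(sim, seed = NULL) {
  config <- sim$config
  truth <- sim$truth
  genomeStr <- as.character(sim$genome[[1L]])
  L <- nchar(genomeStr)
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)
  mLen <- config$matureLen

  datasets <- vector("list", config$nDatasets)
  names(datasets) <- colnames(truth$expression)
  for (d in seq_len(config$nDatasets)) {
    reads <- character(0)
    for (i in seq_len(nrow(truth))) {
      lambda <- truth$expression[i, d]
      if (lambda <= 0) next
      n <- rpois(1L, lambda)
      if (n == 0L) next
      if (truth$class[i] == "mirna") {
        nStar <- rbinom(1L, n, config$starFraction)
        nLoop <- rbinom(1L, n - nStar, config$loopFraction)
        nBad <- rbinom(1L, n - nStar - nLoop, config$inconsistentFraction)
        nMat <- n - nStar - nLoop - nBad
        starts <- integer(0); ends <- integer(0)
        if (nMat > 0L) {
          s <- truth$mature_start[i] + .jitter5p(nMat, truth$five_prime_fidelity[i])
          starts <- c(starts, s); ends <- c(ends, s + mLen - 1L + .jitter3p(nMat))
        }
        if (nStar > 0L) {
          s <- truth$star_start[i] + 2L + .jitter5p(nStar, truth$five_prime_fidelity[i])
          starts <- c(starts, s); ends <- c(ends, s + mLen - 1L + .jitter3p(nStar))
        }
        if (nLoop > 0L) {
          s <- truth$mature_start[i] + mLen + .jitter5p(nLoop, truth$five_prime_fidelity[i])
          starts <- c(starts, s)
          ends <- c(ends, s + config$loopLen - 1L + .jitter3p(nLoop))
        }
        if (nBad > 0L) {
          s <- truth$mature_start[i] + sample(7:15, nBad, replace = TRUE)
          starts <- c(starts, s); ends <- c(ends, s + mLen - 1L)
        }
      } else {
        # decoy: scattered 5' ends across the locus, like local degradation
        s <- truth$mature_start[i] + sample(0:30, n, replace = TRUE)
        starts <- s
        ends <- s + sample(18:24, n, replace = TRUE) - 1L
      }
      ok <- starts >= 1L & ends <= L
      reads <- c(reads, substring(genomeStr, starts[ok], ends[ok]))
    }
    nBg <- round(config$depth * config$backgroundFraction)
    if (nBg > 0L) {
      w <- sample(18:26, nBg, replace = TRUE)
      s <- floor(runif(nBg) * (L - w)) + 1L
      bg <- substring(genomeStr, s, s + w - 1L)
      flip <- runif(nBg) < 0.5
      bg[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(bg[flip])))
      reads <- c(reads, bg)
    }
    datasets[[d]] <- reads
  }
  datasets
}

#' Simulate a biogenesis knock-down pair at the reference level
#'
#' Expected counts of miRNA-class references are scaled by
#' (1 - efficiency) in the treatment library; control-class references are
#' unscaled. Both libraries are multinomially resampled to a fixed depth.
#'
#' @param sim result of \code{\link{generateGenomeWithHairpins}}; its
#'   miRNA-class mature sequences become the miRNA references.
#' @param efficiency knock-down efficiency in [0, 1] (default 0.5).
#' @param nControls number of control references per control class
#'   (default 60).
#' @param depth resampled library depth (default 200,000).
#' @param seed RNG seed.
#' @return data.frame of count records with columns \code{ref_id},
#'   \code{ref_class}, \code{control_count}, \code{treatment_count}.
#' @export
simulateKnockdownPair <- function(sim, efficiency = 0.5, nControls = 60L,
                                  depth = 200000L, seed = NULL) {
  stopifnot(efficiency >= 0, efficiency <= 1)
  truth <- sim$truth
  if (is.null(seed)) seed <- sim$config$seed + 2L
  set.seed(seed)
  mir <- truth[truth$class == "mirna", , drop = FALSE]
  refs <- data.frame(
    ref_id = mir$locus_id,
    ref_class = "novel_mirna",
    expected = rowSums(mir$expression),
    stringsAsFactors = FALSE)
  for (cls in c("control_snoRNA", "control_tRNA")) {
    refs <- rbind(refs, data.frame(
      ref_id = sprintf("%s%02d", cls, seq_len(nControls)),
      ref_class = cls,
      expected = exp(rnorm(nControls, log(mean(refs$expected)), 0.6)),
      stringsAsFactors = FALSE))
  }
  pCtrl <- refs$expected / sum(refs$expected)
  scaled <- ifelse(refs$ref_class == "novel_mirna",
                   refs$expected * (1 - efficiency), refs$expected)
  pTrt <- scaled / sum(scaled)
  data.frame(ref_id = refs$ref_id, ref_class = refs$ref_class,
             control_count = as.integer(stats::rmultinom(1L, depth, pCtrl)),
             treatment_count = as.integer(stats::rmultinom(1L, depth, pTrt)),
             stringsAsFactors = FALSE)
}

#' Simulate CLIP tags around planted loci
#'
#' Tags are centered at the mature and star 5' positions with +/-2 nt
#' jitter; off-target tags are uniform over the genome.
#'
#' @param sim result of \code{\link{generateGenomeWithHairpins}}.
#' @param tagsPerLocus tags per miRNA locus (default 5).
#' @param offTargetRate fraction of additional uniform tags relative to
#'   on-target tags (default 0.1).
#' @param tagLen tag length (default 30).
#' @param seed RNG seed.
#' @return \code{GRanges} of tags (all on the + strand, where loci are
#'   planted, plus uniform off-target tags on both strands).
#' @export
simulateClipTags <- function(sim, tagsPerLocus = 5L, offTargetRate = 0.1,
                             tagLen = 30L, seed = NULL) {
  truth <- sim$truth
  if (is.null(seed)) seed <- sim$config$seed + 3L
  set.seed(seed)
  L <- nchar(as.character(sim$genome[[1L]]))
  mir <- truth[truth$class == "mirna", , drop = FALSE]
  starts <- integer(0); strands <- character(0)
  for (i in seq_len(nrow(mir))) {
    anchors <- c(rep(mir$mature_start[i], ceiling(tagsPerLocus / 2)),
                 rep(mir$star_start[i] + 2L, floor(tagsPerLocus / 2)))
    starts <- c(starts, anchors + sample(-2:2, length(anchors), replace = TRUE))
    strands <- c(strands, rep("+", length(anchors)))
  }
  nOff <- round(length(starts) * offTargetRate)
  if (nOff > 0L) {
    starts <- c(starts, floor(runif(nOff) * (L - tagLen)) + 1L)
    strands <- c(strands, sample(c("+", "-"), nOff, replace = TRUE))
  }
  ok <- starts >= 1L & starts + tagLen - 1L <= L
  GenomicRanges::GRanges("chr1",
                         IRanges::IRanges(starts[ok], width = tagLen),
                         strand = strands[ok])
}

#' Simulate CLASH chimeric reads
#'
#' Generates synthetic transcripts carrying target sites and ligates
#' miRNA + site-context fragments into chimeric reads: canonical reads get
#' sites perfectly complementary to miRNA positions 1-12 (guaranteeing
#' seed pairing), non-seed reads get scrambled sites.
#'
#' @param sim result of \code{\link{generateGenomeWithHairpins}}.
#' @param nCanonical,nNonseed chimera counts per type (defaults 30/10).
#' @param transcriptLen synthetic transcript length (default 300).
#' @param armLen target-arm length on the read (default 30).
#' @param seed RNG seed.
#' @return list with \code{reads} (named character), \code{transcripts}
#'   (named character), \code{mirnas} (named character) and \code{truth}
#'   (data.frame with the planted label per read).
#' @export
simulateChimeras <- function(sim, nCanonical = 30L, nNonseed = 10L,
                             transcriptLen = 300L, armLen = 30L, seed = NULL) {
  truth <- sim$truth
  if (is.null(seed)) seed <- sim$config$seed + 4L
  set.seed(seed)
  mir <- truth[truth$class == "mirna", , drop = FALSE]
  mirnas <- setNames(mir$mature_seq, mir$locus_id)
  n <- nCanonical + nNonseed
  labels <- sample(rep(c("canonical", "non_seed"), c(nCanonical, nNonseed)))
  reads <- character(n); rows <- vector("list", n)
  transcripts <- character(0)
  for (i in seq_len(n)) {
    mi <- sample.int(length(mirnas), 1L)
    m <- mirnas[[mi]]
    tx <- .randomSeq(transcriptLen, 0.45)
    sitePos <- sample(50:(transcriptLen - 50L), 1L)
    if (labels[i] == "canonical") {
      site <- .revcompDNA(substr(m, 1L, 12L))
    } else {
      repeat {
        site <- .randomSeq(12L, 0.5)
        # make sure the scrambled site cannot seed-pair
        dup <- duplexMFE(m, site)
        if (sum(dup@mirnaPaired[2:8]) < 5L) break
      }
    }
    substr(tx, sitePos, sitePos + nchar(site) - 1L) <- site
    txId <- sprintf("tx%03d", i)
    transcripts[txId] <- tx
    fragStart <- sitePos - sample(5:10, 1L)
    frag <- substr(tx, fragStart, fragStart + armLen - 1L)
    reads[i] <- paste0(m, frag)
    rows[[i]] <- data.frame(read_id = sprintf("chimera%03d", i),
                            mirna_id = names(mirnas)[mi], transcript_id = txId,
                            label = labels[i], stringsAsFactors = FALSE)
  }
  names(reads) <- sprintf("chimera%03d", seq_len(n))
  list(reads = reads, transcripts = transcripts, mirnas = mirnas,
       truth = do.call(rbind, rows))
}

#' Simulate derived-allele-frequency tables
#'
#' Background frequencies follow a neutral-like rare-skewed Beta
#' distribution; focal frequencies come from the same family with the
#' shape down-weighted toward rare alleles by the constraint shift
#' (shift 0 reproduces the background distribution exactly).
#'
#' @param nFocal,nBackground SNP counts.
#' @param constraintShift non-negative constraint strength (default 0).
#' @param seed RNG seed.
#' @return data.frame with columns \code{position},
#'   \code{derived_allele_frequency}, \code{stratum}.
#' @export
simulateDAF <- function(nFocal, nBackground, constraintShift = 0, seed = 1L) {
  stopifnot(constraintShift >= 0)
  if (nFocal < 1L) stop("empty focal set")
  set.seed(seed)
  aBg <- 0.25
  focal <- rbeta(nFocal, aBg / (1 + constraintShift), 1)
  background <- rbeta(nBackground, aBg, 1)
  data.frame(
    position = seq_len(nFocal + nBackground),
    derived_allele_frequency = c(focal, background),
    stratum = rep(c("focal", "background"), c(nFocal, nBackground)),
    stringsAsFactors = FALSE)
}

#' Write simulated datasets to FASTA files
#'
#' One plain FASTA per dataset plus a manifest TSV, for exercising the
#' file-based interfaces.
#'
#' @param datasets named list of read vectors.
#' @param dir output directory (created if needed).
#' @return path of the written manifest.
#' @export
writeDatasetFasta <- function(datasets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(datasets))
  for (i in seq_along(datasets)) {
    x <- Biostrings::DNAStringSet(datasets[[i]])
    names(x) <- sprintf("%s_r%d", names(datasets)[i], seq_along(x))
    paths[i] <- file.path(dir, paste0(names(datasets)[i], ".fa"))
    Biostrings::writeXStringSet(x, paths[i])
  }
  man <- file.path(dir, "manifest.tsv")
  write.table(data.frame(dataset_id = names(datasets),
                         path = basename(paths), format = "fasta"),
              man, sep = "\t", quote = FALSE, row.names = FALSE)
  man
}
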