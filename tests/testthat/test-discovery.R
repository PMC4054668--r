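test_that("exact mapping is strand-aware and caps multi-mapping", {
  set.seed(17)
  uniq <- randomDNA(22)
  multi <- randomDNA(20)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  revOnly <- randomDNA(21)
  genome <- c(chr1 = paste0(randomDNA(100), uniq, randomDNA(50),
                            strrep(multi, 6), randomDNA(50), rc(revOnly),
                            randomDNA(40)))
  gr <- mapExact(c(uniq, multi, revOnly), genome, maxLoci = 5L)
  seqs <- S4Vectors::mcols(gr)$sequence
  expect_identical(sum(seqs == uniq), 1L)
  expect_identical(S4Vectors::mcols(gr)$n_mappings[seqs == uniq], 1L)
  expect_identical(as.character(BiocGenerics::strand(gr[seqs == uniq])), "+")
  # planted at 6 loci with maxLoci = 5: no mappings at all
  expect_false(multi %in% seqs)
  # present only as reverse complement: single minus-strand mapping
  expect_identical(sum(seqs == revOnly), 1L)
  expect_identical(as.character(BiocGenerics::strand(gr[seqs == revOnly])), "-")
  expect_error(mapExact(uniq, Biostrings::DNAStringSet()), "empty genome")
})

test_that("prevalence filtering applies the two-dataset rule", {
  x <- randomDNA(20, seed = 1); y <- randomDNA(20, seed = 2)
  z <- randomDNA(20, seed = 4)
  pool <- collapsePool(list(d1 = c(x, y), d2 = c(x, z), d3 = c(x, z),
                            d4 = c(x, z), d5 = x))
  expect_setequal(poolSequences(dropLowPrevalence(pool, 2L)), c(x, z))
  expect_identical(dropLowPrevalence(pool, 1L), pool)
  expect_identical(nrow(dropLowPrevalence(collapsePool(list(d1 = x)), 2L)), 0L)
})

test_that("overlap resolution keeps the highest-weight sequence", {
  # A (prevalence 4, 1 locus, w=4) overlaps B (prevalence 6, 2 loci, w=3)
  a <- randomDNA(20, seed = 5); b <- randomDNA(20, seed = 6)
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 110, 300), width = 20), strand = "+")
  S4Vectors::mcols(gr)$sequence <- c(a, b, b)
  S4Vectors::mcols(gr)$n_mappings <- c(1L, 2L, 2L)
  res <- resolveOverlaps(gr, setNames(c(4L, 6L), c(a, b)))
  expect_identical(unique(S4Vectors::mcols(res)$sequence), a)

  # non-overlapping sequences are both retained
  gr2 <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(100, 200), width = 20),
                                strand = "+")
  S4Vectors::mcols(gr2)$sequence <- c(a, b)
  S4Vectors::mcols(gr2)$n_mappings <- c(1L, 1L)
  res2 <- resolveOverlaps(gr2, setNames(c(2L, 2L), c(a, b)))
  expect_setequal(unique(S4Vectors::mcols(res2)$sequence), c(a, b))

  # chain A-B-C with descending weights: A and C retained
  cc <- randomDNA(20, seed = 7)
  gr3 <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(100, 112, 124), width = 20),
                                strand = "+")
  S4Vectors::mcols(gr3)$sequence <- c(a, b, cc)
  S4Vectors::mcols(gr3)$n_mappings <- c(1L, 1L, 1L)
  res3 <- resolveOverlaps(gr3, setNames(c(6L, 4L, 2L), c(a, b, cc)))
  expect_setequal(unique(S4Vectors::mcols(res3)$sequence), c(a, cc))
})

test_that("overlap resolution agrees with the naive greedy reference", {
  for (seed in 1:60) {
    inst <- randomOverlapInstance(sample(2:15, 1), seed = 1000 + seed)
    gr <- instanceToGRanges(inst)
    res <- resolveOverlaps(gr, setNames(inst$seqs$prevalence,
                                        inst$seqs$sequence))
    expect_identical(sort(unique(S4Vectors::mcols(res)$sequence)),
                     oracleResolveOverlaps(inst$seqs, inst$mappings),
                     info = paste("seed", seed))
  }
})

test_that("annotation exclusion removes same-strand 1-nt overlaps only", {
  a <- randomDNA(20, seed = 8); b <- randomDNA(20, seed = 9)
  cc <- randomDNA(20, seed = 10)
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100, 200, 300), width = 20),
                               strand = c("+", "+", "+"))
  S4Vectors::mcols(gr)$sequence <- c(a, b, cc)
  S4Vectors::mcols(gr)$n_mappings <- rep(1L, 3)
  excl <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(50, 219), c(119, 230)), strand = c("+", "+"))
  res <- excludeAnnotated(gr, excl)  # a inside; b 1-nt edge overlap
  expect_identical(unique(S4Vectors::mcols(res)$sequence), cc)
  # opposite-strand overlap only: retained
  exclMinus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(300, 320),
                                      strand = "-")
  expect_identical(length(excludeAnnotated(gr, exclMinus)), 3L)
  # chromosome name mismatch: warning, treated as no overlap
  exclChr <- GenomicRanges::GRanges("chrX", IRanges::IRanges(100, 120),
                                    strand = "+")
  expect_warning(res3 <- excludeAnnotated(gr, exclChr), "chromosome")
  expect_identical(length(res3), 3L)
})

test_that("hairpin excision produces 10/70 and 70/10 hypotheses", {
  set.seed(23)
  genome <- c(chr1 = randomDNA(400))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, width = 22),
                               strand = "+")
  S4Vectors::mcols(gr)$sequence <- substr(genome[["chr1"]], 200, 221)
  S4Vectors::mcols(gr)$n_mappings <- 1L
  hp <- exciseCandidateHairpins(gr, genome)
  expect_identical(length(hp), 2L)
  expect_identical(unique(nchar(S4Vectors::mcols(hp)$hairpin_seq)), 102L)
  expect_setequal(S4Vectors::mcols(hp)$arm, c("5p", "3p"))
  expect_identical(S4Vectors::mcols(hp)$seed_start,
                   c(11L, 71L)[match(S4Vectors::mcols(hp)$arm, c("5p", "3p"))])
  # minus-strand mapping: reverse-complemented genomic context
  grM <- gr; BiocGenerics::strand(grM) <- "-"
  hpM <- exciseCandidateHairpins(grM, genome)
  i5 <- which(S4Vectors::mcols(hpM)$arm == "5p")
  expected <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(genome[["chr1"]], 200 - 70, 221 + 10))))
  expect_identical(S4Vectors::mcols(hpM)$hairpin_seq[i5], expected)
  # mapping close to the contig start: the 70-upstream hypothesis is
  # impossible, the 10-upstream one survives
  grEdge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, width = 22),
                                   strand = "+")
  S4Vectors::mcols(grEdge)$sequence <- substr(genome[["chr1"]], 51, 72)
  S4Vectors::mcols(grEdge)$n_mappings <- 1L
  hpE <- exciseCandidateHairpins(grEdge, genome)
  expect_identical(length(hpE), 1L)
  expect_match(attr(hpE, "skipped"), "flank beyond contig", all = FALSE)
})

test_that("Dicer consistency passes at the 10 percent boundary", {
  hp <- perfectHairpin(30L)  # 30-bp stem, loop 8: mature arm 1..30
  hp <- paste0(randomDNA(10, seed = 3), hp, randomDNA(10))
  # nine reads at the mature 5' position, one offset mid-loop by 7
  reads <- data.frame(start = c(rep(11L, 9), 18L), width = 22L, weight = 1)
  res <- evaluateDicerConsistency(hp, reads)
  expect_true(res$pass)
  expect_equal(res$consistent_fraction, 0.9)
  # 8 of 10 scattered: fail
  reads2 <- data.frame(start = c(11L, 11L, seq(15L, 50L, by = 5L)),
                       width = 18L, weight = 1)
  res2 <- evaluateDicerConsistency(hp, reads2)
  expect_false(res2$pass)
  # no reads
  expect_false(evaluateDicerConsistency(hp, NULL)$pass)
  expect_identical(evaluateDicerConsistency(hp, NULL)$reason, "no support")
})

test_that("star reads with the 2-nt 3' overhang geometry support the star window", {
  sim <- smallSim()
  truth <- sim$sim$truth
  mir <- truth[truth$class == "mirna", ][1, ]
  g <- as.character(sim$sim$genome[[1]])
  hp <- substr(g, mir$mature_start - 10L, mir$mature_start + 91L)
  mStart <- 11L
  starLocal <- mir$star_start + 2L - mir$mature_start + 11L
  reads <- data.frame(start = c(rep(mStart, 8), rep(starLocal, 2)),
                      width = 22L, weight = 1)
  res <- evaluateDicerConsistency(hp, reads)
  expect_true(res$pass)
  expect_true(res$star_supported)
  expect_equal(res$star_window[1], starLocal)
})

test_that("locus resolution keeps the most prevalent seed and is deterministic", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100, 140), width = 102),
                               strand = "+")
  S4Vectors::mcols(gr)$prevalence <- c(4L, 2L)
  S4Vectors::mcols(gr)$sequence <- c("AAAA", "CCCC")
  res <- resolveHairpinLoci(gr)
  expect_identical(S4Vectors::mcols(res)$prevalence, 4L)
  # single hairpin: unchanged
  expect_identical(length(resolveHairpinLoci(gr[1])), 1L)
  # equal prevalence: deterministic leftmost, regardless of input order
  S4Vectors::mcols(gr)$prevalence <- c(3L, 3L)
  r1 <- resolveHairpinLoci(gr)
  r2 <- resolveHairpinLoci(rev(gr))
  expect_identical(BiocGenerics::start(r1), 100L)
  expect_identical(BiocGenerics::start(r1), BiocGenerics::start(r2))
})

test_that("discovery recovers planted loci and rejects decoys end to end", {
  fix <- smallSim()
  cand <- runDiscovery(fix$datasets, fix$sim$genome)
  truth <- fix$sim$truth
  mir <- truth[truth$class == "mirna", ]
  st <- BiocGenerics::start(cand); en <- BiocGenerics::end(cand)
  recovered <- vapply(mir$mature_start, function(a)
    any(st <= a & en >= a + 21L), logical(1))
  expect_gte(sum(recovered), nrow(mir) - 1L)
  decoys <- truth[truth$class == "degradation_only", ]
  fp <- vapply(decoys$mature_start, function(a)
    any(st <= a + 30L & en >= a), logical(1))
  expect_identical(sum(fp), 0L)
  # reported candidates never overlap on the same strand
  ov <- GenomicRanges::findOverlaps(cand, cand, ignore.strand = FALSE)
  expect_true(all(S4Vectors::queryHits(ov) == S4Vectors::subjectHits(ov)))
  # every candidate meets the documented guarantees
  mc <- S4Vectors::mcols(cand)
  expect_true(all(mc$prevalence >= 2L))
  expect_true(all(mc$energy <= -14))
  expect_true(all(mc$consistent_fraction >= 0.9))
})

test_that("a locus expressed in a single dataset is not reported", {
  fix <- smallSim()
  sim <- fix$sim
  mir <- which(sim$truth$class == "mirna")[1]
  # restrict this locus to one dataset
  sim$truth$expression[mir, ] <- c(sim$truth$expression[mir, 1] +
                                     sum(sim$truth$expression[mir, -1]),
                                   rep(0, ncol(sim$truth$expression) - 1L))
  ds <- simulatePooledDatasets(sim, seed = 99L)
  cand <- runDiscovery(ds, sim$genome)
  a <- sim$truth$mature_start[mir]
  st <- BiocGenerics::start(cand); en <- BiocGenerics::end(cand)
  expect_false(any(st <= a & en >= a + 21L))
})

test_that("empty input yields an empty candidate table", {
  genome <- c(chr1 = randomDNA(1000, seed = 2))
  pool <- collapsePool(list(d1 = randomDNA(20, seed = 3)))
  cand <- runDiscovery(pool, genome)
  expect_identical(length(cand), 0L)
})

test_that("discovery output is invariant to dataset and read order", {
  fix <- smallSim()
  ds <- fix$datasets
  shuffled <- lapply(rev(ds), function(r) rev(r))
  c1 <- runDiscovery(ds, fix$sim$genome)
  c2 <- runDiscovery(shuffled, fix$sim$genome)
  expect_identical(BiocGenerics::start(c1), BiocGenerics::start(c2))
  expect_identical(S4Vectors::mcols(c1)$sequence, S4Vectors::mcols(c2)$sequence)
})

test_that("saturation subsampling is monotone and respects dataset mode", {
  fix <- smallSim()
  ds <- fix$datasets
  res <- saturationSimulation(ds, fix$sim$genome,
                              fractions = c(0.3, 1), seed = 7L)
  full <- length(runDiscovery(ds, fix$sim$genome))
  expect_identical(res$n_candidates[res$fraction == 1], full)
  expect_lte(res$n_candidates[1], res$n_candidates[2])
  # dataset mode: retained count within one of the expected mean
  resD <- saturationSimulation(ds, fix$sim$genome, mode = "datasets",
                               fractions = 0.5, seed = 11L)
  expect_lte(abs(resD$n_retained_datasets - length(ds) * 0.5), 1)
})
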