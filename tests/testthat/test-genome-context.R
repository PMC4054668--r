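test_that("homolog evaluation requires structure and a human seed", {
  hp <- perfectHairpin(25L, seed = 81L)
  mature <- substr(hp, 1, 22)
  seeds <- c(seedOf(mature), seedOf(revcompRNA(mature)))
  expect_true(evaluateHomolog(hp, seeds)$present)
  # both seed regions mutated but stem intact elsewhere: absent
  res <- evaluateHomolog(hp, c("AAAAAAA", "AAAAAAA"))
  expect_false(res$present)
  expect_false(res$seed_found)
  # stem disrupted below the pairing minimum: absent despite the seed
  weak <- paste0(substr(hp, 1, 10), strrep("A", 40), seeds[1])
  resW <- evaluateHomolog(weak, seeds)
  expect_false(resW$present)
  expect_true(resW$seed_found)
})

test_that("origin assignment follows parsimony with a recent tie-break", {
  tree <- testSpeciesTree()
  leaves <- tree$tip.label
  mk <- function(present, missing = character()) {
    p <- setNames(rep(FALSE, length(leaves)), leaves)
    p[present] <- TRUE
    p[missing] <- NA
    p
  }
  # present only in human: most recent branch point
  expect_identical(assignOrigin(mk("human"), tree)$label, "human")
  # present in all species: the root clade
  expect_identical(assignOrigin(mk(leaves), tree)$label, "vertebrate")
  # human + old world monkeys only: old-world-monkey ancestor
  expect_identical(assignOrigin(mk(c("human", "chimp", "baboon")), tree)$label,
                   "oldworldmonkey")
  # missing species are ignored: human + chimp with baboon unaligned
  expect_identical(assignOrigin(mk(c("human", "chimp"),
                                   missing = "baboon"), tree)$label,
                   "hominid")
  # no non-missing species beyond human
  expect_identical(assignOrigin(mk("human", missing = setdiff(leaves, "human")),
                                tree)$label, "human")
})

test_that("origin assignment matches exhaustive state enumeration", {
  tree <- testSpeciesTree()
  leaves <- tree$tip.label
  set.seed(91)
  for (i in 1:120) {
    pres <- setNames(sample(c(TRUE, FALSE, NA), length(leaves), replace = TRUE,
                            prob = c(0.4, 0.5, 0.1)), leaves)
    got <- assignOrigin(pres, tree)
    ora <- oracleAssignOrigin(pres, tree)
    expect_identical(got$node, ora$node, info = paste(i))
    expect_identical(got$cost, ora$cost, info = paste(i))
  }
})

test_that("the floating hierarchy resolves annotation conflicts", {
  pos <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 500, 900),
                                                         width = 1),
                                strand = "+")
  tracks <- list(
    tRNA = GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 150),
                                  strand = "+"),
    "repeat" = GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 150),
                                      strand = "+"),
    snoRNA = GenomicRanges::GRanges("chr1", IRanges::IRanges(450, 550),
                                    strand = "+"),
    rRNA = GenomicRanges::GRanges("chr1", IRanges::IRanges(450, 550),
                                  strand = "+"))
  labels <- resolveAnnotation(pos, tracks)
  expect_identical(labels, c("tRNA", "snoRNA", "intergenic"))
  expect_error(resolveAnnotation(pos, list(bogus = tracks[[1]])), "unknown")
})

test_that("genomic source attribution weights mappings inversely", {
  tracks <- list(
    "repeat" = GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1100),
                                      strand = "+"))
  # two mappings, one repeat one intergenic: 0.5 / 0.5
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1040, 5000),
                                                        width = 22),
                               strand = "+")
  S4Vectors::mcols(gr)$n_mappings <- c(2L, 2L)
  frac <- assignGenomicSource(gr, tracks)
  expect_equal(frac[["repeat"]], 0.5)
  expect_equal(frac[["intergenic"]], 0.5)
  expect_equal(sum(frac), 1, tolerance = 1e-9)
  # even-length mapping center under the floor rule:
  # start0 = 9, end0 = 19 -> center0 = floor(27/2) = 13 (1-based 14)
  grE <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, width = 10),
                                strand = "+")
  S4Vectors::mcols(grE)$n_mappings <- 1L
  edge <- list("repeat" = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(14, 14), strand = "+"))
  expect_equal(assignGenomicSource(grE, edge)[["repeat"]], 1)
  # intron/exon subdivision of protein-coding genes
  pc <- list(protein_coding = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(100, 400), strand = "+"))
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 150),
                                  strand = "+")
  grI <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(120, 290),
                                                         width = 21),
                                strand = "+")
  S4Vectors::mcols(grI)$n_mappings <- c(1L, 1L)
  fr <- assignGenomicSource(grI, pc, exons = exons)
  expect_equal(fr[["protein_coding_exon"]], 0.5)
  expect_equal(fr[["protein_coding_intron"]], 0.5)
})

test_that("prevalence profiling demands exact sequence identity", {
  s <- randomDNA(22, seed = 7)
  datasets <- list(d1 = c(s, randomDNA(20)), d2 = s, d3 = randomDNA(22),
                   d4 = paste0(substr(s, 1, 21), "A"))
  expect_identical(prevalenceProfile(s, datasets), 2L)
  expect_identical(prevalenceProfile(substr(s, 1, 21), datasets), 0L)
  expect_identical(prevalenceProfile("ACGT", list(d1 = "AAAA")), 0L)
  pool <- collapsePool(datasets)
  expect_identical(prevalenceProfile(s, pool), 2L)
})

test_that("TPM normalization is count over total times a million", {
  expect_equal(tpm(5, 1e6), 5.0)
  expect_equal(tpm(0, 1e6), 0.0)
  expect_equal(tpm(82, 1e7), 8.2)
  expect_error(tpm(5, 0), "positive")
})

test_that("processing precision applies the nine-out-of-ten rule", {
  reads <- data.frame(start = c(rep(11L, 9), 14L), width = 22L)
  res <- processingPrecision(reads, "5p")
  expect_equal(res$fraction_at_consensus, 0.9)
  expect_true(res$precise)
  expect_identical(res$consensus, 11L)
  # uniform over 4 start positions: imprecise
  resU <- processingPrecision(data.frame(start = rep(c(1L, 2L, 3L, 4L), 5),
                                         width = 20L), "5p")
  expect_equal(resU$fraction_at_consensus, 0.25)
  expect_false(resU$precise)
  expect_identical(resU$consensus, 1L)  # tie toward the 5'-most coordinate
  # single read
  res1 <- processingPrecision(data.frame(start = 5L, width = 20L), "3p")
  expect_equal(res1$fraction_at_consensus, 1.0)
  expect_true(res1$precise)
  # order invariance
  shuffled <- reads[sample(nrow(reads)), , drop = FALSE]
  expect_identical(processingPrecision(shuffled, "5p")$fraction_at_consensus,
                   res$fraction_at_consensus)
})
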