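test_that("CLIP tag overlap reports per-hairpin representative offsets", {
  hairpins <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 2000, 3000), width = 102),
    strand = c("+", "+", "-"))
  names(hairpins) <- c("h1", "h2", "h3")
  tags <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1010, 2000, 2004, 2008, 2979), width = 30),
    strand = c("+", "+", "+", "+", "-"))
  res <- overlapClipTags(hairpins, tags, seed = 4L)
  expect_identical(res$offset[res$hairpin_id == "h1"], 10L)
  expect_identical(res$n_supporting_tags[res$hairpin_id == "h2"], 3L)
  # minus-strand: offset measured from the hairpin 3' genomic end
  expect_identical(res$offset[res$hairpin_id == "h3"], 93L)
  # a tag 21 nt away with window 20 gives no support
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000 - 21 - 30,
                                                         width = 30),
                                strand = "+")
  resFar <- overlapClipTags(hairpins[1], far)
  expect_identical(nrow(resFar), 0L)
  # representative choice is reproducible under the seed
  res2 <- overlapClipTags(hairpins, tags, seed = 4L)
  expect_identical(res, res2)
})

test_that("genomic control sampling scales with hairpin mappings", {
  set.seed(3)
  genome <- c(chr1 = randomDNA(20000), chr2 = randomDNA(10000))
  ctl <- sampleGenomicControls(genome, nMappings = 12L, nPerMapping = 100L,
                               seed = 5L)
  expect_identical(length(ctl$regions), 1200L)
  # uniform strand sampling
  frac <- mean(as.character(BiocGenerics::strand(ctl$regions)) == "+")
  expect_lt(abs(frac - 0.5), 0.05)
  # tags confined to hairpins leave control support near zero
  tags <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, width = 30),
                                 strand = "+")
  ctl2 <- sampleGenomicControls(genome, nMappings = 5L, tags = tags, seed = 6L)
  expect_lte(ctl2$scaled_support, 0.05)
})

test_that("mature-tag matching requires 5' identity with 3' tolerance", {
  mature <- c(mirA = "TAGCTTATCAGACTGATGTTGA")
  expect_identical(matchMatureTags("TAGCTTATCAGACTGATGTTGA", mature)[1], "mirA")
  # 3 nt shorter at the 3' end: still a match
  expect_identical(matchMatureTags(substr(mature, 1, 19), mature)[1], "mirA")
  # 4 nt shorter: too much
  expect_identical(length(matchMatureTags(substr(mature, 1, 18), mature)), 0L)
  # 3 nt longer at the 3' end: a match
  expect_identical(matchMatureTags(paste0(mature, "ACG"), mature)[1], "mirA")
  # 1 nt shifted at the 5' end: no match
  expect_identical(length(matchMatureTags(
    paste0("A", substr(mature, 1, 21)), mature)), 0L)
})

test_that("IP presence summaries count detected references", {
  ip <- setNames(c(rep(1, 17), rep(0, 3)), sprintf("m%d", 1:20))
  input <- setNames(rep(5, 20), sprintf("m%d", 1:20))
  expect_equal(unname(ipPresenceSummary(ip, input)), 0.85)
  expect_equal(unname(ipPresenceSummary(input, input)), 1)
  expect_equal(unname(ipPresenceSummary(ip * 0, input)), 0)
  # per-class split
  classes <- setNames(rep(c("known", "novel"), each = 10), sprintf("m%d", 1:20))
  byClass <- ipPresenceSummary(ip, input, classes)
  expect_equal(byClass[["known"]], 1)
  expect_equal(byClass[["novel"]], 0.7)
})

test_that("chimera calling reconstructs read arms and clusters sites", {
  set.seed(51)
  m <- c(mirX = randomDNA(22))
  tx <- c(txA = randomDNA(300))
  frag <- substr(tx, 101, 130)
  reads <- c(r1 = paste0(m, frag),
             r2 = paste0(m, substr(tx, 103, 132)),  # site offset by 2
             r3 = frag)                              # target arm only
  res <- callChimeras(reads, m, tx)
  expect_identical(sort(unique(res$read_id)), c("r1", "r2"))
  expect_identical(unique(res$mirna_id), "mirX")
  expect_identical(unique(res$interaction_id), res$interaction_id[1])
  # arms reconstruct the read exactly
  for (i in seq_len(nrow(res))) {
    read <- reads[[res$read_id[i]]]
    arm1 <- substr(read, 1, res$mirna_span_end[i])
    arm2 <- substr(read, res$mirna_span_end[i] + 1L, nchar(read))
    expect_identical(paste0(arm1, arm2), read)
    expect_identical(unname(substr(tx, res$site_start[i] + 1L,
                                   res$site_end[i])), arm2)
  }
  # 3'-trimmed miRNA arm still called
  resTrim <- callChimeras(c(r4 = paste0(substr(m, 1, 19), frag)), m, tx)
  expect_identical(nrow(resTrim), 1L)
  expect_identical(resTrim$mirna_span_end, 19L)
  # arms below the minimum are never called
  resShort <- callChimeras(c(r5 = paste0(substr(m, 1, 10), frag)), m, tx)
  expect_identical(nrow(resShort), 0L)
})

test_that("seed classes follow the canonical / imperfect / non-seed rules", {
  set.seed(61)
  m <- randomRNA(22)
  # site perfectly complementary to positions 1-12
  canonical <- duplexMFE(m, revcompRNA(substr(m, 1, 12)))
  expect_identical(classifySeedInteraction(canonical), "canonical_7mer_seed")
  # poly-A site pairs nothing
  polyA <- duplexMFE("CCCCCCCCCCCCCCCCCCCCCC", strrep("A", 30))
  expect_identical(classifySeedInteraction(polyA), "non_seed")
  # constructed duplex with exactly 5 of 7 seed positions paired, one GU
  dup <- new("DuplexHybrid", mirna = m, site = "NNNN", energy = -5,
             mirnaPaired = c(FALSE, rep(TRUE, 5), FALSE, FALSE, rep(FALSE, 14)),
             mirnaWatsonCrick = c(FALSE, rep(TRUE, 4), FALSE, FALSE, FALSE,
                                  rep(FALSE, 14)),
             sitePartner = rep(NA_integer_, 22))
  expect_identical(classifySeedInteraction(dup), "seed_with_imperfections")
})

test_that("planted chimera labels are recovered from synthetic reads", {
  fix <- smallSim()
  ch <- simulateChimeras(fix$sim, nCanonical = 20L, nNonseed = 5L, seed = 8L)
  res <- callChimeras(ch$reads, ch$mirnas, ch$transcripts)
  called <- res[!duplicated(res$read_id), ]
  merged <- merge(called, ch$truth, by = "read_id")
  expect_gte(nrow(merged), 24L)  # nearly every read called
  canon <- merged[merged$label == "canonical", ]
  expect_gte(mean(canon$seed_class == "canonical_7mer_seed"), 0.95)
  expect_identical(nrow(callChimeras(character(), ch$mirnas, ch$transcripts)),
                   0L)
})

test_that("shuffled-miRNA controls rank a perfect duplex as extreme", {
  set.seed(71)
  m <- randomRNA(20)
  res <- shuffledEnergyControl(m, revcompRNA(m), nShuffles = 200L, seed = 9L)
  expect_lte(res$p, 2 / 201)
  expect_identical(length(res$shuffled), 200L)
  expect_error(shuffledEnergyControl(m, revcompRNA(m), nShuffles = 0L),
               "nShuffles")
})
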