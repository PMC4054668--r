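test_that("generation is deterministic and respects the truth contract", {
  cfg <- simulationConfig(genomeLength = 30000L, nDatasets = 3L,
                          depth = 5000L, seed = 17L)
  s1 <- generateGenomeWithHairpins(cfg, nMirna = 3L, nDecoy = 3L)
  s2 <- generateGenomeWithHairpins(cfg, nMirna = 3L, nDecoy = 3L)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  expect_identical(nrow(s1$truth), 6L)
  expect_setequal(unique(s1$truth$class), c("mirna", "degradation_only"))
  # every locus is expressed in at least two datasets
  expect_true(all(rowSums(s1$truth$expression > 0) >= 2L))
  # datasets also reproduce bit for bit under the seed
  d1 <- simulatePooledDatasets(s1)
  d2 <- simulatePooledDatasets(s2)
  expect_identical(d1, d2)
  expect_error(generateGenomeWithHairpins(
    simulationConfig(genomeLength = 1000L), 3L, 3L), "too short")
})

test_that("planted hairpins satisfy the discovery structure thresholds", {
  fix <- smallSim()
  truth <- fix$sim$truth
  g <- as.character(fix$sim$genome[[1]])
  mir <- truth[truth$class == "mirna", ]
  for (i in seq_len(nrow(mir))) {
    hp <- substr(g, mir$mature_start[i] - 10L, mir$mature_start[i] + 91L)
    str <- foldHairpin(hp, TRUE, reportUnconstrained = FALSE)
    expect_lte(foldEnergy(str), -14)
    pm <- pairMap(str)
    idx <- 11L:32L
    pairsOut <- sum(!is.na(pm[idx]) & (pm[idx] < 11L | pm[idx] > 32L))
    expect_gte(pairsOut, 14L)
  }
  # mature and star sequences form the planted duplex arms
  expect_true(all(nchar(mir$mature_seq) == 22L))
  expect_true(all(nchar(mir$star_seq) == 22L))
})

test_that("a fidelity-1 locus emits a single 5' start", {
  cfg <- simulationConfig(genomeLength = 30000L, nDatasets = 2L,
                          depth = 3000L, seed = 19L, fivePrimeFidelity = 1,
                          backgroundFraction = 0)
  sim <- generateGenomeWithHairpins(cfg, nMirna = 1L, nDecoy = 0L)
  ds <- simulatePooledDatasets(sim)
  m <- sim$truth$mature_seq[1]
  # all mature-derived reads share the consensus 5' start: every read whose
  # first 18 nt match the mature prefix starts with exactly that prefix
  pre <- substr(m, 1, 18)
  reads <- unlist(ds)
  matPrefix <- reads[substr(reads, 1, 18) == pre]
  expect_gt(length(matPrefix), 0L)
  shifted <- substr(sim$genome[[1]], sim$truth$mature_start[1] - 1L,
                    sim$truth$mature_start[1] + 16L)
  expect_false(as.character(shifted) %in% substr(reads, 1, 18))
})

test_that("zero background means every read overlaps a planted locus", {
  cfg <- simulationConfig(genomeLength = 30000L, nDatasets = 2L,
                          depth = 2000L, seed = 23L, backgroundFraction = 0)
  sim <- generateGenomeWithHairpins(cfg, nMirna = 2L, nDecoy = 1L)
  ds <- simulatePooledDatasets(sim)
  g <- as.character(sim$genome[[1]])
  loci <- substring(g, sim$truth$mature_start - 30L,
                    sim$truth$mature_start + 90L)
  hit <- vapply(unlist(ds), function(r)
    any(vapply(loci, grepl, logical(1), pattern = r, fixed = TRUE)),
    logical(1))
  expect_true(all(hit))
})

test_that("knock-down simulation scales only miRNA classes", {
  fix <- smallSim()
  rec <- simulateKnockdownPair(fix$sim, efficiency = 0.5, seed = 31L)
  expect_setequal(unique(rec$ref_class),
                  c("novel_mirna", "control_snoRNA", "control_tRNA"))
  # controls only (efficiency irrelevant): normalization shift near zero
  fcs <- normalizeToControls(computeFoldChanges(rec))
  expect_lt(abs(attr(fcs, "shift")), 0.3)
  mir <- fcs$f_normalized[fcs$ref_class == "novel_mirna"]
  ctrl <- fcs$f_normalized[fcs$ref_class != "novel_mirna"]
  expect_lt(median(mir), median(ctrl) - 0.5)
})

test_that("CLIP tag simulation puts the offset mode at the mature position", {
  fix <- smallSim()
  tags <- simulateClipTags(fix$sim, tagsPerLocus = 7L, offTargetRate = 0,
                           seed = 41L)
  truth <- fix$sim$truth
  mir <- truth[truth$class == "mirna", ]
  hairpins <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(mir$mature_start - 10L, width = 102L),
    strand = "+")
  names(hairpins) <- mir$locus_id
  res <- overlapClipTags(hairpins, tags, seed = 6L)
  expect_identical(nrow(res), nrow(mir))
  # representative offsets cluster near the mature offset (10) or star
  tab <- table(res$offset)
  expect_lte(min(abs(as.integer(names(tab)[which.max(tab)]) - 10L)), 2L)
  # with no off-target tags, genomic control support is near zero
  ctl <- sampleGenomicControls(fix$sim$genome, nMappings = nrow(mir),
                               tags = tags, seed = 7L)
  expect_lte(ctl$scaled_support, 1)
})

test_that("DAF simulation responds to the constraint shift", {
  d0 <- simulateDAF(300L, 300L, 0, seed = 51L)
  expect_setequal(unique(d0$stratum), c("focal", "background"))
  p0 <- wilcoxonConstraintTest(
    d0$derived_allele_frequency[d0$stratum == "focal"],
    d0$derived_allele_frequency[d0$stratum == "background"])
  expect_gt(p0, 0.01)
  dS <- simulateDAF(500L, 500L, 1.5, seed = 52L)
  pS <- wilcoxonConstraintTest(
    dS$derived_allele_frequency[dS$stratum == "focal"],
    dS$derived_allele_frequency[dS$stratum == "background"])
  expect_lt(pS, 0.01)
  expect_error(simulateDAF(0L, 10L, 0), "empty focal")
})
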