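# Shared small-scale synthetic fixtures, built once per test session.

smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(genomeLength = 50000L, nDatasets = 4L,
                              depth = 20000L, seed = 3L)
      sim <- generateGenomeWithHairpins(cfg, nMirna = 5L, nDecoy = 5L)
      cache <<- list(sim = sim, datasets = simulatePooledDatasets(sim))
    }
    cache
  }
})

randomDNA <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randomRNA <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# a clean synthetic hairpin: stem + tetraloop + reverse complement
perfectHairpin <- function(stemLen = 36L, seed = 11L) {
  set.seed(seed)
  stem <- randomDNA(stemLen)
  paste0(stem, "GCTTCGGC", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(stem))))
}
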