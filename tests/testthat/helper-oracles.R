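# Independent reference implementations used to validate package algorithms.
# These are deliberately naive: direct definitions, no shared code with the
# implementations they check.

# ---- greedy overlap resolution, naive O(n^2) re-check ----------------------
# seqs: data.frame(sequence, prevalence); mappings: list (per sequence) of
# data.frames (chrom, start, end, strand). Returns retained sequence strings.
oracleResolveOverlaps <- function(seqs, mappings) {
  nmap <- vapply(mappings, nrow, integer(1))
  weight <- seqs$prevalence / nmap
  leftChrom <- vapply(mappings, function(m) min(m$chrom), character(1))
  leftStart <- vapply(mappings, function(m)
    min(m$start[m$chrom == min(m$chrom)]), numeric(1))
  ord <- order(-weight, -seqs$prevalence, leftChrom, leftStart, seqs$sequence,
               method = "radix")
  kept <- integer(0)
  overlapsAny <- function(a, b) {
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$strand[i] == b$strand[j] &&
          a$start[i] <= b$end[j] && b$start[j] <= a$end[i]) return(TRUE)
    }
    FALSE
  }
  for (i in ord) {
    conflict <- any(vapply(kept, function(k)
      overlapsAny(mappings[[i]], mappings[[k]]), logical(1)))
    if (!conflict) kept <- c(kept, i)
  }
  sort(seqs$sequence[kept])
}

# random instance generator for overlap resolution
randomOverlapInstance <- function(nSeq, seed) {
  set.seed(seed)
  seqs <- data.frame(
    sequence = vapply(seq_len(nSeq), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
      character(1)),
    prevalence = sample.int(10L, nSeq, replace = TRUE),
    stringsAsFactors = FALSE)
  mappings <- lapply(seq_len(nSeq), function(i) {
    k <- sample.int(3L, 1L)
    data.frame(chrom = sample(c("chr1", "chr2"), k, TRUE),
               start = sample.int(200L, k, TRUE),
               strand = sample(c("+", "-"), k, TRUE),
               stringsAsFactors = FALSE) |>
      transform(end = start + 19L)
  })
  list(seqs = seqs, mappings = mappings)
}

# package-input form of the same instance
instanceToGRanges <- function(inst) {
  df <- do.call(rbind, lapply(seq_along(inst$mappings), function(i)
    cbind(inst$mappings[[i]], sequence = inst$seqs$sequence[i])))
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$sequence <- df$sequence
  nm <- table(df$sequence)
  S4Vectors::mcols(gr)$n_mappings <- as.integer(nm[df$sequence])
  gr
}

# ---- parsimony origin by exhaustive ancestral-state enumeration ------------
# For branch point X on the human lineage: cost(X) = 1 gain + minimal losses
# within the clade (enumerating all presence states of internal nodes in X,
# forbidding regains) + one gain per present leaf outside X.
oracleAssignOrigin <- function(presence, tree, humanLeaf = "human") {
  ntip <- length(tree$tip.label)
  pres <- presence[tree$tip.label]
  pres[match(humanLeaf, tree$tip.label)] <- TRUE
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  childrenOf <- split(tree$edge[, 2], tree$edge[, 1])
  descTips <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(childrenOf[[as.character(node)]], descTips))
  }
  descNodes <- function(node) {  # internal nodes within clade, incl. node
    if (node <= ntip) return(integer(0))
    c(node, unlist(lapply(childrenOf[[as.character(node)]], descNodes)))
  }
  path <- humanTip <- match(humanLeaf, tree$tip.label)
  node <- humanTip; root <- ntip + 1L
  while (node != root) { node <- parent[node]; path <- c(path, node) }

  minLosses <- function(X) {
    if (X <= ntip) return(0L)
    internals <- descNodes(X)
    tips <- descTips(X)
    best <- Inf
    for (mask in 0:(2^length(internals) - 1L)) {
      st <- integer(ntip + tree$Nnode)  # 0 absent, 1 present
      st[internals] <- bitwAnd(mask %/% 2^(seq_along(internals) - 1L), 1L)
      if (st[X] != 1L) next  # gain happened at X
      for (t in tips) st[t] <- ifelse(is.na(pres[t]), NA, as.integer(pres[t]))
      losses <- 0L; ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
        if (!(a %in% internals)) next
        if (b <= ntip && is.na(st[b])) next  # missing species: free
        if (st[a] == 0L && st[b] == 1L) { ok <- FALSE; break }  # regain
        if (st[a] == 1L && st[b] == 0L) losses <- losses + 1L
      }
      if (ok && losses < best) best <- losses
    }
    best
  }

  presentTips <- which(!is.na(pres) & pres)
  best <- NULL
  for (X in path) {
    outside <- setdiff(presentTips, descTips(X))
    cost <- 1 + minLosses(X) + length(outside)
    if (is.null(best) || cost < best$cost) best <- list(node = X, cost = cost)
  }
  best
}

# ---- exact one-sided rank-sum p by full enumeration ------------------------
oracleWilcoxonLess <- function(focal, background) {
  pooled <- c(focal, background)
  n <- length(focal); N <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  combos <- utils::combn(N, n)
  stats <- apply(combos, 2L, function(idx) sum(r[idx]))
  mean(stats <= obs)
}

# ---- fixed 10-leaf species tree along a human lineage ----------------------
testSpeciesTree <- function() {
  ape::read.tree(text = paste0(
    "(((((((human,chimp)hominid,baboon)oldworldmonkey,tarsier)primate,",
    "treeshrew)simian,armadillo)placental,platypus)mammal,",
    "(frog,(zebrafish,fugu)fish)nonmammal)vertebrate;"))
}
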