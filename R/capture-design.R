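#' Design a 120-nt capture bait for a small RNA target
#'
#' The hybridized region is the insert flanked by the tail of the 5'
#' adapter and the head of the 3' adapter, its total length held constant
#' at \code{hybridLen} for every target in a design: the adapter
#' contribution \code{hybridLen - insert length} is split as evenly as
#' possible between the two adapters (any odd nucleotide goes to the 3'
#' adapter side). The bait is the reverse complement of the hybridized
#' region, 3'-padded to \code{baitLen} with an inert spacer that is
#' validated to share no \code{>= 8}-nt substring with either adapter.
#'
#' @param insertSeq target small RNA sequence (DNA alphabet).
#' @param adapter5,adapter3 ligation adapter sequences.
#' @param baitLen total bait length (default 120).
#' @param hybridLen constant hybridized length H (default 60;
#'   insert length <= H <= baitLen).
#' @param targetId identifier carried through to the design table.
#' @return list with \code{target_id}, \code{bait_sequence},
#'   \code{hybridized_len}, \code{adapter5_used}, \code{adapter3_used},
#'   \code{spacer_len}.
#' @export
designBait <- function(insertSeq, adapter5, adapter3, baitLen = 120L,
                       hybridLen = 60L, targetId = "target") {
  ins <- nchar(insertSeq)
  if (ins > hybridLen) stop("insert longer than the hybridized length")
  if (hybridLen > baitLen) stop("hybridLen cannot exceed baitLen")
  pad <- hybridLen - ins
  a5 <- pad %/% 2L
  a3 <- pad - a5  # odd nucleotide goes to the 3'-adapter side
  if (a5 > nchar(adapter5) || a3 > nchar(adapter3))
    stop("adapters too short to supply the hybridized flanks")
  tail5 <- if (a5 > 0) substr(adapter5, nchar(adapter5) - a5 + 1L,
                              nchar(adapter5)) else ""
  head3 <- if (a3 > 0) substr(adapter3, 1L, a3) else ""
  hybridRegion <- paste0(tail5, insertSeq, head3)
  bait <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(hybridRegion)))
  spacerLen <- baitLen - hybridLen
  spacer <- .baitSpacer(spacerLen, c(adapter5, adapter3))
  list(target_id = targetId,
       bait_sequence = paste0(bait, spacer),
       hybridized_len = hybridLen,
       adapter5_used = a5, adapter3_used = a3,
       spacer_len = spacerLen)
}

# fixed non-genomic spacer: ACT repeat, checked for adapter complementarity
.baitSpacer <- function(len, adapters) {
  if (len == 0L) return("")
  spacer <- paste(rep_len(c("A", "C", "T"), len), collapse = "")
  for (ad in adapters) {
    if (nchar(spacer) >= 8L && nchar(ad) >= 8L) {
      for (i in seq_len(nchar(spacer) - 7L)) {
        if (grepl(substr(spacer, i, i + 7L), ad, fixed = TRUE))
          stop("spacer shares an 8-mer with an adapter")
      }
    }
  }
  spacer
}

#' Design baits for a set of targets
#'
#' @param targets named character vector of target small RNA sequences.
#' @param adapter5,adapter3,baitLen,hybridLen as in \code{\link{designBait}}.
#' @return data.frame, one row per target, with the fields of
#'   \code{\link{designBait}}.
#' @export
designBaitSet <- function(targets, adapter5, adapter3, baitLen = 120L,
                          hybridLen = 60L) {
  if (is.null(names(targets)))
    names(targets) <- sprintf("target%d", seq_along(targets))
  rows <- lapply(names(targets), function(id)
    as.data.frame(designBait(targets[[id]], adapter5, adapter3, baitLen,
                             hybridLen, id), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Detection saturation with progressive sequencing depth
#'
#' Shuffles the reads once under the seed, then reports, for each depth,
#' how many targets are matched (5' end exact, up to \code{tol} nt length
#' difference at the 3' end) among the first \code{depth} reads.
#'
#' @param reads character vector of preprocessed reads.
#' @param targetSet named character vector of target mature sequences.
#' @param depths increasing read depths to report.
#' @param tol 3' length tolerance (default 3).
#' @param seed RNG seed for the one-time shuffle.
#' @return data.frame with columns \code{depth}, \code{n_detected};
#'   non-decreasing in depth.
#' @export
detectionSaturation <- function(reads, targetSet, depths, tol = 3L, seed = 1L) {
  if (is.null(names(targetSet)))
    names(targetSet) <- sprintf("target%d", seq_along(targetSet))
  set.seed(seed)
  reads <- sample(reads)
  # first read index at which each target is detected
  firstHit <- rep(NA_integer_, length(targetSet))
  readLen <- nchar(reads)
  for (j in seq_along(targetSet)) {
    m <- targetSet[[j]]
    Lm <- nchar(m)
    ok <- abs(readLen - Lm) <= tol
    if (!any(ok)) next
    L <- pmin(readLen, Lm)
    hit <- ok & substring(reads, 1L, L) == substring(m, 1L, L)
    if (any(hit)) firstHit[j] <- which.max(hit)
  }
  data.frame(depth = depths,
             n_detected = vapply(depths, function(d)
               sum(!is.na(firstHit) & firstHit <= d), integer(1)))
}

#' Capture enrichment and fold-change agreement
#'
#' For matched captured/uncaptured libraries over two conditions: computes
#' the per-target depth enrichment and the condition log2 fold-changes on
#' miRNA-mapped-TPM normalization, applying the >= \code{minSum}-sum and
#' no-zero filters independently with and without capture, and reports the
#' Pearson correlation of the two fold-change vectors over the targets that
#' survive both filters.
#'
#' @param countsWith,countsWithout data.frames with columns \code{ref_id},
#'   \code{cond1}, \code{cond2}: read counts with and without capture.
#' @param minSum minimum cond1+cond2 sum in each library type (default 30).
#' @return list with \code{records} (per-target depth_fold on cond1+cond2
#'   totals), \code{fold_changes} (per-target log2 FC with and without
#'   capture, TPM-normalized), \code{agreement} (correlation).
#' @export
enrichmentAndQuantitation <- function(countsWith, countsWithout, minSum = 30L) {
  stopifnot(all(c("ref_id", "cond1", "cond2") %in% colnames(countsWith)),
            all(c("ref_id", "cond1", "cond2") %in% colnames(countsWithout)))
  ids <- intersect(countsWith$ref_id, countsWithout$ref_id)
  w <- countsWith[match(ids, countsWith$ref_id), ]
  wo <- countsWithout[match(ids, countsWithout$ref_id), ]
  totW <- w$cond1 + w$cond2
  totWo <- wo$cond1 + wo$cond2
  records <- data.frame(ref_id = ids, count_with = totW, count_without = totWo,
                        depth_fold = ifelse(totWo > 0, totW / totWo, NA_real_),
                        stringsAsFactors = FALSE)
  keep <- totW >= minSum & totWo >= minSum &
    w$cond1 > 0 & w$cond2 > 0 & wo$cond1 > 0 & wo$cond2 > 0
  # TPM against reads mapping to the targets (miRNA-mapped totals)
  tpmW1 <- tpm(w$cond1, sum(w$cond1)); tpmW2 <- tpm(w$cond2, sum(w$cond2))
  tpmWo1 <- tpm(wo$cond1, sum(wo$cond1)); tpmWo2 <- tpm(wo$cond2, sum(wo$cond2))
  fc <- data.frame(ref_id = ids,
                   fc_with = log2(tpmW2 / tpmW1),
                   fc_without = log2(tpmWo2 / tpmWo1),
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  agreement <- if (nrow(fc) >= 3L) cor(fc$fc_with, fc$fc_without) else NA_real_
  list(records = records, fold_changes = fc, agreement = agreement)
}
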