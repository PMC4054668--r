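#' Compute knock-down log2 fold-changes
#'
#' For each reference the control and treatment read counts are summed; if
#' the sum is below \code{minSum} (default 30) the reference is excluded.
#' References with a zero count in either condition are also excluded (the
#' log2 ratio is undefined at zero). Otherwise
#' f = log2(treatment / control).
#'
#' @param records data.frame with columns \code{ref_id}, \code{ref_class},
#'   \code{control_count}, \code{treatment_count}.
#' @param minSum minimum control+treatment sum (default 30).
#' @return data.frame with columns \code{ref_id}, \code{ref_class},
#'   \code{f}; excluded records are in the \code{"excluded"} attribute with
#'   a reason.
#' @examples
#' computeFoldChanges(data.frame(ref_id = "a", ref_class = "known_mirna",
#'                               control_count = 30, treatment_count = 15))
#' @export
computeFoldChanges <- function(records, minSum = 30L) {
  stopifnot(all(c("ref_id", "ref_class", "control_count", "treatment_count")
                %in% colnames(records)))
  s <- records$control_count + records$treatment_count
  zero <- records$control_count == 0 | records$treatment_count == 0
  lowsum <- s < minSum
  keep <- !lowsum & !zero
  out <- data.frame(ref_id = records$ref_id[keep],
                    ref_class = records$ref_class[keep],
                    f = log2(records$treatment_count[keep] /
                             records$control_count[keep]),
                    stringsAsFactors = FALSE)
  excl <- data.frame(ref_id = records$ref_id[!keep],
                     reason = ifelse(lowsum[!keep], "sum below minimum",
                                     "zero count"),
                     stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  out
}

#' Normalize fold-changes to control sequences
#'
#' Shifts every fold-change so that the location (median by default) of the
#' control-class fold-changes becomes exactly zero, correcting for unequal
#' sequencing depth between the compared libraries.
#'
#' @param fcs data.frame from \code{\link{computeFoldChanges}}.
#' @param controlClasses character vector of control \code{ref_class}
#'   values (default snoRNA/tRNA/miscRNA controls).
#' @param center \code{"median"} (robust default) or \code{"mean"}.
#' @return \code{fcs} with an added \code{f_normalized} column; the shift is
#'   in the \code{"shift"} attribute.
#' @export
normalizeToControls <- function(fcs,
                                controlClasses = c("control_snoRNA",
                                                   "control_tRNA",
                                                   "control_miscRNA"),
                                center = c("median", "mean")) {
  center <- match.arg(center)
  ctrl <- fcs$f[fcs$ref_class %in% controlClasses]
  if (!length(ctrl)) stop("no control-class records to normalize to")
  shift <- if (center == "median") median(ctrl) else mean(ctrl)
  fcs$f_normalized <- fcs$f - shift
  attr(fcs, "shift") <- shift
  fcs
}

#' Subsampling significance of a group's down-regulation
#'
#' Draws \code{nIter} random subsets of the control fold-changes, each the
#' size of the group, and compares the group statistic against the subset
#' statistics. The p-value is one-sided toward down-regulation with an
#' add-one correction: p = (1 + #\{subset statistic <= observed\}) /
#' (1 + nIter).
#'
#' @param groupFcs numeric fold-changes of the group of interest.
#' @param controlFcs numeric fold-changes of the control sequences.
#' @param nIter number of random subsets.
#' @param statistic \code{"median"} or \code{"fraction_down"} (fraction
#'   below the 30 percent down-regulation cut).
#' @param seed RNG seed.
#' @param pctThreshold threshold used by \code{"fraction_down"}.
#' @return one-sided p-value.
#' @export
subsampleSignificance <- function(groupFcs, controlFcs, nIter = 10000L,
                                  statistic = c("median", "fraction_down"),
                                  seed = 1L, pctThreshold = 30) {
  statistic <- match.arg(statistic)
  if (!length(groupFcs)) stop("empty group")
  if (!length(controlFcs)) stop("empty control set")
  statFun <- if (statistic == "median") median else
    function(x) mean(x <= log2(1 - pctThreshold / 100))
  obs <- statFun(groupFcs)
  if (nIter <= 0L) return(1)
  set.seed(seed)
  k <- length(groupFcs)
  replace <- k > length(controlFcs)
  hits <- 0L
  for (b in seq_len(nIter)) {
    sub <- sample(controlFcs, k, replace = replace)
    s <- statFun(sub)
    if (statistic == "median") { if (s <= obs) hits <- hits + 1L }
    else { if (s >= obs) hits <- hits + 1L }
  }
  (1 + hits) / (1 + nIter)
}

#' Fraction of references substantially down-regulated
#'
#' Fraction of normalized fold-changes at or below
#' log2(1 - pctThreshold/100); with the default 30 percent threshold the
#' cut is about -0.515 log2 units.
#'
#' @param fNormalized numeric vector of normalized log2 fold-changes.
#' @param pctThreshold percent down-regulation defining "substantial"
#'   (default 30).
#' @return fraction in [0, 1].
#' @export
fractionDownregulated <- function(fNormalized, pctThreshold = 30) {
  if (!length(fNormalized)) return(0)
  mean(fNormalized <= log2(1 - pctThreshold / 100))
}

#' One-sided Wilcoxon test for selective constraint
#'
#' Tests whether the focal derived-allele frequencies are stochastically
#' smaller than the background frequencies (an enrichment of rare derived
#' alleles indicates purifying selection). Uses the exact rank-sum
#' distribution for small tie-free samples and the tie-corrected normal
#' approximation otherwise.
#'
#' @param focal,background numeric vectors of derived allele frequencies in
#'   [0, 1].
#' @return one-sided p-value (alternative: focal < background).
#' @export
wilcoxonConstraintTest <- function(focal, background) {
  if (!length(focal) || !length(background)) stop("both samples must be non-empty")
  stopifnot(all(focal >= 0 & focal <= 1), all(background >= 0 & background <= 1))
  ties <- anyDuplicated(c(focal, background)) > 0L
  exact <- min(length(focal), length(background)) <= 10L && !ties
  suppressWarnings(
    wilcox.test(focal, background, alternative = "less", exact = exact,
                correct = !exact)$p.value)
}

#' Summarise a knock-down comparison end to end
#'
#' Convenience wrapper: fold-changes, control normalization, per-class
#' medians, the fraction substantially down-regulated among miRNA classes,
#' and the subsampling p-value of the miRNA classes against the controls.
#'
#' @param records count records (see \code{\link{computeFoldChanges}}).
#' @param mirnaClasses,controlClasses class labels defining the two groups.
#' @param minSum,nIter,seed passed through.
#' @return list with \code{fcs}, \code{median_mirna_fc},
#'   \code{fraction_down}, \code{p_value}.
#' @export
knockdownSummary <- function(records,
                             mirnaClasses = c("known_mirna", "novel_mirna",
                                              "mirtron"),
                             controlClasses = c("control_snoRNA",
                                                "control_tRNA",
                                                "control_miscRNA"),
                             minSum = 30L, nIter = 10000L, seed = 1L) {
  fcs <- computeFoldChanges(records, minSum)
  fcs <- normalizeToControls(fcs, controlClasses)
  mir <- fcs$f_normalized[fcs$ref_class %in% mirnaClasses]
  ctrl <- fcs$f_normalized[fcs$ref_class %in% controlClasses]
  list(fcs = fcs,
       median_mirna_fc = if (length(mir)) median(mir) else NA_real_,
       fraction_down = fractionDownregulated(mir),
       p_value = if (length(mir) && length(ctrl))
         subsampleSignificance(mir, ctrl, nIter, seed = seed) else NA_real_)
}
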