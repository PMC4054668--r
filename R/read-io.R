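#' Clip 3' adapters with a cascading fallback search
#'
#' Primary pass: the first \code{primaryMatchLen} nucleotides of the adapter
#' are searched anywhere in the read and the read is truncated at the
#' leftmost occurrence. Reads without a primary match enter a cascade: for
#' k = \code{primaryMatchLen} - 1 down to \code{minMatchLen}, if the first k
#' adapter nucleotides equal the last k read nucleotides, those k
#' nucleotides are removed and the cascade stops. Reads with no match at any
#' k are retained, but not clipped. N bases never match adapter bases.
#'
#' @param reads character vector of read sequences.
#' @param adapter the 3' adapter sequence (A/C/G/T/U only).
#' @param primaryMatchLen length of the primary adapter prefix (default 8).
#' @param minMatchLen smallest suffix length tried by the cascade
#'   (default 6; the cascade is open-ended in principle but short matches
#'   clip random sequence).
#' @return character vector of clipped reads, same length and order.
#' @examples
#' clipAdapterCascade("ACGTACGTACGTTGGAATTC", "TGGAATTCTCGGGTGCCAAG")
#' @export
clipAdapterCascade <- function(reads, adapter, primaryMatchLen = 8L,
                               minMatchLen = 6L) {
  stopifnot(is.character(reads), length(adapter) == 1L)
  adapter <- toupper(adapter)
  if (!grepl("^[ACGTU]+$", adapter))
    stop("adapter must contain only A/C/G/T/U")
  if (primaryMatchLen > nchar(adapter))
    stop("primaryMatchLen exceeds adapter length")
  if (minMatchLen < 1L) stop("minMatchLen must be >= 1")
  out <- reads
  pref <- substr(adapter, 1L, primaryMatchLen)
  pos <- regexpr(pref, out, fixed = TRUE)
  hit <- pos > 0L
  out[hit] <- substr(out[hit], 1L, pos[hit] - 1L)
  todo <- !hit
  k <- primaryMatchLen - 1L
  while (k >= minMatchLen && any(todo)) {
    prefk <- substr(adapter, 1L, k)
    n <- nchar(out)
    cand <- todo & n >= k
    suff <- substr(out[cand], n[cand] - k + 1L, n[cand])
    clip <- suff == prefk
    idx <- which(cand)[clip]
    out[idx] <- substr(out[idx], 1L, nchar(out[idx]) - k)
    todo[idx] <- FALSE
    k <- k - 1L
  }
  out
}

#' Discard reads shorter than a minimum length
#'
#' @param reads character vector of read sequences.
#' @param minLen minimum retained length (default 18 nt).
#' @return the reads of length >= \code{minLen}, order preserved.
#' @export
filterMinLength <- function(reads, minLen = 18L) {
  stopifnot(minLen >= 1L)
  reads[nchar(reads) >= minLen]
}

#' Collapse pooled datasets into a prevalence-annotated pool
#'
#' Collapses reads from multiple datasets to unique sequences, recording the
#' per-dataset copy number and the prevalence: the number of datasets in
#' which each sequence was detected.
#'
#' @param datasets a named list; each element is either a character vector of
#'   reads (one entry per copy) or a data.frame with columns
#'   \code{sequence} and \code{count}.
#' @return a \linkS4class{SmallRNAPool}.
#' @export
collapsePool <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("datasets must be named by dataset id")
  tabs <- lapply(names(datasets), function(id) {
    d <- datasets[[id]]
    if (is.character(d)) {
      dt <- data.table::data.table(sequence = d)[, list(count = .N), by = sequence]
    } else {
      dt <- data.table::as.data.table(d[, c("sequence", "count")])
      dt <- dt[, list(count = sum(count)), by = sequence]
    }
    dt[, dataset_id := id]
    dt
  })
  long <- data.table::rbindlist(tabs)
  seqs <- sort(unique(long$sequence))
  ids <- names(datasets)
  counts <- matrix(0L, nrow = length(seqs), ncol = length(ids),
                   dimnames = list(seqs, ids))
  counts[cbind(match(long$sequence, seqs), match(long$dataset_id, ids))] <-
    as.integer(long$count)
  totals <- colSums(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(prevalence = as.integer(rowSums(counts > 0L))),
    colData = S4Vectors::DataFrame(total_reads = as.integer(totals),
                                   row.names = ids))
  new("SmallRNAPool", se)
}

#' Read small RNA sequences from FASTA/FASTQ
#'
#' Reads a (optionally collapsed) FASTA or 4-line Phred+33 FASTQ file and
#' returns one sequence per read copy. Collapsed FASTA headers of the form
#' \code{>seqid_xN} expand to N copies.
#'
#' @param path file path.
#' @param format one of \code{"fasta"}, \code{"collapsed_fasta"},
#'   \code{"fastq"}.
#' @return character vector of read sequences.
#' @export
readSmallRNA <- function(path, format = c("fasta", "collapsed_fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fastq") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    return(as.character(x, use.names = FALSE))
  }
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x, use.names = FALSE)
  if (format == "collapsed_fasta") {
    nm <- names(x)
    counts <- suppressWarnings(as.integer(sub(".*_x(\\d+)$", "\\1", nm)))
    counts[is.na(counts)] <- 1L
    seqs <- rep(seqs, counts)
  }
  seqs
}

#' Write a pool as collapsed FASTA
#'
#' One record per unique sequence with header \code{>seq<i>_x<total count>}.
#'
#' @param pool a \linkS4class{SmallRNAPool}.
#' @param path output path.
#' @export
writeCollapsedFasta <- function(pool, path) {
  counts <- SummarizedExperiment::assay(pool, "counts")
  total <- rowSums(counts)
  x <- Biostrings::DNAStringSet(rownames(pool))
  names(x) <- sprintf("seq%d_x%d", seq_len(nrow(pool)), total)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the collapsed pool as a TSV table
#'
#' Columns: sequence, prevalence, then one count column per dataset.
#'
#' @param pool a \linkS4class{SmallRNAPool}.
#' @param path output path.
#' @export
writePoolTSV <- function(pool, path) {
  counts <- SummarizedExperiment::assay(pool, "counts")
  df <- data.frame(sequence = rownames(pool),
                   prevalence = prevalence(pool),
                   counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest and load its datasets
#'
#' The manifest is a TSV with columns \code{dataset_id}, \code{path},
#' \code{format}; relative paths are resolved against the manifest location.
#'
#' @param manifestPath path to the manifest TSV.
#' @param clip optional adapter string; when given, reads are adapter-clipped
#'   and length-filtered on load.
#' @param minLen minimum read length applied when \code{clip} is given.
#' @return named list of character read vectors.
#' @export
readDatasetManifest <- function(manifestPath, clip = NULL, minLen = 18L) {
  man <- read.table(manifestPath, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("dataset_id", "path", "format") %in% colnames(man)))
  base <- dirname(manifestPath)
  out <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    reads <- readSmallRNA(p, man$format[i])
    if (!is.null(clip)) {
      reads <- clipAdapterCascade(reads, clip)
      reads <- filterMinLength(reads, minLen)
    }
    reads
  })
  names(out) <- man$dataset_id
  out
}
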