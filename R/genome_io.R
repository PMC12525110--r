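#' Read and sanitize genome sequences from a FASTA file
#'
#' Reads a (plain or gzip-compressed) FASTA file into a [Biostrings::DNAStringSet],
#' uppercasing soft-masked residues and validating that every residue is one of
#' A, C, G, T or N.  Record order is preserved.
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @return A `DNAStringSet`; `sum(width(.))` is the total genome length in bp.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt", ">b", "NNGG"), fa)
#' g <- read_genome(fa)
#' width(g)          # 4 4
#' as.character(g[[1]])  # "ACGT"
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  g <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(g) == 0L) stop("no sequences in FASTA file: ", path)
  g <- Biostrings::DNAStringSet(toupper(g))
  validate_genome(g, path)
  # keep only the first whitespace-delimited token of each header, UCSC-style
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

validate_genome <- function(g, label = "genome") {
  freq <- Biostrings::alphabetFrequency(g)
  bad <- freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"), drop = FALSE]
  offender <- which(rowSums(bad) > 0L)
  if (length(offender)) {
    sym <- colnames(bad)[which(bad[offender[1L], ] > 0L)[1L]]
    stop("illegal residue '", sym, "' in record ", offender[1L],
         " ('", names(g)[offender[1L]], "') of ", label,
         ": only A/C/G/T/N (any case) are accepted")
  }
  invisible(g)
}

#' Write genome sequences to FASTA
#'
#' @param g A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  Biostrings::writeXStringSet(g, filepath = path, format = "fasta")
  invisible(path)
}

#' Excise intervals from a sequence
#'
#' Removes 0-based half-open `[start, end)` intervals from a single sequence
#' and returns the complement segments as separate sequences, so that no
#' artificial k-mer windows are later counted across excision junctions.
#'
#' @param g A `DNAString` or single-sequence `DNAStringSet`.
#' @param intervals Two-column matrix or data.frame of 0-based half-open
#'   `start`, `end` coordinates, sorted and non-overlapping.
#' @return A `DNAStringSet` of the complement segments (zero-width segments are
#'   dropped).  If the whole sequence is excised the result has length 0 and a
#'   warning is raised.
#' @export
excise_intervals <- function(g, intervals) {
  if (methods::is(g, "DNAStringSet")) {
    stopifnot(length(g) == 1L)
    nm <- names(g)
    g <- g[[1L]]
  } else nm <- "seq"
  L <- length(g)
  iv <- as.matrix(as.data.frame(intervals))
  if (NROW(iv) == 0L) {
    out <- Biostrings::DNAStringSet(g)
    names(out) <- nm
    return(out)
  }
  iv <- matrix(as.numeric(iv[, 1:2]), ncol = 2L)
  if (any(iv[, 1L] < 0) || any(iv[, 2L] > L) || any(iv[, 1L] >= iv[, 2L]))
    stop("intervals must satisfy 0 <= start < end <= sequence length")
  if (is.unsorted(iv[, 1L], strictly = TRUE) && NROW(iv) > 1L)
    stop("intervals must be sorted by start")
  if (NROW(iv) > 1L && any(iv[-1L, 1L] < iv[-NROW(iv), 2L]))
    stop("intervals must be non-overlapping")
  # complement segments, 0-based half-open
  starts <- c(0, iv[, 2L])
  ends <- c(iv[, 1L], L)
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) {
    warning("all residues excised; returning empty sequence set")
    return(Biostrings::DNAStringSet())
  }
  segs <- Biostrings::DNAStringSet(g, start = starts + 1L, end = ends)
  names(segs) <- paste0(nm, "_seg", seq_along(segs))
  segs
}

#' Read and write BED interval files
#'
#' Thin wrappers around [rtracklayer::import.bed()] / [rtracklayer::export.bed()].
#' `intervals_to_granges()` converts the package's 0-based half-open interval
#' data.frames to the 1-based closed `GRanges` convention and back.
#'
#' @param path BED file path.
#' @return `read_bed` returns a data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
write_bed <- function(intervals, path) {
  gr <- intervals_to_granges(intervals)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
}

#' Write a table as TSV
#'
#' @param x Data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
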