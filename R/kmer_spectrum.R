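#' Count k-mer occurrences across a genome
#'
#' Slides a window of `k` bases along each sequence of the genome and counts
#' every window consisting solely of A/C/G/T, on the given strand only (no
#' reverse-complement merging).  Windows containing N are skipped, and windows
#' never span sequence boundaries, so multi-chromosome genomes are counted
#' per sequence and summed.
#'
#' Motifs are indexed 0..4^k - 1 by their base-4 expansion with A=0, C=1,
#' G=2, T=3 and the first base as the most significant digit; this equals the
#' alphabetical order of the motif strings.
#'
#' @param g A `DNAStringSet` (or single `DNAString`).
#' @param k Motif length (default 8).
#' @return An object of class `kmer_counts`: a list with `k`, `counts`
#'   (named integer vector of length 4^k, names are motif strings in
#'   alphabetical order) and `windows` (total valid windows counted).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "AAAAAAAAAA"))
#' ct <- count_kmers(g, k = 8)
#' ct$counts[["AAAAAAAA"]]  # 3
#' @export
count_kmers <- function(g, k = 8L) {
  if (methods::is(g, "DNAString")) g <- Biostrings::DNAStringSet(g)
  stopifnot(k >= 1L)
  if (length(g) == 0L || sum(Biostrings::width(g)) == 0L)
    stop("genome is empty")
  if (all(Biostrings::width(g) < k)) {
    warning("k = ", k, " exceeds every sequence length; all counts are zero")
    counts <- integer(4^k)
    names(counts) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  } else {
    m <- Biostrings::oligonucleotideFrequency(g, width = k, step = 1L)
    counts <- as.integer(colSums(m))
    names(counts) <- colnames(m)
  }
  structure(list(k = as.integer(k), counts = counts,
                 windows = sum(counts)),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("k-mer count table: k =", x$k, "|", length(x$counts), "motifs |",
      format(x$windows, big.mark = ","), "windows counted\n")
  cat("  nullomers:", sum(x$counts == 0L),
      "| max count:", max(x$counts), "\n")
  invisible(x)
}

#' Frequency-of-appearance spectrum of a k-mer count table
#'
#' For each appearance count x, the FA value is the number of motifs in the
#' chosen universe whose genome occurrence count equals x, divided by 4^k
#' (the full motif universe size, regardless of the subset considered).
#' x = 0 records the nullomers of the universe.
#'
#' @param tab A `kmer_counts` object.
#' @param universe Optional integer vector of 0-based motif indices defining a
#'   subset (e.g. a stratum); `NULL` means the full 4^k universe.
#' @return An object of class `fa_spectrum`: a list with `k`, a data.frame
#'   `spectrum` (columns `x`, `n`, `fa`, including the x = 0 row), and
#'   `universe_size`.
#' @export
fa_spectrum <- function(tab, universe = NULL) {
  stopifnot(inherits(tab, "kmer_counts"))
  h <- tab$counts
  if (!is.null(universe)) {
    if (length(universe) == 0L) stop("empty universe")
    if (any(universe < 0L) || any(universe >= length(h)))
      stop("universe indices out of range for k = ", tab$k)
    h <- h[universe + 1L]
  }
  denom <- 4^tab$k
  xs <- sort(unique(h))
  n <- as.integer(table(factor(h, levels = xs)))
  if (!0L %in% xs) { xs <- c(0L, xs); n <- c(0L, n) }
  structure(list(k = tab$k,
                 spectrum = data.frame(x = xs, n = n, fa = n / denom),
                 universe_size = length(h)),
            class = "fa_spectrum")
}

#' @export
print.fa_spectrum <- function(x, ...) {
  sp <- x$spectrum
  cat("FA spectrum: k =", x$k, "| universe", x$universe_size, "motifs\n")
  cat("  nullomers:", sp$n[sp$x == 0L],
      "| appearance counts 1..", max(sp$x), "\n", sep = "")
  invisible(x)
}

# Materialize a spectrum on the dense x-grid 1..max(x) (bin size 1, x = 0
# excluded): the form smoothing and peak finding operate on.
dense_fa <- function(spec) {
  sp <- spec$spectrum
  sp <- sp[sp$x >= 1L, , drop = FALSE]
  if (nrow(sp) == 0L) stop("spectrum has no motifs with count >= 1")
  xmax <- max(sp$x)
  y <- numeric(xmax)
  y[sp$x] <- sp$fa
  list(x = seq_len(xmax), y = y)
}

#' Moving-average smoothing of an FA spectrum
#'
#' Materializes the spectrum on a dense grid of bin size 1 from x = 1 to the
#' maximum observed appearance count (nullomers excluded), then applies a
#' centered moving average with the valid-window (truncating) convention,
#' `passes` times.  With an even window the re-centered x grid falls on
#' half-integers.
#'
#' @param spec An `fa_spectrum`, or a list with numeric `x`, `y` grids.
#' @param window Moving-average width (default 10).
#' @param passes Number of smoothing rounds (default 1).
#' @return An object of class `smoothed_curve`: list with `x`, `y`, `window`,
#'   `passes`.
#' @export
smooth_spectrum <- function(spec, window = 10L, passes = 1L) {
  stopifnot(window >= 1L, passes >= 0L)
  g <- if (inherits(spec, "fa_spectrum")) dense_fa(spec) else spec
  x <- as.numeric(g$x); y <- as.numeric(g$y)
  if (window > 1L) {
    for (i in seq_len(passes)) {
      if (length(y) < window)
        stop("smoothing window (", window, ") exceeds grid length (",
             length(y), ")")
      y <- zoo::rollmean(y, k = window, align = "center")
      x <- zoo::rollmean(x, k = window, align = "center")
    }
  }
  structure(list(x = x, y = y, window = as.integer(window),
                 passes = as.integer(passes)),
            class = "smoothed_curve")
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat("smoothed FA curve:", length(x$x), "points | window", x$window,
      "| passes", x$passes, "\n")
  invisible(x)
}

#' Extract the least and most frequent k-mers
#'
#' @param tab A `kmer_counts` object.
#' @param n_low,n_high Number of motifs to report from each extreme.
#'   The low list contains motifs with count >= 1; nullomers are listed
#'   separately.  Ties are broken alphabetically.
#' @return List with character vectors `lowest`, `highest`, `nullomers` and
#'   integer vectors `lowest_counts`, `highest_counts`.
#' @export
extreme_kmers <- function(tab, n_low = 15L, n_high = 15L) {
  stopifnot(inherits(tab, "kmer_counts"))
  h <- tab$counts
  present <- h[h >= 1L]
  # order() is stable, and names are already alphabetical
  asc <- present[order(present)]
  desc <- present[order(-present)]
  list(lowest = names(asc)[seq_len(min(n_low, length(asc)))],
       lowest_counts = unname(asc[seq_len(min(n_low, length(asc)))]),
       highest = names(desc)[seq_len(min(n_high, length(desc)))],
       highest_counts = unname(desc[seq_len(min(n_high, length(desc)))]),
       nullomers = names(h)[h == 0L])
}

#' Convert between motif strings and 0-based indices
#'
#' The index is the base-4 expansion of the motif with A=0, C=1, G=2, T=3,
#' first base most significant; this equals alphabetical rank.
#'
#' @param motif Character vector of equal-length A/C/G/T strings.
#' @return `kmer_index`: integer 0-based indices. `kmer_string`: motif strings.
#' @export
kmer_index <- function(motif) {
  k <- unique(nchar(motif))
  stopifnot(length(k) == 1L)
  dig <- match(strsplit(paste(motif, collapse = ""), "")[[1]],
               c("A", "C", "G", "T")) - 1L
  if (anyNA(dig)) stop("motifs must be over A/C/G/T")
  dig <- matrix(dig, nrow = k)
  as.integer(crossprod(dig, 4^((k - 1):0)))
}

#' @rdname kmer_index
#' @param index Integer vector of 0-based motif indices.
#' @param k Motif length.
#' @export
kmer_string <- function(index, k) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(index), ncol = k)
  for (j in seq_len(k))
    out[, j] <- bases[(index %/% 4^(k - j)) %% 4 + 1L]
  apply(out, 1L, paste, collapse = "")
}

#' Write an FA spectrum as TSV (columns x, N_x, FA)
#'
#' @param spec An `fa_spectrum`.
#' @param path Output path.
#' @export
write_spectrum_tsv <- function(spec, path) {
  sp <- spec$spectrum
  names(sp) <- c("x", "N_x", "FA")
  write_tsv(sp, path)
}
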