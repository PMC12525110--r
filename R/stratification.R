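# Cached 65,536 x 8 base-digit matrix of the full 8-mer universe (A=0..T=3),
# and derived per-dinucleotide occurrence vectors.  Built once per session.
.kmerstrat_cache <- new.env(parent = emptyenv())

digit_matrix <- function(k = 8L) {
  key <- paste0("digits", k)
  if (!is.null(.kmerstrat_cache[[key]])) return(.kmerstrat_cache[[key]])
  idx <- 0:(4^k - 1)
  d <- matrix(0L, nrow = 4^k, ncol = k)
  for (j in seq_len(k)) d[, j] <- (idx %/% 4^(k - j)) %% 4L
  .kmerstrat_cache[[key]] <- d
  d
}

#' Count overlapping dinucleotide occurrences within motifs
#'
#' Counts positions i with `motif[i] == X` and `motif[i+1] == Y`, overlap
#' included (so "AAA" contains two AA occurrences).
#'
#' @param motif Character vector of motif strings, or integer vector of
#'   0-based motif indices (then `k` must be given).
#' @param xy Dinucleotide, e.g. `"CG"`.
#' @param k Motif length when `motif` is given as indices (default 8).
#' @return Integer vector of occurrence counts.
#' @examples
#' dinucleotide_occurrences("CGCGCGCG", "CG")  # 4
#' dinucleotide_occurrences("CGCGCGCG", "GC")  # 3
#' @export
dinucleotide_occurrences <- function(motif, xy, k = 8L) {
  stopifnot(nchar(xy) == 2L)
  d2 <- match(strsplit(xy, "")[[1]], c("A", "C", "G", "T")) - 1L
  if (anyNA(d2)) stop("dinucleotide must be over A/C/G/T")
  if (is.character(motif)) {
    k <- unique(nchar(motif))
    stopifnot(length(k) == 1L)
    idx <- kmer_index(motif)
  } else idx <- as.integer(motif)
  n <- integer(length(idx))
  for (j in seq_len(k - 1L)) {
    a <- (idx %/% 4^(k - j)) %% 4L
    b <- (idx %/% 4^(k - j - 1L)) %% 4L
    n <- n + as.integer(a == d2[1L] & b == d2[2L])
  }
  n
}

# occurrence counts of xy over the full 8-mer universe, cached
universe_occurrences <- function(xy, k = 8L) {
  key <- paste0("occ", k, xy)
  if (!is.null(.kmerstrat_cache[[key]])) return(.kmerstrat_cache[[key]])
  d <- digit_matrix(k)
  d2 <- match(strsplit(xy, "")[[1]], c("A", "C", "G", "T")) - 1L
  n <- integer(nrow(d))
  for (j in seq_len(k - 1L))
    n <- n + as.integer(d[, j] == d2[1L] & d[, j + 1L] == d2[2L])
  .kmerstrat_cache[[key]] <- n
  n
}

#' Partition the 8-mer universe by dinucleotide occupancy
#'
#' Splits all 4^8 = 65,536 8-mers into three strata by the number of
#' overlapping occurrences of dinucleotide `xy`: zero ("0XY"), exactly one
#' ("1XY"), and two or more ("2XY").  The three strata partition the universe
#' exactly.
#'
#' @param xy Dinucleotide, e.g. `"CG"`.
#' @param k Motif length (default 8).
#' @return An object of class `dinucleotide_strata`: list with `xy`, `k`, and
#'   `members`, a named list of three sorted 0-based motif index vectors
#'   (`"0"`, `"1"`, `"2"`).
#' @export
build_strata <- function(xy, k = 8L) {
  occ <- universe_occurrences(toupper(xy), k)
  idx <- 0:(4^k - 1)
  structure(list(xy = toupper(xy), k = as.integer(k),
                 members = list("0" = idx[occ == 0L],
                                "1" = idx[occ == 1L],
                                "2" = idx[occ >= 2L])),
            class = "dinucleotide_strata")
}

#' @export
print.dinucleotide_strata <- function(x, ...) {
  sz <- vapply(x$members, length, integer(1))
  cat("dinucleotide strata for", x$xy, "(k =", x$k, "):",
      paste0(c("|0", "|1", "|2"), x$xy, "| = ", sz, collapse = ", "), "\n")
  invisible(x)
}

#' FA spectrum of one stratum
#'
#' Restricts the frequency-of-appearance spectrum to the members of one
#' stratum; the denominator stays 4^k.
#'
#' @param tab A `kmer_counts` object with `k` matching the strata.
#' @param strata A `dinucleotide_strata` object.
#' @param class Which stratum: `"0"`, `"1"` or `"2"`.
#' @return An `fa_spectrum` over the stratum members.
#' @export
stratum_spectrum <- function(tab, strata, class = c("0", "1", "2")) {
  class <- match.arg(class)
  stopifnot(inherits(strata, "dinucleotide_strata"), tab$k == strata$k)
  fa_spectrum(tab, universe = strata$members[[class]])
}

#' Stratum sizes for all 16 dinucleotides
#'
#' @param k Motif length (default 8).
#' @return Data.frame with columns `dinucleotide`, `class`, `size`.
#' @export
strata_size_table <- function(k = 8L) {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  do.call(rbind, lapply(dinucs, function(xy) {
    s <- build_strata(xy, k)
    data.frame(dinucleotide = xy, class = c("0", "1", "2"),
               size = vapply(s$members, length, integer(1)),
               row.names = NULL)
  }))
}
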