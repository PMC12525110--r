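#' Genome-weighted relative frequency of m-mers within an 8-mer set
#'
#' For a set of 8-mers with genome occurrence counts H, the relative
#' frequency of an m-mer is
#' \deqn{RF = \frac{4^m}{8-m+1}\cdot
#'   \frac{\sum_i N_{mi} H_i}{\sum_i H_i}}
#' where \eqn{N_{mi}} is the overlap-counted number of occurrences of the
#' m-mer among the \eqn{8-m+1} windows of the i-th member 8-mer.  The scaling
#' makes the mean RF over all 4^m m-mers exactly 1 (so the vector sums to
#' 4^m), because every 8-mer contributes exactly \eqn{8-m+1} m-mer windows.
#'
#' @param tab A `kmer_counts` object with `k = 8`.
#' @param members Optional 0-based motif indices of the set (a stratum);
#'   `NULL` means the full universe.
#' @param m Sub-motif length, 3 or 4 in practice (1..7 accepted).
#' @return An object of class `mmer_rf`: list with `m`, `rf` (named numeric
#'   vector of length 4^m, names are m-mer strings in alphabetical order) and
#'   `total_weight` (sum of H over the set).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = strrep("A", 20)))
#' prof <- mmer_rf(count_kmers(g, 8), members = kmer_index("AAAAAAAA"), m = 3)
#' prof$rf[["AAA"]]  # 64
#' @export
mmer_rf <- function(tab, members = NULL, m = 3L) {
  stopifnot(inherits(tab, "kmer_counts"))
  k <- tab$k
  stopifnot(m >= 1L, m < k)
  h <- as.numeric(tab$counts)
  idx <- if (is.null(members)) 0:(4^k - 1) else as.integer(members)
  h <- h[idx + 1L]
  tot <- sum(h)
  if (tot <= 0)
    stop("set has zero total genome weight (sum of H = 0)")
  lm <- 4^m
  num <- numeric(lm)
  # accumulate H over the k-m+1 m-mer windows of each member 8-mer
  for (w in seq_len(k - m + 1L)) {
    sub <- (idx %/% 4^(k - w - m + 1L)) %% 4^m    # m-mer index of window w
    acc <- rowsum(h, group = sub)
    num[as.integer(rownames(acc)) + 1L] <- num[as.integer(rownames(acc)) + 1L] +
      acc[, 1L]
  }
  rf <- (lm / (k - m + 1L)) * num / tot
  names(rf) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), m)
  structure(list(m = as.integer(m), rf = rf, total_weight = tot),
            class = "mmer_rf")
}

#' @export
print.mmer_rf <- function(x, ...) {
  cat("m-mer relative-frequency profile: m =", x$m, "|",
      length(x$rf), "m-mers | sum(RF) =", format(sum(x$rf)), "\n")
  rng <- range(x$rf)
  cat("  min", format(rng[1], digits = 4), "(", names(x$rf)[which.min(x$rf)],
      ") max", format(rng[2], digits = 4), "(", names(x$rf)[which.max(x$rf)],
      ")\n")
  invisible(x)
}

#' Paired m-mer usage of a stratum against the overall set
#'
#' Index-aligned pairs (q, p) with q the RF of each m-mer in the overall
#' 8-mer set and p its RF in the stratum; deviation from the diagonal p = q
#' measures usage separation.
#'
#' @param overall,stratum `mmer_rf` profiles with the same `m`.
#' @return Data.frame with columns `mmer`, `q` (overall), `p` (stratum).
#' @export
usage_pairs <- function(overall, stratum) {
  stopifnot(inherits(overall, "mmer_rf"), inherits(stratum, "mmer_rf"))
  if (overall$m != stratum$m)
    stop("profiles have different m (", overall$m, " vs ", stratum$m, ")")
  data.frame(mmer = names(overall$rf), q = unname(overall$rf),
             p = unname(stratum$rf), stringsAsFactors = FALSE)
}

#' Write usage pairs as TSV (m-mer, RF_overall, RF_stratum)
#'
#' @param pairs Data.frame from [usage_pairs()].
#' @param path Output path.
#' @export
write_usage_tsv <- function(pairs, path) {
  out <- data.frame(mmer = pairs$mmer, RF_overall = pairs$q,
                    RF_stratum = pairs$p)
  write_tsv(out, path)
}
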