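# Independent brute-force oracles, deliberately naive and string-based so
# they share no code path with the package internals.

random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# naive sliding-window k-mer counter over one string; windows with non-ACGT
# letters are skipped
naive_count_kmers <- function(s, k) {
  out <- new.env(parent = emptyenv())
  n <- nchar(s)
  if (n >= k) {
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("^[ACGT]+$", w))
        assign(w, (if (exists(w, out)) get(w, out) else 0L) + 1L, envir = out)
    }
  }
  counts <- unlist(as.list(out))
  if (is.null(counts)) counts <- integer(0)
  counts
}

# overlap-counted occurrences of dinucleotide xy in each motif string
naive_dinuc_count <- function(motifs, xy) {
  vapply(motifs, function(s) {
    n <- 0L
    for (i in seq_len(nchar(s) - 1L))
      if (substr(s, i, i + 1L) == xy) n <- n + 1L
    n
  }, integer(1), USE.NAMES = FALSE)
}

# centered valid-window moving average, written as an explicit loop
naive_rollmean <- function(y, w) {
  n <- length(y) - w + 1L
  vapply(seq_len(n), function(i) mean(y[i:(i + w - 1L)]), numeric(1))
}

# Jensen-Shannon divergence (base 2), via explicit KL terms to the mixture
naive_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# brute-force m-mer RF over a weighted 8-mer set: expand strings, scan windows
naive_mmer_rf <- function(motifs, h, m) {
  lm <- 4^m
  all_m <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), m)
  num <- setNames(numeric(lm), all_m)
  for (i in seq_along(motifs)) {
    s <- motifs[i]
    for (w in seq_len(nchar(s) - m + 1L))
      num[substr(s, w, w + m - 1L)] <- num[substr(s, w, w + m - 1L)] + h[i]
  }
  (lm / (nchar(motifs[1]) - m + 1L)) * num / sum(h)
}

# GC fraction of a vector of motif strings
mean_gc <- function(motifs) {
  mean(vapply(motifs, function(s)
    mean(strsplit(s, "")[[1]] %in% c("C", "G")), numeric(1)))
}
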