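test_that("k-mer counting matches sliding-window expectations", {
  g <- Biostrings::DNAStringSet(c(chr = "AAAAAAAAAA"))
  tab <- count_kmers(g, 8)
  expect_equal(tab$counts[["AAAAAAAA"]], 3L)
  expect_equal(sum(tab$counts), 3L)
  expect_length(tab$counts, 65536L)

  # windows containing N are skipped; windows never span sequence boundaries
  g2 <- Biostrings::DNAStringSet(c(a = "ACGTNACG", b = "ACG"))
  t2 <- count_kmers(g2, 3)
  expect_equal(t2$counts[["ACG"]], 3L)
  expect_equal(t2$windows, 4L)  # ACG, CGT from a; ACG from b; plus GTN.. skipped

  expect_warning(t3 <- count_kmers(Biostrings::DNAStringSet("ACG"), 8),
                 "exceeds every sequence length")
  expect_equal(sum(t3$counts), 0L)
})

test_that("counting agrees with a naive per-window oracle across k and fixtures", {
  set.seed(42)
  for (rep in 1:100) {
    k <- sample(c(3L, 4L, 8L), 1)
    s <- random_dna(sample(50:250, 1))
    tab <- count_kmers(Biostrings::DNAStringSet(s), k)
    oracle <- naive_count_kmers(s, k)
    expect_equal(tab$windows, nchar(s) - k + 1L)
    got <- tab$counts[tab$counts > 0L]
    expect_identical(got[order(names(got))], oracle[order(names(oracle))])
  }
})

test_that("FA spectrum is the normalized partition of the motif universe", {
  g <- Biostrings::DNAStringSet("ACGTACGTACGTACGTACG")  # 19 bp, 12 windows
  spec <- fa_spectrum(count_kmers(g, 8))
  sp <- spec$spectrum
  expect_equal(sp$fa[sp$x == 3], 4 / 65536)
  expect_equal(sp$fa[sp$x == 0], 65532 / 65536)
  expect_equal(sum(sp$n), 65536L)       # partition identity, x = 0 included
  expect_equal(sum(sp$fa), 1)

  # all-zero table: everything is a nullomer
  suppressWarnings(t0 <- count_kmers(Biostrings::DNAStringSet("ACG"), 8))
  expect_equal(fa_spectrum(t0)$spectrum$fa, 1)

  # subset universe: FA mass is |universe| / 4^k
  sub <- fa_spectrum(count_kmers(g, 8), universe = 0:99)
  expect_equal(sum(sub$spectrum$fa), 100 / 65536)
  expect_error(fa_spectrum(count_kmers(g, 8), universe = integer(0)), "empty")
})

test_that("moving-average smoothing follows the valid-window convention", {
  const <- smooth_spectrum(list(x = 1:50, y = rep(0.3, 50)), window = 10)
  expect_equal(const$y, rep(0.3, 41))
  expect_length(const$x, 41L)

  set.seed(5)
  y <- runif(100)
  sm <- smooth_spectrum(list(x = 1:100, y = y), window = 10)
  expect_equal(sm$y, naive_rollmean(y, 10))
  expect_equal(sm$x, naive_rollmean(1:100, 10))

  # window 1 is the identity; repeated passes chain the oracle
  expect_equal(smooth_spectrum(list(x = 1:10, y = y[1:10]), window = 1)$y,
               y[1:10])
  two <- smooth_spectrum(list(x = 1:100, y = y), window = 5, passes = 2)
  expect_equal(two$y, naive_rollmean(naive_rollmean(y, 5), 5))

  expect_error(smooth_spectrum(list(x = 1:5, y = y[1:5]), window = 10),
               "exceeds grid length")
})

test_that("extreme motif extraction orders by count with alphabetical ties", {
  g <- Biostrings::DNAStringSet("AAAAAAAAAA")
  ex <- extreme_kmers(count_kmers(g, 8), 5, 5)
  expect_equal(ex$lowest[1], "AAAAAAAA")     # only nonzero motif heads both
  expect_equal(ex$highest[1], "AAAAAAAA")
  expect_length(ex$nullomers, 65535L)

  # tie on count: alphabetical order
  tab <- count_kmers(Biostrings::DNAStringSet(c("TTTA", "AAAC")), 3)
  ex2 <- extreme_kmers(tab, 4, 4)
  expect_equal(ex2$lowest, sort(ex2$lowest))
  expect_equal(ex2$lowest_counts, rep(1L, 4))
})

test_that("least frequent 8-mers are GC-richer than most frequent on a CpG-suppressed genome", {
  tab <- fixture_suppressed()$counts
  ex <- extreme_kmers(tab, 100, 100)
  expect_gt(mean_gc(ex$lowest), mean_gc(ex$highest))
})

test_that("motif index/string conversion is the base-4 alphabetical code", {
  expect_equal(kmer_index(c("AAA", "AAC", "TTT")), c(0L, 1L, 63L))
  set.seed(3)
  idx <- sample(0:65535, 50)
  expect_equal(kmer_index(kmer_string(idx, 8)), idx)
})

test_that("uniform i.i.d. genome yields a spectrum mode near the Poisson mean", {
  fx <- fixture_uniform()
  pk <- find_peak(smooth_spectrum(fa_spectrum(fx$counts)))
  expected <- 1e7 / 65536
  expect_lt(abs(pk$x_hat - expected) / expected, 0.25)
})
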