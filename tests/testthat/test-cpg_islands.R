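test_that("window statistics match closed forms and a naive recount", {
  allA <- Biostrings::DNAString(strrep("A", 1000))
  ws <- window_stats(allA, 1000, 500)
  expect_equal(ws$gc_fraction[1], 0)
  expect_equal(ws$oe_ratio[1], 0)

  cg <- Biostrings::DNAString(strrep("CG", 500))
  ws2 <- window_stats(cg, 1000, 500)
  expect_equal(ws2$gc_fraction[1], 1)
  expect_equal(ws2$oe_ratio[1], (500 * 1000) / (500 * 500))

  set.seed(41)
  s <- random_dna(1000, probs = c(0.3, 0.2, 0.2, 0.3))
  ws3 <- window_stats(Biostrings::DNAString(s), 1000, 500)
  chars <- strsplit(s, "")[[1]]
  nc <- sum(chars == "C"); ng <- sum(chars == "G")
  ncg <- sum(chars[-1000] == "C" & chars[-1] == "G")
  expect_equal(ws3$gc_fraction[1], (nc + ng) / 1000)
  expect_equal(ws3$oe_ratio[1], ncg * 1000 / (nc * ng))

  # final partial window is evaluated with its actual length
  s2 <- paste0(strrep("A", 1000), strrep("CG", 100))
  ws4 <- window_stats(Biostrings::DNAString(s2), 1000, 500)
  last <- ws4[nrow(ws4), ]
  expect_equal(last$end - last$start, 200)
  expect_equal(last$gc_fraction, 1)

  # windows containing N are skipped
  s3 <- paste0(strrep("A", 600), "N", strrep("A", 1399))
  ws5 <- window_stats(Biostrings::DNAString(s3), 1000, 500)
  expect_false(any(ws5$start <= 600 & ws5$end > 600))
})

test_that("island calling retains inclusive-threshold windows and merges them", {
  stats <- data.frame(start = c(0, 500, 3000), end = c(1000, 1500, 4000),
                      gc_fraction = c(0.5, 0.62, 0.4),
                      oe_ratio = c(0.6, 0.9, 1.2))
  ann <- call_islands(stats)
  # thresholds are inclusive: the (0.5, 0.6) window qualifies and merges
  expect_equal(ann$intervals, data.frame(start = 0, end = 1500))

  none <- call_islands(data.frame(start = 0, end = 1000, gc_fraction = 0.3,
                                  oe_ratio = 0.2))
  expect_equal(nrow(none$intervals), 0L)
})

test_that("an embedded island is recovered with high reciprocal overlap", {
  bg <- sim_markov_genome(1e5, gc = 0.3, cg_odds = 1, seed = 5)
  emb <- embed_islands(bg, data.frame(start = 50000, length = 2000,
                                      gc = 0.65, cg_odds = 1.0), seed = 6)
  ann <- detect_islands(emb$genome)
  expect_equal(nrow(ann$intervals), 1L)
  tr <- emb$truth
  ov <- max(0, min(ann$intervals$end, tr$end) -
               max(ann$intervals$start, tr$start))
  expect_gte(ov / (tr$end - tr$start), 0.8)
  expect_gte(ov / (ann$intervals$end - ann$intervals$start), 0.8)

  # island calling is idempotent: the excised remainder is island-free
  rem <- remove_islands(emb$genome, ann)
  for (i in seq_along(rem))
    expect_equal(nrow(detect_islands(rem[[i]])$intervals), 0L)
})

test_that("island removal delegates to interval excision", {
  g <- Biostrings::DNAString("ACGTACGTAC")
  empty <- structure(list(intervals = data.frame(start = integer(0),
                                                 end = integer(0)),
                          params = list()), class = "island_annotation")
  expect_equal(unname(as.character(remove_islands(g, empty))), "ACGTACGTAC")

  full <- structure(list(intervals = data.frame(start = 0, end = 10),
                         params = list()), class = "island_annotation")
  expect_warning(out <- remove_islands(g, full), "all residues excised")
  expect_length(out, 0L)
})

test_that("gene-body exclusion masks drop overlapping called islands", {
  stats <- data.frame(start = c(0, 5000), end = c(1000, 6000),
                      gc_fraction = 0.7, oe_ratio = 1.0)
  ann <- call_islands(stats)
  expect_equal(nrow(ann$intervals), 2L)
  # emulate detect_islands' exclusion step on precomputed stats
  g <- Biostrings::DNAString(paste0(strrep("CG", 500), strrep("A", 4000),
                                    strrep("CG", 500)))
  ann2 <- detect_islands(g, exclude = data.frame(start = 4900, end = 5100))
  expect_true(all(ann2$intervals$start >= 5100 | ann2$intervals$end <= 4900))
})
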