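# Shared synthetic fixtures, generated once per test run and cached.
# The study conditions: 10 Mb sequences, yeast-like base composition
# (GC ~ 0.38), CpG odds 1.0 (i.i.d.-like control) or 0.25 (suppressed),
# fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 10 Mb CpG-suppressed Markov genome (the main qualitative fixture)
fixture_suppressed <- function() cached("sup", {
  g <- sim_markov_genome(1e7, cg_odds = 0.25, seed = 1)
  list(genome = g, counts = count_kmers(g, 8))
})

# 10 Mb uniform-composition i.i.d. genome
fixture_uniform <- function() cached("unif", {
  g <- sim_iid_genome(1e7, base_probs = rep(0.25, 4), seed = 2)
  list(genome = g, counts = count_kmers(g, 8))
})

# 10 Mb suppressed background with 100 embedded 2 kb CpG islands (2% load)
fixture_islands <- function() cached("isl", {
  bg <- sim_markov_genome(1e7, cg_odds = 0.25, seed = 2)
  spans <- data.frame(start = round(seq(2e4, 9.9e6, length.out = 100)),
                      length = 2000)
  emb <- embed_islands(bg, spans, seed = 3)
  list(background = bg, genome = emb$genome, truth = emb$truth)
})
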