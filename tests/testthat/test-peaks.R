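make_curve <- function(x, y, window = 1L, passes = 0L)
  structure(list(x = x, y = y, window = window, passes = passes),
            class = "smoothed_curve")

test_that("peak finding takes the global argmax with smallest-x ties", {
  delta <- make_curve(1:60, replace(numeric(60), 30, 1))
  expect_equal(find_peak(delta)$x_hat, 30)

  plateau <- make_curve(1:20, replace(numeric(20), 10:11, 0.5))
  expect_equal(find_peak(plateau)$x_hat, 10)

  set.seed(31)
  y <- dpois(1:100, 35) + runif(100, 0, 1e-4)
  cur <- make_curve(1:100, y)
  expect_equal(find_peak(cur)$x_hat, which(y == max(y)))  # full-scan oracle

  expect_error(find_peak(make_curve(1:5, numeric(5))), "all-zero")
})

test_that("peak distance is the absolute difference under one smoothing config", {
  a <- find_peak(make_curve(1:40, replace(numeric(40), 10, 1)))
  b <- find_peak(make_curve(1:40, replace(numeric(40), 30, 1)))
  expect_equal(peak_distance(a, b), 20)
  expect_equal(peak_distance(a, a), 0)

  c2 <- find_peak(smooth_spectrum(list(x = 1:40, y = dpois(1:40, 12)),
                                  window = 5))
  expect_error(peak_distance(a, c2), "different smoothing configurations")
})

test_that("a zero observed distance yields p = 1", {
  # two disjoint motif sets carrying identical count multisets
  h <- integer(65536)
  h[1:40] <- rep(c(5L, 9L, 14L), length.out = 40)
  h[101:140] <- rep(c(5L, 9L, 14L), length.out = 40)
  tab <- structure(list(k = 8L, counts = setNames(h, kmer_string(0:65535, 8)),
                        windows = sum(h)), class = "kmer_counts")
  res <- peak_permutation_test(tab, 0:39, 100:139, B = 200, window = 3,
                               seed = 1)
  expect_equal(res$d_obs, 0)
  expect_equal(res$p_value, 1)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on a toy pool", {
  # 8 motifs split 4/4: all choose(8,4) = 70 label assignments enumerable
  h_i <- c(2L, 3L, 4L, 5L)
  h_j <- c(9L, 10L, 11L, 12L)
  h <- integer(65536)
  h[1:4] <- h_i; h[11:14] <- h_j
  tab <- structure(list(k = 8L, counts = setNames(h, kmer_string(0:65535, 8)),
                        windows = sum(h)), class = "kmer_counts")

  pool <- c(h_i, h_j)
  xmax <- max(pool)
  peak_of <- function(v) which.max(tabulate(v, xmax))  # window 1 = identity
  d_obs <- abs(peak_of(h_i) - peak_of(h_j))
  combos <- utils::combn(8, 4)
  d_null <- apply(combos, 2, function(ix)
    abs(peak_of(pool[ix]) - peak_of(pool[-ix])))
  p_exact <- mean(d_null >= d_obs)

  res <- peak_permutation_test(tab, 0:3, 10:13, B = 10000, window = 1,
                               seed = 7)
  expect_equal(res$d_obs, d_obs)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1e-12)
})

test_that("the p-value is the count-based tail proportion and is seed-reproducible", {
  set.seed(3)
  h <- integer(65536)
  h[1:500] <- rpois(500, 20)
  h[1001:1500] <- rpois(500, 28)
  tab <- structure(list(k = 8L, counts = setNames(h, kmer_string(0:65535, 8)),
                        windows = sum(h)), class = "kmer_counts")
  res <- peak_permutation_test(tab, 0:499, 1000:1499, B = 500, window = 5,
                               seed = 11)
  expect_equal(res$p_value, sum(res$null >= res$d_obs) / res$B)
  expect_length(res$null, 500L)

  res2 <- peak_permutation_test(tab, 0:499, 1000:1499, B = 500, window = 5,
                                seed = 11)
  expect_identical(res, res2)

  # for the fixed null sample, the tail proportion is non-increasing in d
  ds <- sort(unique(c(0, res$null)))
  tail_p <- vapply(ds, function(d) mean(res$null >= d), numeric(1))
  expect_true(all(diff(tail_p) <= 0))

  expect_error(peak_permutation_test(tab, 0:499, 400:899, B = 10),
               "overlap")
})

test_that("p-values are approximately uniform when the two strata share one null", {
  # Peak distances are discrete, so the raw tail proportion is conservative
  # under ties; the exchangeable-rank construction that includes the observed
  # draw and randomizes over ties is exactly Uniform(0,1) under the null and
  # is the right calibration check.  The reported p itself must dominate it.
  tab <- fixture_uniform()$counts
  set.seed(37)
  ps <- replicate(200, {
    members <- sample(0:65535, 2000)
    res <- peak_permutation_test(tab, members[1:1000], members[1001:2000],
                                 B = 99, window = 10)
    p_rand <- (sum(res$null > res$d_obs) +
                 stats::runif(1) * (sum(res$null == res$d_obs) + 1)) /
              (res$B + 1)
    c(rand = p_rand, raw = res$p_value)
  })
  ks <- suppressWarnings(stats::ks.test(ps["rand", ], "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_true(all(ps["raw", ] >= ps["rand", ] - 1 / 99))
})
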