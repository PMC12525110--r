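#' Main peak of a smoothed spectrum
#'
#' Global argmax of the smoothed curve; ties are broken by the smallest x.
#'
#' @param curve A `smoothed_curve`.
#' @return An object of class `peak_estimate`: list with `x_hat`, `y_hat`,
#'   `window`, `passes`.
#' @export
find_peak <- function(curve) {
  stopifnot(inherits(curve, "smoothed_curve"))
  if (length(curve$y) == 0L) stop("empty curve")
  if (all(curve$y == 0)) stop("all-zero curve has no peak")
  i <- which.max(curve$y)    # first maximum = smallest x on an ordered grid
  structure(list(x_hat = curve$x[i], y_hat = curve$y[i],
                 window = curve$window, passes = curve$passes),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat("peak at x =", x$x_hat, "(FA =", format(x$y_hat, digits = 4),
      "; smoothing window", x$window, ", passes", x$passes, ")\n")
  invisible(x)
}

#' Distance between two spectrum peaks
#'
#' Absolute difference of the peak appearance counts.  Both peaks must come
#' from the same smoothing configuration.
#'
#' @param a,b `peak_estimate` objects.
#' @return Non-negative distance in appearance-count units.
#' @export
peak_distance <- function(a, b) {
  stopifnot(inherits(a, "peak_estimate"), inherits(b, "peak_estimate"))
  if (a$window != b$window || a$passes != b$passes)
    stop("peaks were estimated under different smoothing configurations")
  abs(a$x_hat - b$x_hat)
}

# FA curve (dense grid 1..xmax) of a vector of motif counts; FA scale uses
# the full 4^k denominator but any positive constant leaves peaks unchanged.
counts_to_curve <- function(h, xmax, denom) {
  h <- h[h >= 1L]
  y <- tabulate(h, nbins = xmax) / denom
  list(x = seq_len(xmax), y = y)
}

#' Permutation test for the distance between two stratum peaks
#'
#' Tests whether the observed peak distance between the smoothed FA curves of
#' two disjoint motif strata could arise by chance.  The member 8-mers of
#' both strata are pooled, each carrying its genome occurrence count H; each
#' replicate randomly reassigns stratum labels preserving the two original
#' subset sizes, rebuilds both FA curves on a shared dense grid, smooths them
#' with the same configuration, and records the peak distance.  The p-value
#' is the proportion of null distances greater than or equal to the observed
#' one (>= as the inequality).
#'
#' @param tab A `kmer_counts` object.
#' @param members_i,members_j Disjoint 0-based motif index vectors (e.g. two
#'   entries of `build_strata(...)$members`).
#' @param B Number of permutation replicates (default 10000).
#' @param window,passes Smoothing configuration (defaults 10, 1), applied
#'   identically to observed and null curves.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `peak_permutation`: list with `d_obs`,
#'   `p_value`, `null` (the B null distances), `B`, `peak_i`, `peak_j`,
#'   `window`, `passes`, `seed`.
#' @export
peak_permutation_test <- function(tab, members_i, members_j, B = 10000L,
                                  window = 10L, passes = 1L, seed = NULL) {
  stopifnot(inherits(tab, "kmer_counts"), B >= 1L)
  members_i <- as.integer(members_i); members_j <- as.integer(members_j)
  if (length(intersect(members_i, members_j)) > 0L)
    stop("strata overlap; the permutation test requires disjoint member sets")
  if (!is.null(seed)) set.seed(seed)
  denom <- 4^tab$k
  hi <- tab$counts[members_i + 1L]
  hj <- tab$counts[members_j + 1L]
  pool <- c(hi, hj)
  n_i <- length(hi)
  xmax <- max(pool, 1L)
  smooth_peak <- function(h) {
    cur <- smooth_spectrum(counts_to_curve(h, xmax, denom),
                           window = window, passes = passes)
    find_peak(cur)$x_hat
  }
  pk_i <- smooth_peak(hi)
  pk_j <- smooth_peak(hj)
  d_obs <- abs(pk_i - pk_j)
  null <- numeric(B)
  n_pool <- length(pool)
  for (b in seq_len(B)) {
    lab <- sample.int(n_pool, n_i)
    null[b] <- abs(smooth_peak(pool[lab]) - smooth_peak(pool[-lab]))
  }
  structure(list(d_obs = d_obs, p_value = mean(null >= d_obs), null = null,
                 B = as.integer(B), peak_i = pk_i, peak_j = pk_j,
                 window = as.integer(window), passes = as.integer(passes),
                 seed = seed),
            class = "peak_permutation")
}

#' @export
print.peak_permutation <- function(x, ...) {
  cat("Peak-distance permutation test\n")
  cat("  peaks at x =", x$peak_i, "and", x$peak_j,
      "| observed distance:", x$d_obs, "\n")
  p_lab <- if (x$p_value == 0) paste0("< ", format(1 / x$B)) else
    format(x$p_value)
  cat("  B =", x$B, "replicates | p-value:", p_lab, "\n")
  invisible(x)
}
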