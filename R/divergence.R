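#' Zero-replacement normalization of an RF vector for entropy comparison
#'
#' Replaces every zero entry by half the smallest non-zero entry of the same
#' vector, then (by default) rescales the vector to sum to 1 so it is a
#' proper probability distribution.
#'
#' @param raw An `mmer_rf` profile or non-negative numeric vector with at
#'   least one non-zero entry.
#' @param renormalize Rescale to sum 1 after zero-replacement (default TRUE).
#' @return List with `probs` (the normalized vector), `floor` (the
#'   substituted value, or NA if no zeros were present).
#' @export
normalize_rf <- function(raw, renormalize = TRUE) {
  v <- if (inherits(raw, "mmer_rf")) raw$rf else as.numeric(raw)
  if (any(v < 0)) stop("negative frequencies are not allowed")
  nz <- v[v > 0]
  if (length(nz) == 0L) stop("all-zero frequency vector")
  fl <- NA_real_
  if (any(v == 0)) {
    fl <- min(nz) / 2
    v[v == 0] <- fl
  }
  if (renormalize) v <- v / sum(v)
  list(probs = v, floor = fl)
}

#' Symmetric relative entropy between two frequency vectors
#'
#' \deqn{NSRE(P\|Q) = \sum_i \left[p_i \log_2\frac{2p_i}{p_i+q_i}
#'   + q_i \log_2\frac{2q_i}{p_i+q_i}\right]}
#' Symmetric in P and Q, zero iff P = Q entrywise, and bounded by 2 for
#' probability vectors (it equals twice the Jensen-Shannon divergence).
#' Inputs are expected to be strictly positive (apply [normalize_rf()] first
#' when zeros may occur).
#'
#' @param p,q Positive numeric vectors of equal length (or the `probs` lists
#'   returned by [normalize_rf()]).
#' @return NSRE in bits.
#' @export
nsre <- function(p, q) {
  if (is.list(p)) p <- p$probs
  if (is.list(q)) q <- q$probs
  if (length(p) != length(q))
    stop("length mismatch: ", length(p), " vs ", length(q))
  if (any(p <= 0) || any(q <= 0))
    stop("nsre requires strictly positive vectors; use normalize_rf() first")
  m <- p + q
  sum(p * log2(2 * p / m) + q * log2(2 * q / m))
}

#' Diagonal distance and angle of usage pairs
#'
#' For each pair (q, p) — overall RF on the x axis, stratum RF on the y axis —
#' computes the angle \eqn{\alpha = \pi/4 - \arctan(p/q)} between the ray
#' from the origin through the point and the diagonal p = q, and the signed
#' diagonal distance \eqn{d = \sqrt{p^2+q^2}\,\sin\alpha}.  The two-argument
#' arctangent is used so that q = 0 maps to \eqn{\alpha = -\pi/4} and p = 0
#' to \eqn{\alpha = +\pi/4}; |d| equals the perpendicular distance
#' \eqn{|p-q|/\sqrt2} from the point to the diagonal.  Pairs with p = q = 0
#' have no direction and are dropped with a warning.
#'
#' @param pairs Data.frame from [usage_pairs()] (columns `p`, `q`), or any
#'   data.frame/list with those columns.
#' @return List with numeric vectors `d` and `alpha` (radians), plus
#'   `n_dropped`, the number of (0,0) pairs removed.
#' @export
deviation_components <- function(pairs) {
  p <- pairs$p; q <- pairs$q
  if (any(p < 0) || any(q < 0)) stop("p and q must be non-negative")
  zero <- p == 0 & q == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with p = q = 0 dropped (undefined direction)")
    p <- p[!zero]; q <- q[!zero]
  }
  alpha <- pi / 4 - atan2(p, q)
  d <- sqrt(p^2 + q^2) * sin(alpha)
  list(d = d, alpha = alpha, n_dropped = sum(zero))
}

#' Distance deviation S1 and angular deviation S2
#'
#' Root-mean-square summaries of the deviation components with an n - 1
#' denominator: \eqn{S_1 = \sqrt{\sum d_i^2/(n-1)}} (RF units) and
#' \eqn{S_2 = \sqrt{\sum \alpha_i^2/(n-1)}} (radians), where n is the number
#' of components (64 for 3-mers, 256 for 4-mers when no pair was dropped).
#'
#' @param comp List from [deviation_components()].
#' @return Non-negative scalar.
#' @export
s1 <- function(comp) rms_nm1(comp$d)

#' @rdname s1
#' @export
s2 <- function(comp) rms_nm1(comp$alpha)

rms_nm1 <- function(v) {
  n <- length(v)
  if (n < 2L) stop("need at least 2 components")
  sqrt(sum(v^2) / (n - 1))
}

#' All three divergence scores of a stratum against the overall set
#'
#' Convenience wrapper: computes NSRE on zero-replaced, probability-normalized
#' vectors and S1/S2 on the raw RF pairs.
#'
#' @param overall,stratum `mmer_rf` profiles with the same `m`.
#' @param renormalize Passed to [normalize_rf()] for the NSRE branch.
#' @return Data.frame row with columns `m`, `nsre`, `s1`, `s2`.
#' @export
divergence_scores <- function(overall, stratum, renormalize = TRUE) {
  pr <- usage_pairs(overall, stratum)
  comp <- deviation_components(pr)
  data.frame(m = overall$m,
             nsre = nsre(normalize_rf(stratum, renormalize),
                         normalize_rf(overall, renormalize)),
             s1 = s1(comp), s2 = s2(comp))
}
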