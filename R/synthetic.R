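#' Seeded synthetic genome sequences
#'
#' `sim_iid_genome()` draws residues independently from `base_probs`.
#' `sim_markov_genome()` draws a first-order Markov chain whose transition
#' matrix is the i.i.d. matrix (all rows equal to `base_probs`) with the
#' C-to-G entry down- or up-weighted so that the chain's stationary CpG
#' observed/expected ratio equals `cg_odds` (see [markov_theory()]); for
#' long sequences the measured O/E therefore approaches `cg_odds`.
#' `cg_odds = 1` reduces to the i.i.d. model.  Both generators are
#' bit-reproducible for a fixed seed.
#'
#' @param length Sequence length in bp.
#' @param base_probs Probabilities of A, C, G, T (sum 1).  The default
#'   matches a yeast-like composition with GC ~ 0.38; `gc` is a shorthand
#'   that sets `base_probs = c((1-gc)/2, gc/2, gc/2, (1-gc)/2)`.
#' @param gc Optional GC fraction overriding `base_probs`.
#' @param cg_odds Target stationary CpG observed/expected ratio
#'   (1 = no CpG suppression).
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param name Sequence name in the returned set.
#' @return A single-sequence `DNAStringSet`.
#' @export
sim_iid_genome <- function(length, base_probs = yeastlike_probs(), gc = NULL,
                           seed = NULL, name = "sim") {
  probs <- resolve_probs(base_probs, gc)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")[sample.int(4L, length, replace = TRUE,
                                            prob = probs)]
  out <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(out) <- name
  out
}

#' @rdname sim_iid_genome
#' @export
sim_markov_genome <- function(length, base_probs = yeastlike_probs(),
                              gc = NULL, cg_odds = 1, seed = NULL,
                              name = "sim") {
  probs <- resolve_probs(base_probs, gc)
  stopifnot(cg_odds > 0)
  th <- markov_theory(probs, cg_odds)
  if (!is.null(seed)) set.seed(seed)
  codes <- .markov_chain_bases(as.integer(length), th$trans, th$stationary)
  out <- Biostrings::DNAStringSet(
    paste(c("A", "C", "G", "T")[codes + 1L], collapse = ""))
  names(out) <- name
  out
}

yeastlike_probs <- function() c(A = 0.31, C = 0.19, G = 0.19, T = 0.31)

resolve_probs <- function(base_probs, gc) {
  if (!is.null(gc)) {
    stopifnot(gc > 0, gc < 1)
    base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  }
  base_probs <- as.numeric(base_probs)
  if (length(base_probs) != 4L || any(base_probs < 0) ||
      abs(sum(base_probs) - 1) > 1e-12)
    stop("base_probs must be 4 non-negative values summing to 1")
  base_probs
}

#' Transition matrix and stationary properties of the CpG-suppressed chain
#'
#' Builds the first-order transition matrix used by [sim_markov_genome()]:
#' all rows equal `base_probs` except the C row, whose C-to-G entry is
#' scaled by a factor chosen (by root finding) so that the chain's
#' *stationary* CpG observed/expected ratio
#' \eqn{O/E = \pi_C T_{CG} / (\pi_C \pi_G) = T_{CG}/\pi_G}
#' equals `cg_odds` exactly.  Simply multiplying the entry by `cg_odds` and
#' renormalizing would overshoot (the renormalization deflates \eqn{\pi_G}),
#' so the scale is calibrated instead; `cg_odds = 1` gives the i.i.d. matrix
#' unchanged.
#'
#' @inheritParams sim_iid_genome
#' @param cg_odds Target stationary CpG observed/expected ratio.
#' @return List with `trans` (4x4), `stationary` (length 4), `cg_oe` (the
#'   realized stationary O/E, equal to `cg_odds` to root-finding tolerance)
#'   and `scale` (the calibrated factor on the raw C-to-G entry).
#' @export
markov_theory <- function(base_probs = yeastlike_probs(), cg_odds = 1,
                          gc = NULL) {
  probs <- resolve_probs(base_probs, gc)
  stopifnot(cg_odds > 0)
  if (any(probs == 0)) stop("base_probs must be strictly positive for the Markov chain")
  build <- function(s) {
    trans <- matrix(rep(probs, each = 4L), nrow = 4L,
                    dimnames = list(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")))
    trans["C", "G"] <- trans["C", "G"] * s
    trans <- trans / rowSums(trans)
    e <- eigen(t(trans))
    i <- which.min(abs(e$values - 1))
    st <- Re(e$vectors[, i]); st <- st / sum(st)
    names(st) <- c("A", "C", "G", "T")
    list(trans = trans, stationary = st,
         cg_oe = unname(trans["C", "G"] / st["G"]))
  }
  if (cg_odds == 1) {
    th <- build(1)
  } else {
    # stationary O/E is continuous and increasing in the scale; bracket it
    hi <- if (cg_odds > 1) cg_odds * 4 else 1
    lo <- if (cg_odds > 1) 1 else cg_odds / 4
    s <- stats::uniroot(function(s) build(s)$cg_oe - cg_odds,
                        lower = lo, upper = hi, tol = 1e-12)$root
    th <- build(s)
  }
  th$scale <- if (cg_odds == 1) 1 else s
  th
}

#' Embed CpG-island segments into a background sequence
#'
#' Replaces disjoint spans of the background with GC-rich, CpG-unsuppressed
#' Markov draws, producing ground-truth islands for the island caller.
#'
#' @param g A `DNAString` or single-sequence `DNAStringSet` (the background).
#' @param islands Data.frame with columns `start` (0-based), `length`, and
#'   optionally `gc` (default 0.65) and `cg_odds` (default 1.0) per island.
#' @param seed Optional integer seed.
#' @return List with `genome` (single-sequence `DNAStringSet`) and `truth`
#'   (data.frame `start`, `end`, 0-based half-open).
#' @export
embed_islands <- function(g, islands, seed = NULL) {
  if (methods::is(g, "DNAStringSet")) {
    stopifnot(length(g) == 1L)
    nm <- names(g); g <- g[[1L]]
  } else nm <- "sim"
  if (NROW(islands) == 0L) {
    out <- Biostrings::DNAStringSet(g); names(out) <- nm
    return(list(genome = out,
                truth = data.frame(start = integer(0), end = integer(0))))
  }
  if (is.null(islands$gc)) islands$gc <- 0.65
  if (is.null(islands$cg_odds)) islands$cg_odds <- 1.0
  islands <- islands[order(islands$start), , drop = FALSE]
  st <- islands$start; en <- islands$start + islands$length
  if (any(st < 0) || any(en > length(g)))
    stop("island spans must lie within the background sequence")
  if (NROW(islands) > 1L && any(st[-1L] < en[-NROW(islands)]))
    stop("island spans must be disjoint")
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(as.character(g), "")[[1]]
  for (i in seq_len(NROW(islands))) {
    isl <- sim_markov_genome(islands$length[i], gc = islands$gc[i],
                             cg_odds = islands$cg_odds[i])
    s[(st[i] + 1L):en[i]] <- strsplit(as.character(isl[[1L]]), "")[[1]]
  }
  out <- Biostrings::DNAStringSet(paste(s, collapse = ""))
  names(out) <- nm
  list(genome = out, truth = data.frame(start = st, end = en))
}
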