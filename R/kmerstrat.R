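#' kmerstrat: CG-stratified k-mer spectrum analysis
#'
#' Frequency-of-appearance spectra of genomic 8-mers, dinucleotide-content
#' strata, m-mer usage divergence metrics, peak-distance permutation tests,
#' CpG island detection and seeded synthetic genomes.  The main entry point
#' is [kmerstrat()]; the per-stage functions ([count_kmers()],
#' [build_strata()], [mmer_rf()], [divergence_scores()],
#' [peak_permutation_test()], [detect_islands()], [sim_markov_genome()])
#' compose to the same results.
#'
#' @useDynLib kmerstrat, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

#' Stratified 8-mer spectrum analysis of a genome
#'
#' Runs the full analysis for one genome: counts 8-mers, builds the 0XY /
#' 1XY / 2XY strata for the requested dinucleotides, locates the smoothed
#' peak of each stratum spectrum and the pairwise peak distances, computes
#' the m-mer relative-frequency profiles and the three usage-divergence
#' scores (symmetric relative entropy, distance deviation S1, angular
#' deviation S2) of every stratum against the overall set, and (optionally)
#' runs the label-shuffling permutation test on each pair of strata.
#'
#' @param genome A `DNAStringSet` (e.g. from [read_genome()] or
#'   [sim_markov_genome()]).
#' @param dinucleotides Character vector of dinucleotides to stratify by
#'   (default `"CG"`; `"all"` expands to all 16).
#' @param k Motif length (default 8).
#' @param m Sub-motif lengths for the usage profiles (default `c(3, 4)`).
#' @param window,passes Moving-average smoothing configuration for peak
#'   finding (defaults 10 and 1).
#' @param B Permutation replicates per stratum pair; 0 (default) skips the
#'   permutation tests.
#' @param seed Optional integer seed used for the permutation tests.
#' @return An object of class `kmerstrat`: list with `counts`
#'   (`kmer_counts`), `overall_spectrum`, `overall_peak`, `strata` (per
#'   dinucleotide: the strata, their spectra, peaks, pairwise distances and
#'   permutation results), `usage` (data.frame of divergence scores with
#'   columns `dinucleotide`, `class`, `m`, `nsre`, `s1`, `s2`), `rf`
#'   (m-mer RF profiles, overall and per stratum) and `call`.
#' @examples
#' g <- sim_markov_genome(2e5, cg_odds = 0.25, seed = 1)
#' fit <- kmerstrat(g, dinucleotides = "CG")
#' fit
#' coef(fit)   # divergence scores
#' @export
kmerstrat <- function(genome, dinucleotides = "CG", k = 8L, m = c(3L, 4L),
                      window = 10L, passes = 1L, B = 0L, seed = NULL) {
  cl <- match.call()
  if (identical(dinucleotides, "all"))
    dinucleotides <- as.vector(outer(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"), paste0))
  dinucleotides <- toupper(dinucleotides)
  tab <- count_kmers(genome, k = k)
  overall_spec <- fa_spectrum(tab)
  overall_peak <- find_peak(smooth_spectrum(overall_spec, window, passes))
  rf_overall <- lapply(m, function(mm) mmer_rf(tab, NULL, mm))
  names(rf_overall) <- paste0("m", m)

  strata_out <- list(); usage_rows <- list(); rf_strata <- list()
  for (xy in dinucleotides) {
    st <- build_strata(xy, k)
    specs <- lapply(c("0", "1", "2"), function(cls)
      stratum_spectrum(tab, st, cls))
    names(specs) <- c("0", "1", "2")
    peaks <- lapply(specs, function(sp)
      find_peak(smooth_spectrum(sp, window, passes)))
    dist <- data.frame(
      pair = c("0-1", "0-2", "1-2"),
      distance = c(peak_distance(peaks[["0"]], peaks[["1"]]),
                   peak_distance(peaks[["0"]], peaks[["2"]]),
                   peak_distance(peaks[["1"]], peaks[["2"]])))
    perm <- NULL
    if (B > 0L) {
      pairs <- list(c("0", "1"), c("0", "2"), c("1", "2"))
      perm <- lapply(pairs, function(pr)
        peak_permutation_test(tab, st$members[[pr[1]]], st$members[[pr[2]]],
                              B = B, window = window, passes = passes,
                              seed = seed))
      names(perm) <- c("0-1", "0-2", "1-2")
      dist$p_value <- vapply(perm, function(p) p$p_value, numeric(1))
    }
    for (mm in m) {
      ov <- rf_overall[[paste0("m", mm)]]
      for (cls in c("0", "1", "2")) {
        prof <- mmer_rf(tab, st$members[[cls]], mm)
        rf_strata[[paste0(xy, cls, "_m", mm)]] <- prof
        sc <- divergence_scores(ov, prof)
        usage_rows[[length(usage_rows) + 1L]] <-
          cbind(data.frame(dinucleotide = xy, class = cls), sc)
      }
    }
    strata_out[[xy]] <- list(strata = st, spectra = specs, peaks = peaks,
                             distances = dist, permutation = perm)
  }
  structure(list(counts = tab, overall_spectrum = overall_spec,
                 overall_peak = overall_peak, strata = strata_out,
                 usage = do.call(rbind, usage_rows),
                 rf = c(list(overall = rf_overall), rf_strata),
                 window = as.integer(window), passes = as.integer(passes),
                 call = cl),
            class = "kmerstrat")
}

#' @export
print.kmerstrat <- function(x, ...) {
  cat("Stratified ", x$counts$k, "-mer spectrum analysis\n", sep = "")
  cat("  windows counted:", format(x$counts$windows, big.mark = ","),
      "| overall peak at x =", x$overall_peak$x_hat, "\n")
  for (xy in names(x$strata)) {
    s <- x$strata[[xy]]
    pk <- vapply(s$peaks, function(p) p$x_hat, numeric(1))
    cat("  ", xy, ": peaks N0(p)=", pk[["0"]], " N1(p)=", pk[["1"]],
        " N2(p)=", pk[["2"]], "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.kmerstrat <- function(object, ...) {
  structure(list(fit = object), class = "summary.kmerstrat")
}

#' @export
print.summary.kmerstrat <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPeak distances:\n")
  for (xy in names(f$strata)) {
    d <- f$strata[[xy]]$distances
    cat(" ", xy, paste0("D(", d$pair, ")=", d$distance, collapse = "  "),
        "\n")
    if (!is.null(d$p_value))
      cat("   p-values:", paste(format(d$p_value), collapse = "  "), "\n")
  }
  cat("\nUsage divergence (stratum vs overall):\n")
  print(f$usage, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Divergence scores of a fitted analysis
#'
#' @param object A `kmerstrat` object.
#' @param ... Unused.
#' @return The usage-divergence data.frame (`dinucleotide`, `class`, `m`,
#'   `nsre`, `s1`, `s2`).
#' @export
coef.kmerstrat <- function(object, ...) object$usage

#' Plot stratum spectra of a fitted analysis
#'
#' Draws the smoothed FA curves of the three strata of one dinucleotide
#' (base graphics), with peak positions marked.
#'
#' @param x A `kmerstrat` object.
#' @param dinucleotide Which stratification to plot (default the first).
#' @param xlim Optional x range; default covers the three peaks generously.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.kmerstrat <- function(x, dinucleotide = names(x$strata)[1],
                           xlim = NULL, ...) {
  s <- x$strata[[dinucleotide]]
  if (is.null(s)) stop("no stratification for ", dinucleotide)
  curves <- lapply(s$spectra, function(sp)
    smooth_spectrum(sp, x$window, x$passes))
  pk <- vapply(s$peaks, function(p) p$x_hat, numeric(1))
  if (is.null(xlim)) xlim <- c(0, max(pk) * 3)
  ymax <- max(vapply(curves, function(cv)
    max(cv$y[cv$x <= xlim[2]]), numeric(1)))
  cols <- c("0" = "black", "1" = "dodgerblue3", "2" = "firebrick3")
  graphics::plot(NA, xlim = xlim, ylim = c(0, ymax * 1.05),
                 xlab = "appearance count x", ylab = "FA",
                 main = paste0(dinucleotide, " strata, k = ", x$counts$k),
                 ...)
  for (cls in names(curves)) {
    graphics::lines(curves[[cls]]$x, curves[[cls]]$y, col = cols[cls])
    graphics::abline(v = pk[cls], col = cols[cls], lty = 3)
  }
  graphics::legend("topright", bty = "n", col = cols, lty = 1,
                   legend = paste0(c("0", "1", "2"), dinucleotide))
  invisible(x)
}

#' Table-style species summary for CG strata
#'
#' Runs the CG stratification with a permutation test on a genome FASTA and
#' returns one row per stratum pair with the observed peak distance and
#' permutation p-value (the layout of the cross-species comparison table).
#'
#' @param fasta Path to a genome FASTA file.
#' @param label Species/genome label for the output row.
#' @param B Permutation replicates (default 10000).
#' @param window,passes Smoothing configuration.
#' @param seed Integer seed.
#' @return Data.frame with columns `species`, `pair`, `distance`, `p_value`.
#' @export
reproduce_species_table <- function(fasta, label = basename(fasta),
                                    B = 10000L, window = 10L, passes = 1L,
                                    seed = 1L) {
  g <- read_genome(fasta)
  fit <- kmerstrat(g, dinucleotides = "CG", window = window,
                   passes = passes, B = B, seed = seed)
  d <- fit$strata$CG$distances
  data.frame(species = label, pair = d$pair, distance = d$distance,
             p_value = d$p_value)
}
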