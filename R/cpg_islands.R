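#' Sliding-window GC content and CpG observed/expected ratio
#'
#' Slides a window of `window` bp with step `step` along one sequence and
#' reports, per window, the GC fraction and the CpG observed/expected ratio
#' in the Gardiner-Garden form \eqn{O/E = N_{CG} \cdot W / (N_C \cdot N_G)},
#' with W the actual window length.  The final partial window is evaluated
#' with its actual length; windows containing N are skipped.  When a window
#' has no C or no G the ratio is defined as 0.
#'
#' @param g A `DNAString` or single-sequence `DNAStringSet`.
#' @param window Window size in bp (default 1000).
#' @param step Step size in bp (default 500).
#' @return Data.frame with columns `start`, `end` (0-based half-open),
#'   `gc_fraction`, `oe_ratio`.
#' @export
window_stats <- function(g, window = 1000L, step = 500L) {
  if (methods::is(g, "DNAStringSet")) {
    stopifnot(length(g) == 1L)
    g <- g[[1L]]
  }
  stopifnot(window >= 2L, step >= 1L)
  L <- length(g)
  if (L < 2L) return(data.frame(start = integer(0), end = integer(0),
                                gc_fraction = numeric(0),
                                oe_ratio = numeric(0)))
  starts <- seq.int(0L, max(L - 1L, 0L), by = step)
  starts <- starts[starts < L]
  ends <- pmin(starts + window, L)
  keep <- ends - starts >= 2L
  starts <- starts[keep]; ends <- ends[keep]
  views <- Biostrings::Views(g, start = starts + 1L, end = ends)
  base <- Biostrings::alphabetFrequency(views, baseOnly = TRUE)
  has_n <- base[, "other"] > 0L
  w <- ends - starts
  ncg <- Biostrings::vcountPattern("CG", views)
  nc <- base[, "C"]; ng <- base[, "G"]
  gc <- (nc + ng) / w
  oe <- ifelse(nc * ng > 0, ncg * w / (nc * ng), 0)
  out <- data.frame(start = starts, end = ends, gc_fraction = gc,
                    oe_ratio = oe)
  out[!has_n, , drop = FALSE]
}

#' Call CpG islands from window statistics
#'
#' Retains windows with GC fraction and CpG O/E ratio at or above the
#' thresholds (inclusive), and merges overlapping or adjacent retained
#' windows into maximal intervals.
#'
#' @param stats Data.frame from [window_stats()] (one sequence).
#' @param gc_min Minimum GC fraction (default 0.5).
#' @param oe_min Minimum CpG observed/expected ratio (default 0.6).
#' @return An object of class `island_annotation`: list with `intervals`
#'   (data.frame `start`, `end`, 0-based half-open, merged and sorted) and
#'   `params`.
#' @export
call_islands <- function(stats, gc_min = 0.5, oe_min = 0.6) {
  hit <- stats[stats$gc_fraction >= gc_min & stats$oe_ratio >= oe_min, ,
               drop = FALSE]
  merged <- merge_intervals(hit$start, hit$end)
  structure(list(intervals = merged,
                 params = list(gc_min = gc_min, oe_min = oe_min)),
            class = "island_annotation")
}

merge_intervals <- function(start, end) {
  if (length(start) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' @export
print.island_annotation <- function(x, ...) {
  iv <- x$intervals
  cat("CpG island annotation:", nrow(iv), "interval(s), ",
      sum(iv$end - iv$start), "bp total (gc >= ", x$params$gc_min,
      ", O/E >= ", x$params$oe_min, ")\n", sep = "")
  invisible(x)
}

#' Detect CpG islands in a sequence
#'
#' Convenience wrapper chaining [window_stats()] and [call_islands()].
#'
#' @inheritParams window_stats
#' @inheritParams call_islands
#' @param exclude Optional data.frame of 0-based half-open intervals (e.g.
#'   gene bodies from a BED file read with [read_bed()]); called islands that
#'   overlap any excluded interval are dropped.  Default: no exclusion.
#' @return An `island_annotation`.
#' @export
detect_islands <- function(g, window = 1000L, step = 500L, gc_min = 0.5,
                           oe_min = 0.6, exclude = NULL) {
  ann <- call_islands(window_stats(g, window, step), gc_min, oe_min)
  if (!is.null(exclude) && nrow(ann$intervals) > 0L && nrow(exclude) > 0L) {
    iv <- ann$intervals
    keep <- vapply(seq_len(nrow(iv)), function(i)
      !any(iv$start[i] < exclude$end & exclude$start < iv$end[i]),
      logical(1))
    ann$intervals <- iv[keep, , drop = FALSE]
  }
  ann$params <- c(ann$params, list(window = window, step = step))
  ann
}

#' Excise called islands from a sequence
#'
#' @param g A `DNAString` or single-sequence `DNAStringSet`.
#' @param annotation An `island_annotation` for the same sequence.
#' @return A `DNAStringSet` of the complement segments (see
#'   [excise_intervals()]).
#' @export
remove_islands <- function(g, annotation) {
  stopifnot(inherits(annotation, "island_annotation"))
  excise_intervals(g, annotation$intervals)
}
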