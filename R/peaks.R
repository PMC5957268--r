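#' Percentile-threshold peak calling
#'
#' The threshold is the `percentile`-th percentile (linear interpolation)
#' of all bin scores genome-wide, zeros included.  Peaks are maximal runs of
#' consecutive same-chromosome bins with score strictly above the threshold
#' and at least `min_bins` bins long (the default 2 bins = 300 bp at the
#' 150 bp grid).
#'
#' @param track A normalized, input-subtracted `BinnedTrack`.
#' @param percentile Percentile in (0, 100); default 98.
#' @param min_bins Minimum run length in bins; default 2.
#' @param per_chrom Compute the threshold per chromosome instead of
#'   genome-wide.
#' @param nonzero_only Restrict the percentile to nonzero bins.
#' @return A `PeakSet`: `data.table` with `chrom`, `start`, `end`
#'   (grid-aligned, 0-based half-open), `n_bins`, `mean_score`,
#'   `max_score`, and attribute `threshold`.
#' @export
call_peaks <- function(track, percentile = 98, min_bins = 2L,
                       per_chrom = FALSE, nonzero_only = FALSE) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  grid <- track$grid
  thr_of <- function(x) {
    if (nonzero_only) x <- x[x != 0]
    if (!length(x)) return(Inf)
    stats::quantile(x, percentile / 100, type = 7, names = FALSE)
  }
  thr_global <- if (per_chrom) NA_real_ else thr_of(track$score)
  out <- list()
  for (ci in seq_along(grid$n_bins)) {
    sc <- track$score[grid$offset[ci] + seq_len(grid$n_bins[ci])]
    t <- if (per_chrom) thr_of(sc) else thr_global
    r <- rle(sc > t)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_bins)
    if (!length(keep)) next
    chrom <- names(grid$n_bins)[ci]
    out[[length(out) + 1L]] <- data.table::rbindlist(lapply(keep, function(j) {
      k0 <- run_start[j] - 1L
      k1 <- run_end[j] - 1L
      s <- sc[run_start[j]:run_end[j]]
      data.table::data.table(
        chrom = chrom,
        start = k0 * grid$bin_size,
        end = min((k1 + 1L) * grid$bin_size, grid$chrom_sizes[ci]),
        n_bins = r$lengths[j],
        mean_score = mean(s), max_score = max(s))
    }))
  }
  peaks <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(chrom = character(), start = numeric(),
                           end = numeric(), n_bins = integer(),
                           mean_score = numeric(), max_score = numeric())
  data.table::setattr(peaks, "threshold", thr_global)
  data.table::setattr(peaks, "class", c("PeakSet", class(peaks)))
  peaks[]
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = if (nrow(peaks)) peaks$chrom else character(),
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' Peak overlap statistics
#'
#' Counts peaks of one set overlapping at least 1 bp of the other, in both
#' directions, with the exclusive counts used for Venn-style summaries.
#'
#' @param a,b `PeakSet`s on the same genome.
#' @return List: `n_a`, `n_b`, `n_a_overlap`, `n_b_overlap`,
#'   `frac_a_overlap`, `frac_b_overlap`, `n_a_only`, `n_b_only`.
#' @export
overlap_peaks <- function(a, b) {
  ga <- peaks_to_granges(a)
  gb <- peaks_to_granges(b)
  ao <- sum(IRanges::overlapsAny(ga, gb))
  bo <- sum(IRanges::overlapsAny(gb, ga))
  list(n_a = length(ga), n_b = length(gb),
       n_a_overlap = ao, n_b_overlap = bo,
       frac_a_overlap = if (length(ga)) ao / length(ga) else NA_real_,
       frac_b_overlap = if (length(gb)) bo / length(gb) else NA_real_,
       n_a_only = length(ga) - ao, n_b_only = length(gb) - bo)
}

#' Length-normalized peak density per chromosome
#'
#' @param peaks A `PeakSet`.
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @return `data.table` with `chrom`, `n_peaks`, `mb`, `peaks_per_mb`.
#' @export
peak_density <- function(peaks, chrom_sizes) {
  n <- vapply(names(chrom_sizes),
              function(ch) sum(peaks$chrom == ch), integer(1))
  data.table::data.table(chrom = names(chrom_sizes), n_peaks = n,
                         mb = chrom_sizes / 1e6,
                         peaks_per_mb = n / (chrom_sizes / 1e6))
}
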