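#' Binned coverage track
#'
#' A `BinnedTrack` carries one per-bin score per grid bin for a single sample,
#' together with sample metadata (strain, gender, animal, mark) and the
#' library size the scores were derived from.  Raw tracks hold read counts;
#' [normalize_track()] rescales them to a common sequencing depth and
#' [subtract_input()] removes background measured in a matched non-enriched
#' (input) library.
#'
#' @param score Numeric vector, one value per grid bin.
#' @param grid A [bin_grid()].
#' @param meta Named list of sample metadata (free-form; the pipeline uses
#'   `sample`, `strain`, `gender`, `animal`, `mark`).
#' @param library_size Total mapped reads the track was built from.
#' @return Object of class `BinnedTrack`.
#' @export
binned_track <- function(score, grid, meta = list(), library_size = NA_real_) {
  stopifnot(inherits(grid, "BinGrid"))
  if (length(score) != grid$total_bins)
    stop("score length (", length(score), ") != grid bin count (",
         grid$total_bins, ")")
  structure(list(score = as.numeric(score), grid = grid, meta = meta,
                 library_size = as.numeric(library_size)),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  id <- if (!is.null(x$meta$sample)) x$meta$sample else "<unnamed>"
  cat(sprintf("BinnedTrack %s: %d bins, library %.0f, mean score %.3f\n",
              id, length(x$score), x$library_size, mean(x$score)))
  invisible(x)
}

#' Count reads into grid bins
#'
#' Each read increments exactly one bin: the bin containing its midpoint
#' `floor((start + end) / 2)`.  Coordinates are 0-based half-open (BED
#' convention).  The sum of bin counts therefore equals the number of reads.
#'
#' @param reads `data.table`/`data.frame` with columns `chrom`, `start`,
#'   `end`, or a `GRanges` (converted to 0-based half-open).
#' @param grid A [bin_grid()].
#' @param meta Sample metadata list passed on to the track.
#' @return `BinnedTrack` of raw counts with `library_size = nrow(reads)`.
#' @export
bin_reads <- function(reads, grid, meta = list()) {
  if (methods::is(reads, "GRanges")) {
    reads <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(reads)),
      start = GenomicRanges::start(reads) - 1L,
      end = GenomicRanges::end(reads))
  }
  score <- numeric(grid$total_bins)
  n <- nrow(reads)
  if (n > 0L) {
    unknown <- setdiff(unique(reads$chrom), names(grid$chrom_sizes))
    if (length(unknown)) {
      bad <- which(reads$chrom %in% unknown)[1L]
      stop(sprintf("read on unknown chromosome: %s:%d-%d (record %d)",
                   reads$chrom[bad], reads$start[bad], reads$end[bad], bad))
    }
    mid <- (reads$start + reads$end) %/% 2
    idx <- bin_index_of(grid, reads$chrom, mid)
    score <- tabulate(idx, nbins = grid$total_bins)
  }
  binned_track(score, grid, meta = meta, library_size = n)
}

#' Normalize a track by total read count
#'
#' Rescales per-bin scores to a common sequencing depth:
#' `score * target_depth / library_size`.  At full scale the reference depth
#' is typically the cohort's characteristic library size (tens of millions of
#' reads); the pipeline defaults to the cohort mean so that normalized scores
#' stay on the per-bin read-count scale that the absolute promoter threshold
#' assumes.
#'
#' @param track A `BinnedTrack` of raw counts.
#' @param target_depth Reference depth in reads.
#' @return Normalized `BinnedTrack` (library_size preserved in metadata).
#' @export
normalize_track <- function(track, target_depth) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (is.na(track$library_size) || track$library_size <= 0)
    stop("track has zero or unknown library size; cannot normalize")
  if (target_depth <= 0) stop("target_depth must be positive")
  out <- track
  out$score <- track$score * (target_depth / track$library_size)
  out$meta$normalized_to <- target_depth
  out
}

#' Subtract an input (non-enriched) track
#'
#' Per-bin `max(0, track - input)`; both tracks must be normalized on the
#' same grid.  Negative differences are clipped to zero because downstream
#' percentile and threshold logic assume non-negative enrichment.
#'
#' @param track,input_track Normalized `BinnedTrack`s on the same grid.
#' @return Input-subtracted `BinnedTrack`.
#' @export
subtract_input <- function(track, input_track) {
  stopifnot(inherits(track, "BinnedTrack"), inherits(input_track, "BinnedTrack"))
  if (!same_grid(track$grid, input_track$grid))
    stop("track and input are on different grids")
  out <- track
  out$score <- pmax(0, track$score - input_track$score)
  out$meta$input <- if (!is.null(input_track$meta$sample))
    input_track$meta$sample else "input"
  out
}

#' Average several tracks bin-wise
#'
#' Arithmetic mean per bin, e.g. to build the per-group average datasets the
#' replicate tracks are summarized into.
#'
#' @param tracks Non-empty list of `BinnedTrack`s sharing a grid.
#' @param meta Metadata for the averaged track.
#' @return `BinnedTrack` of per-bin means.
#' @export
average_tracks <- function(tracks, meta = list()) {
  if (!length(tracks)) stop("no tracks to average")
  grid <- tracks[[1L]]$grid
  for (t in tracks) {
    stopifnot(inherits(t, "BinnedTrack"))
    if (!same_grid(t$grid, grid)) stop("tracks are on different grids")
  }
  m <- rowMeans(vapply(tracks, function(t) t$score,
                       numeric(grid$total_bins)))
  meta$n_averaged <- length(tracks)
  binned_track(m, grid, meta = meta,
               library_size = mean(vapply(tracks, function(t) t$library_size,
                                          numeric(1))))
}
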