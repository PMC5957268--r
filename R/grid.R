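#' Genome-wide fixed-width bin grid
#'
#' Tiles each chromosome with half-open windows `[k*bin_size, (k+1)*bin_size)`
#' in 0-based coordinates; the last window of a chromosome is truncated at the
#' chromosome end.  Every bin has a global index (1-based in R) obtained by
#' concatenating chromosomes in the order of `chrom_sizes`, so a score track
#' is a plain numeric vector of length `total_bins`.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param bin_size Window width in bp (default 150).
#' @return An object of class `BinGrid`.
#' @export
bin_grid <- function(chrom_sizes, bin_size = 150L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  bin_size <- as.integer(bin_size)
  if (bin_size <= 0) stop("bin_size must be positive")
  n_bins <- as.integer(ceiling(chrom_sizes / bin_size))
  offset <- c(0L, cumsum(n_bins))[seq_along(n_bins)]
  names(offset) <- names(n_bins) <- names(chrom_sizes)
  structure(
    list(bin_size = bin_size,
         chrom_sizes = chrom_sizes,
         n_bins = n_bins,
         offset = offset,
         total_bins = sum(n_bins)),
    class = "BinGrid")
}

#' @export
print.BinGrid <- function(x, ...) {
  cat(sprintf("BinGrid: %d chromosome(s), %d bp bins, %d bins total\n",
              length(x$chrom_sizes), x$bin_size, x$total_bins))
  invisible(x)
}

#' Bin coordinate table for a grid
#'
#' @param grid A [bin_grid()].
#' @return `data.table` with columns `chrom`, `start`, `end`, `index`
#'   (0-based half-open coordinates, 1-based global index).
#' @export
grid_bins <- function(grid) {
  stopifnot(inherits(grid, "BinGrid"))
  chrom <- rep(names(grid$n_bins), grid$n_bins)
  k <- unlist(lapply(grid$n_bins, function(n) seq_len(n) - 1L), use.names = FALSE)
  start <- k * grid$bin_size
  end <- pmin(start + grid$bin_size, rep(grid$chrom_sizes, grid$n_bins))
  data.table::data.table(chrom = chrom, start = start, end = end,
                         index = seq_len(grid$total_bins))
}

## global (1-based) bin index of 0-based positions; positions must lie in
## [0, chrom length)
bin_index_of <- function(grid, chrom, pos) {
  unknown <- setdiff(unique(chrom), names(grid$chrom_sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  len <- grid$chrom_sizes[chrom]
  if (any(pos < 0 | pos >= len))
    stop("position(s) outside chromosome bounds")
  grid$offset[chrom] + pos %/% grid$bin_size + 1L
}

## widths of every bin (only terminal bins can be short)
bin_widths <- function(grid) {
  w <- rep(grid$bin_size, grid$total_bins)
  last <- grid$offset + grid$n_bins
  w[last] <- grid$chrom_sizes - (grid$n_bins - 1L) * grid$bin_size
  w
}

same_grid <- function(a, b) {
  identical(a$bin_size, b$bin_size) &&
    identical(a$chrom_sizes, b$chrom_sizes)
}
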