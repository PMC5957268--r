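## File formats.  All interval formats use the BED convention: 0-based,
## half-open.  Gene models travel as BED12 (exon blocks), peaks as BED6,
## tracks as bedGraph; those go through rtracklayer.  Raw read sets are plain
## BED3 and are streamed with data.table for throughput.

#' Read a chrom.sizes file
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  cs <- data.table::fread(path, header = FALSE, col.names = c("chrom", "size"))
  stats::setNames(as.numeric(cs$size), cs$chrom)
}

#' Write a chrom.sizes file
#' @param chrom_sizes Named numeric vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  data.table::fwrite(
    data.table::data.table(chrom = names(chrom_sizes),
                           size = as.integer(chrom_sizes)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED3 read set
#' @param path BED3 file of mapped-read intervals.
#' @return `data.table` with columns `chrom`, `start`, `end`.
#' @export
read_reads_bed <- function(path) {
  data.table::fread(path, header = FALSE, select = 1:3,
                    col.names = c("chrom", "start", "end"))
}

#' Write a BED3 read set
#' @param reads `data.table` with `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_reads_bed <- function(reads, path) {
  data.table::fwrite(reads[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

## GeneSet <-> GRanges (1-based) conversion used by the BED12 round trip
genes_to_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  names(gr) <- genes$gene_id
  gr$name <- genes$gene_id
  gr$score <- 0L
  gr$thick <- IRanges::ranges(gr)
  gr$blocks <- IRanges::IRangesList(lapply(seq_len(nrow(genes)), function(i) {
    IRanges::IRanges(start = genes$exon_starts[[i]] + 1L,
                     width = genes$exon_sizes[[i]])
  }))
  gr
}

#' Write gene models as BED12
#' @param genes A `GeneSet` (see [build_toy_genome()]).
#' @param path Output path.
#' @export
write_genes_bed12 <- function(genes, path) {
  rtracklayer::export(genes_to_granges(genes), path, format = "BED")
  invisible(path)
}

#' Read gene models from BED12
#' @param path BED12 file with strand and exon blocks.
#' @return A `GeneSet` `data.table` with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, and list columns
#'   `exon_starts` (offsets relative to gene start) and `exon_sizes`.
#' @export
read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  blocks <- gr$blocks
  genes <- data.table::data.table(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    exon_starts = lapply(seq_along(gr), function(i)
      IRanges::start(blocks[[i]]) - 1L),
    exon_sizes = lapply(seq_along(gr), function(i)
      IRanges::width(blocks[[i]])))
  data.table::setattr(genes, "class", c("GeneSet", class(genes)))
  genes[]
}

#' Transcription start sites of a gene set
#'
#' 0-based TSS base: gene start on the plus strand, `end - 1` on the minus
#' strand.  Gene records with several annotated starts are represented by a
#' single interval here, so this is the 5'-most start of the record.
#'
#' @param genes A `GeneSet`.
#' @return Integer vector of 0-based TSS positions, named by gene id.
#' @export
tss_positions <- function(genes) {
  stats::setNames(ifelse(genes$strand == "+", genes$start, genes$end - 1L),
                  genes$gene_id)
}

#' Write a track as bedGraph
#'
#' Adjacent bins with equal score are merged into one run.  Coordinates are
#' 0-based half-open.
#'
#' @param track A `BinnedTrack`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  grid <- track$grid
  rows <- vector("list", length(grid$n_bins))
  for (ci in seq_along(grid$n_bins)) {
    chrom <- names(grid$n_bins)[ci]
    sc <- track$score[grid$offset[ci] + seq_len(grid$n_bins[ci])]
    r <- rle(sc)
    ends_bin <- cumsum(r$lengths)
    starts <- c(0, ends_bin[-length(ends_bin)]) * grid$bin_size
    ends <- pmin(ends_bin * grid$bin_size, grid$chrom_sizes[ci])
    rows[[ci]] <- data.table::data.table(chrom = chrom, start = starts,
                                         end = ends, score = r$values)
  }
  out <- data.table::rbindlist(rows)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file onto a grid
#'
#' Inverse of [write_bedgraph()]: every interval must be bin-aligned on the
#' given grid (as written by this package); scores are expanded back to one
#' value per bin.
#'
#' @param path bedGraph file.
#' @param grid The `BinGrid` the file was written from.
#' @param meta Metadata for the returned track.
#' @return A `BinnedTrack`.
#' @export
read_bedgraph <- function(path, grid, meta = list()) {
  bg <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  score <- numeric(grid$total_bins)
  first <- bin_index_of(grid, bg$chrom, bg$start)
  nbin <- ceiling((bg$end - bg$start) / grid$bin_size)
  score[unlist(Map(function(f, n) f + seq_len(n) - 1L, first, nbin))] <-
    rep(bg$score, nbin)
  binned_track(score, grid, meta = meta)
}

#' Write a peak set as BED6
#'
#' The BED score column is `mean_score` rescaled to 0-1000 across the set;
#' full precision is kept in the TSV written alongside by the pipeline.
#'
#' @param peaks A `PeakSet` from [call_peaks()].
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = "*")
  gr$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  top <- max(peaks$mean_score)
  gr$score <- if (top > 0) as.integer(round(1000 * peaks$mean_score / top))
              else rep(0L, nrow(peaks))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}
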