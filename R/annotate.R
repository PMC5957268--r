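#' Assign genomic compartments to grid bins
#'
#' Every bin receives exactly one of six labels based on its midpoint, with
#' fixed priority `promoter_core > promoter_proximal > promoter_distal >
#' exonic > intronic > intergenic`.  Promoter windows are strand-aware
#' around the TSS: core = TSS +/- 250 bp; proximal = 250 bp to 1 kb
#' upstream; distal = 1 kb to 2 kb upstream.
#'
#' @param genes A `GeneSet` with strand and exon blocks.
#' @param grid A `BinGrid`.
#' @return Factor of length `grid$total_bins` with the six compartment
#'   levels.
#' @export
assign_compartments <- function(genes, grid) {
  levels <- c("promoter_core", "promoter_proximal", "promoter_distal",
              "exonic", "intronic", "intergenic")
  lab <- rep("intergenic", grid$total_bins)
  if (any(genes$end > grid$chrom_sizes[genes$chrom] | genes$start < 0))
    stop("gene beyond chromosome bounds")
  bins <- grid_bins(grid)
  mid <- (bins$start + bins$end) / 2
  paint <- function(chrom, start, end, label) {
    # assign label to bins whose midpoint falls in [start, end)
    for (i in seq_along(chrom)) {
      idx <- window_bins(grid, chrom[i], max(0, start[i]),
                         min(grid$chrom_sizes[chrom[i]], end[i]))
      idx <- idx[mid[idx] >= start[i] & mid[idx] < end[i]]
      lab[idx] <<- label
    }
  }
  tss <- tss_positions(genes)
  up <- function(d1, d2) {  # strand-aware upstream window [d1, d2) from TSS
    s <- ifelse(genes$strand == "+", tss - d2, tss + d1 + 1L)
    list(start = s, end = s + (d2 - d1))
  }
  # paint in reverse priority so higher priority overwrites
  paint(genes$chrom, genes$start, genes$end, "intronic")
  for (i in seq_len(nrow(genes))) {
    ex_s <- genes$start[i] + genes$exon_starts[[i]]
    paint(rep(genes$chrom[i], length(ex_s)), ex_s,
          ex_s + genes$exon_sizes[[i]], "exonic")
  }
  d <- up(1000L, 2000L)
  paint(genes$chrom, d$start, d$end, "promoter_distal")
  p <- up(250L, 1000L)
  paint(genes$chrom, p$start, p$end, "promoter_proximal")
  paint(genes$chrom, tss - 250L, tss + 250L, "promoter_core")
  factor(lab, levels = levels)
}

#' Per-compartment score summary
#'
#' Five-number summary (min, Q1, median, Q3, max) plus mean of the bin
#' scores in each compartment; the numbers behind a compartment box plot.
#'
#' @param track A `BinnedTrack`.
#' @param labels Compartment factor from [assign_compartments()] on the
#'   same grid.
#' @return `data.table`, one row per compartment.
#' @export
compartment_summary <- function(track, labels) {
  stopifnot(length(labels) == length(track$score))
  out <- lapply(levels(labels), function(lv) {
    x <- track$score[labels == lv]
    if (!length(x))
      return(data.table::data.table(compartment = lv, n_bins = 0L,
                                    min = NA_real_, q1 = NA_real_,
                                    median = NA_real_, q3 = NA_real_,
                                    max = NA_real_, mean = NA_real_))
    q <- stats::quantile(x, c(0, .25, .5, .75, 1), names = FALSE)
    data.table::data.table(compartment = lv, n_bins = length(x),
                           min = q[1], q1 = q[2], median = q[3],
                           q3 = q[4], max = q[5], mean = mean(x))
  })
  data.table::rbindlist(out)
}

## integral of the per-base step function from 0 to x, per chromosome;
## positions outside [0, chrom length] contribute nothing
track_integral <- function(track) {
  grid <- track$grid
  w <- bin_widths(grid)
  cums <- lapply(seq_along(grid$n_bins), function(ci) {
    idx <- grid$offset[ci] + seq_len(grid$n_bins[ci])
    c(0, cumsum(track$score[idx] * w[idx]))
  })
  names(cums) <- names(grid$n_bins)
  function(chrom, x) {
    ci <- match(chrom, names(grid$n_bins))
    cum <- cums[[ci]]
    L <- grid$chrom_sizes[ci]
    x <- pmin(pmax(x, 0), L)
    k <- pmin(x %/% grid$bin_size, grid$n_bins[ci] - 1L)
    cum[k + 1L] + (x - k * grid$bin_size) *
      track$score[grid$offset[ci] + k + 1L]
  }
}

#' Length-normalized metagene profile
#'
#' Rescales each region's interior to `n_interior` equal sub-windows and
#' averages bin scores into each window weighted by overlap length (the
#' exact integral of the per-bin step function over the window).  Flanks
#' are either a fraction of the region length (rescaled the same way) or a
#' fixed width in bp, split into `n_flank` windows each.  Minus-strand
#' regions are reversed so all profiles read 5' to 3'; the profile is the
#' unweighted mean over regions per window position.  Windows reaching
#' beyond the chromosome are zero-padded.
#'
#' @param track A `BinnedTrack`.
#' @param regions `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand` (`"+"` assumed when absent).
#' @param n_interior Interior window count (default 100).
#' @param flank_frac Flank length as a fraction of each region's length.
#' @param flank_bp Fixed flank length in bp.  At most one of `flank_frac`
#'   and `flank_bp` may be set.
#' @param n_flank Windows per flank; defaults to `round(n_interior *
#'   flank_frac)` or `round(flank_bp / bin_size)`.
#' @return A `MetaProfile`: `data.table` with `window` (1-based, 5' to 3'),
#'   `zone` (`upstream`/`interior`/`downstream`), `mean`; attributes
#'   `n_regions`, `n_skipped`, `n_interior`, `n_flank`, `flank`.
#' @export
metagene_profile <- function(track, regions, n_interior = 100L,
                             flank_frac = NULL, flank_bp = NULL,
                             n_flank = NULL) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (!is.null(flank_frac) && !is.null(flank_bp))
    stop("give only one of flank_frac and flank_bp")
  bs <- track$grid$bin_size
  if (is.null(n_flank))
    n_flank <- if (!is.null(flank_frac)) max(1L, round(n_interior * flank_frac))
               else if (!is.null(flank_bp)) max(1L, round(flank_bp / bs))
               else 0L
  if (is.null(flank_frac) && is.null(flank_bp)) n_flank <- 0L
  regions <- as.data.frame(regions)
  if (is.null(regions$strand)) regions$strand <- "+"
  keep <- (regions$end - regions$start) >= bs
  n_skipped <- sum(!keep)
  if (n_skipped) message(n_skipped, " region(s) shorter than one bin skipped")
  regions <- regions[keep, , drop = FALSE]
  if (!nrow(regions)) stop("no usable regions")
  n_win <- n_interior + 2L * n_flank
  I <- track_integral(track)
  acc <- numeric(n_win)
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i]; e <- regions$end[i]
    f <- if (!is.null(flank_frac)) flank_frac * (e - s)
         else if (!is.null(flank_bp)) flank_bp else 0
    bounds <- c(if (n_flank) seq(s - f, s, length.out = n_flank + 1L)[-(n_flank + 1L)],
                seq(s, e, length.out = n_interior + 1L),
                if (n_flank) seq(e, e + f, length.out = n_flank + 1L)[-1L])
    v <- diff(I(regions$chrom[i], bounds)) / diff(bounds)
    if (regions$strand[i] == "-") v <- rev(v)
    acc <- acc + v
  }
  prof <- data.table::data.table(
    window = seq_len(n_win),
    zone = rep(c("upstream", "interior", "downstream"),
               c(n_flank, n_interior, n_flank)),
    mean = acc / nrow(regions))
  data.table::setattr(prof, "n_regions", nrow(regions))
  data.table::setattr(prof, "n_skipped", n_skipped)
  data.table::setattr(prof, "n_interior", n_interior)
  data.table::setattr(prof, "n_flank", n_flank)
  data.table::setattr(prof, "flank",
                      if (!is.null(flank_frac)) list(frac = flank_frac)
                      else if (!is.null(flank_bp)) list(bp = flank_bp)
                      else list())
  data.table::setattr(prof, "class", c("MetaProfile", class(prof)))
  prof[]
}

#' Window-wise difference of two profiles
#'
#' Signed difference (no clipping), e.g. male minus female average signal.
#'
#' @param profile_a,profile_b `MetaProfile`s with identical window
#'   specifications.
#' @return A `MetaProfile` of window-wise `a - b`.
#' @export
differential_profile <- function(profile_a, profile_b) {
  for (at in c("n_interior", "n_flank", "flank"))
    if (!identical(attr(profile_a, at), attr(profile_b, at)))
      stop("profiles have different window specifications (", at, ")")
  out <- data.table::copy(profile_a)
  out$mean <- profile_a$mean - profile_b$mean
  out[]
}
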