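#' Configuration for the synthetic epigenome generator
#'
#' Defines a toy genome and cohort with the statistical structure the
#' analysis assumes: Poisson per-bin sequencing background, multiplicative
#' antibody-style enrichment at planted features (promoter classes,
#' strain-differential gene bodies, poised/active enhancers), per-sample
#' library-size variation, and a gender-biased expression matrix.  Group
#' sizes mirror the study design the pipeline targets: `n_animals_dna`
#' animals per strain x gender group for the DNA modifications (5mC, 5hmC),
#' two shared input libraries per strain x gender, and `n_animals_chip`
#' animals per gender (one strain) for the chromatin marks.
#'
#' Strain-differential gene bodies are planted at `diff_fold = 8`, above the
#' fivefold calling threshold, so calls have margin against Poisson noise.
#' `library_size_mean = NULL` derives the reference depth from the
#' configuration (`background_rate` x total bins, ~133 k reads at the
#' default toy scale) so that depth-normalized scores stay on the per-bin
#' read-count scale the absolute promoter threshold of 5 assumes.
#'
#' @param seed Integer seed; a fixed seed makes every simulated file
#'   byte-identical across runs.
#' @param n_chrom,chrom_length,n_genes,bin_size Toy-genome dimensions.
#' @param n_animals_dna Animals per strain x gender group, DNA marks.
#' @param n_animals_chip Animals per gender, chromatin marks.
#' @param library_size_mean Reference library size (reads); `NULL` derives
#'   it from `background_rate` and the grid.
#' @param library_size_cv Coefficient of variation of per-sample depth.
#' @param background_rate Expected reads per bin in a non-enriched library.
#' @param enrich_promoter,enrich_genic,enrich_enhancer Enrichment
#'   multipliers for planted promoter, gene-body and enhancer features.
#' @param diff_fold Multiplier applied in the elevated strain at planted
#'   strain-differential gene bodies.
#' @param deplete_enhancer_5mc Multiplicative 5mC depletion at enhancer
#'   cores (< 1).
#' @param gender_genic_fold Genic 5hmC multiplier in the active gender at
#'   gender-biased genes; kept below `diff_fold` so strain structure
#'   dominates gender structure.
#' @param read_length Emitted read length in bp (reads are anchored in
#'   their generating bin so midpoint binning is exactly invertible).
#' @param expr_log2fc_gender Planted log2 expression effect at
#'   gender-biased genes.
#' @param expr_noise_sd Per-animal log2 expression noise.
#' @param n_animals_expr Animals per gender in the expression matrix.
#' @param fracs Named list of planted-class fractions of `n_genes`:
#'   `prom_ii_5mc`, `prom_ii_5hmc`, `prom_strain` (each of the two
#'   strain-specific promoter classes, per mark), `genic_diff` (each
#'   direction, per mark), `genic_expr` (expression-coupled genic 5hmC),
#'   `enh_poised`, `enh_active`, `gender` (each direction).
#' @param min_gene_len,max_gene_len,gene_flank Gene-placement geometry (bp);
#'   `gene_flank` is the guaranteed clearance around each gene so 1-5 kb
#'   upstream enhancer zones never touch a neighboring gene's promoter.
#' @return Validated list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 5e6,
                       n_genes = 400L,
                       bin_size = 150L,
                       n_animals_dna = 5L,
                       n_animals_chip = 3L,
                       library_size_mean = NULL,
                       library_size_cv = 0.1,
                       background_rate = 2.0,
                       enrich_promoter = 8,
                       enrich_genic = 6,
                       diff_fold = 8,
                       enrich_enhancer = 8,
                       deplete_enhancer_5mc = 0.2,
                       gender_genic_fold = 4,
                       read_length = 200L,
                       expr_log2fc_gender = 2.5,
                       expr_noise_sd = 0.2,
                       n_animals_expr = 4L,
                       fracs = list(prom_ii_5mc = 0.20, prom_ii_5hmc = 0.05,
                                    prom_strain = 0.03, genic_diff = 0.025,
                                    genic_expr = 0.20, enh_poised = 0.05,
                                    enh_active = 0.05, gender = 0.03),
                       min_gene_len = 1500L,
                       max_gene_len = 8000L,
                       gene_flank = 12000L) {
  cfg <- as.list(environment())
  if (is.null(cfg$library_size_mean)) {
    total_bins <- n_chrom * ceiling(chrom_length / bin_size)
    cfg$library_size_mean <- background_rate * total_bins
  }
  for (f in c("enrich_promoter", "enrich_genic", "diff_fold",
              "enrich_enhancer", "gender_genic_fold"))
    if (cfg[[f]] <= 1) stop(f, " must exceed 1")
  if (deplete_enhancer_5mc >= 1 || deplete_enhancer_5mc <= 0)
    stop("deplete_enhancer_5mc must lie in (0, 1)")
  if (min_gene_len < 10L * bin_size)
    stop("gene bodies must span at least 10 bins")
  if (read_length >= 2L * bin_size)
    stop("read_length must be below twice the bin size")
  if (n_genes > 0L) {
    per_chrom <- ceiling(n_genes / n_chrom)
    slot <- floor(chrom_length / per_chrom)
    if (slot < gene_flank + max_gene_len + 5000)
      stop("cannot place ", n_genes, " non-overlapping genes with ",
           gene_flank, " bp clearance on this genome")
  }
  structure(cfg, class = "SimConfig")
}

## split n genes over chromosomes as evenly as possible
genes_per_chrom <- function(n_genes, n_chrom) {
  base <- n_genes %/% n_chrom
  extra <- n_genes %% n_chrom
  base + c(rep(1L, extra), rep(0L, n_chrom - extra))
}

#' Build the toy genome and gene annotation
#'
#' Places stranded genes with exon blocks in regular slots along each
#' chromosome, leaving at least `gene_flank` bp of clearance on both sides
#' of every gene so that upstream enhancer zones (1-5 kb from the TSS) can
#' never overlap a neighboring gene or its promoter windows.
#'
#' @param config A [sim_config()].
#' @return List with `chrom_sizes` (named vector) and `genes` (a `GeneSet`
#'   `data.table`; see [read_genes_bed12()] for columns).
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  chrom_sizes <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                                 sprintf("chr%d", seq_len(config$n_chrom)))
  counts <- genes_per_chrom(config$n_genes, config$n_chrom)
  rows <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chrom)) {
    k <- counts[ci]
    if (k == 0L) next
    slot <- floor(config$chrom_length / k)
    for (i in seq_len(k)) {
      gi <- gi + 1L
      glen <- config$min_gene_len +
        sample.int(config$max_gene_len - config$min_gene_len, 1L)
      gstart <- (i - 1L) * slot + config$gene_flank
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(2:6, 1L)
      cuts <- sort(sample.int(glen - 1L, 2L * n_ex - 2L))
      bounds <- c(0L, cuts, glen)
      seg_start <- bounds[-length(bounds)]
      seg_len <- diff(bounds)
      ex <- seq(1L, 2L * n_ex - 1L, by = 2L)
      rows[[gi]] <- data.table::data.table(
        gene_id = sprintf("g%04d", gi),
        chrom = names(chrom_sizes)[ci],
        start = gstart, end = gstart + glen, strand = strand,
        exon_starts = list(seg_start[ex]), exon_sizes = list(seg_len[ex]))
    }
  }
  genes <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(gene_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character(),
                           exon_starts = list(), exon_sizes = list())
  data.table::setattr(genes, "class", c("GeneSet", class(genes)))
  list(chrom_sizes = chrom_sizes, genes = genes[])
}

#' Plant epigenetic features and emit the truth table
#'
#' Assigns each gene (per DNA mark) a promoter class and a gene-body
#' differential label, places poised/active enhancer elements 1-5 kb
#' upstream of the TSS (strand-aware) for a subset of genes, and assigns
#' gender-biased expression labels.  Class sizes are deterministic
#' (`round(fraction x n_genes)` each).  Two classes are coupled to the
#' per-gene baseline expression level so that expression-stratified
#' contrasts hold on synthetic data: the highest-baseline genes carry genic
#' 5hmC enrichment and the lowest-baseline genes carry constitutive promoter
#' 5mC (class ii); all remaining classes are drawn from the middle of the
#' baseline distribution.
#'
#' @param genes A `GeneSet` from [build_toy_genome()].
#' @param config The [sim_config()].
#' @return A `TruthTable` `data.table`, one row per gene: promoter group per
#'   mark (`i`, `ii`, `iii_sd`, `iv_wistar`), genic differential label per
#'   mark (`none`, `wistar_up`, `sd_up`), `genic_expr` flag, enhancer state
#'   (`none`, `poised`, `active`) with its planted interval, gender bias
#'   (`none`, `male`, `female`) and the baseline log2 expression.
#' @export
plant_epigenome <- function(genes, config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- nrow(genes)
  if (n == 0L) stop("gene set is empty")
  set.seed(config$seed + 1L)
  f <- config$fracs
  baseline <- stats::runif(n, 2, 10)
  ord <- order(-baseline)
  n_top <- round(f$genic_expr * n)
  n_bot <- round(f$prom_ii_5mc * n)
  top <- ord[seq_len(n_top)]
  bot <- if (n_bot > 0L) ord[seq.int(n - n_bot + 1L, n)] else integer()
  middle <- sample(setdiff(ord, c(top, bot)))
  take <- function(k) {
    if (k == 0L) return(integer())
    if (k > length(middle))
      stop("planted-class fractions exceed available genes")
    sel <- middle[seq_len(k)]
    middle <<- middle[-seq_len(k)]
    sel
  }
  cnt <- function(fr) round(fr * n)

  truth <- data.table::data.table(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    gene_start = genes$start, gene_end = genes$end,
    tss = tss_positions(genes),
    baseline_expr = baseline,
    prom_group_5mc = "i", prom_group_5hmc = "i",
    genic_diff_5mc = "none", genic_diff_5hmc = "none",
    genic_expr = FALSE,
    enh_state = "none", enh_start = NA_integer_, enh_end = NA_integer_,
    gender_bias = "none")

  truth$genic_expr[top] <- TRUE
  truth$prom_group_5mc[bot] <- "ii"
  truth$prom_group_5mc[take(cnt(f$prom_strain))] <- "iii_sd"
  truth$prom_group_5mc[take(cnt(f$prom_strain))] <- "iv_wistar"
  truth$prom_group_5hmc[take(cnt(f$prom_ii_5hmc))] <- "ii"
  truth$prom_group_5hmc[take(cnt(f$prom_strain))] <- "iii_sd"
  truth$prom_group_5hmc[take(cnt(f$prom_strain))] <- "iv_wistar"
  truth$genic_diff_5mc[take(cnt(f$genic_diff))] <- "wistar_up"
  truth$genic_diff_5mc[take(cnt(f$genic_diff))] <- "sd_up"
  truth$genic_diff_5hmc[take(cnt(f$genic_diff))] <- "wistar_up"
  truth$genic_diff_5hmc[take(cnt(f$genic_diff))] <- "sd_up"
  enh_genes <- c(take(cnt(f$enh_poised)), take(cnt(f$enh_active)))
  truth$enh_state[enh_genes] <- rep(c("poised", "active"),
                                    c(cnt(f$enh_poised), cnt(f$enh_active)))
  truth$gender_bias[take(cnt(f$gender))] <- "male"
  truth$gender_bias[take(cnt(f$gender))] <- "female"

  for (g in enh_genes) {
    len <- 599L + sample.int(901L, 1L)           # 600-1500 bp
    off <- 999L + sample.int(5000L - len - 999L, 1L)  # 1000 .. 5000-len
    if (truth$strand[g] == "+") {
      truth$enh_end[g] <- truth$tss[g] - off
      truth$enh_start[g] <- truth$enh_end[g] - len
    } else {
      truth$enh_start[g] <- truth$tss[g] + off
      truth$enh_end[g] <- truth$enh_start[g] + len
    }
  }
  data.table::setattr(truth, "class", c("TruthTable", class(truth)))
  truth[]
}

## bins overlapping a 0-based half-open interval on one chromosome
window_bins <- function(grid, chrom, start, end) {
  ci <- match(chrom, names(grid$chrom_sizes))
  k0 <- max(0L, start %/% grid$bin_size)
  k1 <- min(grid$n_bins[ci] - 1L, (end - 1L) %/% grid$bin_size)
  if (k1 < k0) return(integer())
  grid$offset[ci] + seq.int(k0, k1) + 1L
}

## bins whose midpoint lies in [start, end)
midpoint_bins <- function(grid, chrom, start, end) {
  idx <- window_bins(grid, chrom, start, end)
  if (!length(idx)) return(idx)
  ci <- match(chrom, names(grid$chrom_sizes))
  k <- idx - grid$offset[ci] - 1L
  w <- pmin((k + 1L) * grid$bin_size, grid$chrom_sizes[ci]) - k * grid$bin_size
  mid <- k * grid$bin_size + w / 2
  idx[mid >= start & mid < end]
}

## precomputed per-gene bin index lists shared across samples
plant_bin_index <- function(truth, grid, half_window = 250L) {
  n <- nrow(truth)
  prom <- genic <- enh <- vector("list", n)
  for (g in seq_len(n)) {
    pw <- window_bins(grid, truth$chrom[g],
                      truth$tss[g] - half_window, truth$tss[g] + half_window)
    gb <- midpoint_bins(grid, truth$chrom[g],
                        truth$gene_start[g], truth$gene_end[g])
    prom[[g]] <- pw
    genic[[g]] <- setdiff(gb, pw)   # keep promoter-core truth independent
    enh[[g]] <- if (truth$enh_state[g] == "none") integer() else
      midpoint_bins(grid, truth$chrom[g], truth$enh_start[g], truth$enh_end[g])
  }
  list(prom = prom, genic = genic, enh = enh)
}

## per-bin rate multiplier for one sample; product over planted features
rate_multipliers <- function(truth, grid, config, mark, strain, gender,
                             index = NULL) {
  if (is.null(index)) index <- plant_bin_index(truth, grid)
  mult <- rep(1, grid$total_bins)
  bump <- function(bins, f) if (length(bins)) mult[bins] <<- mult[bins] * f
  if (mark == "input") return(mult)
  if (mark %in% c("5mC", "5hmC")) {
    grp <- if (mark == "5mC") truth$prom_group_5mc else truth$prom_group_5hmc
    dif <- if (mark == "5mC") truth$genic_diff_5mc else truth$genic_diff_5hmc
    for (g in seq_len(nrow(truth))) {
      hit <- grp[g] == "ii" ||
        (grp[g] == "iii_sd" && strain == "sd") ||
        (grp[g] == "iv_wistar" && strain == "wistar")
      if (hit) bump(index$prom[[g]], config$enrich_promoter)
      if ((dif[g] == "wistar_up" && strain == "wistar") ||
          (dif[g] == "sd_up" && strain == "sd"))
        bump(index$genic[[g]], config$diff_fold)
      if (mark == "5hmC") {
        if (truth$genic_expr[g]) bump(index$genic[[g]], config$enrich_genic)
        if (truth$gender_bias[g] == gender)
          bump(index$genic[[g]], config$gender_genic_fold)
        if (truth$enh_state[g] == "poised")
          bump(index$enh[[g]], config$enrich_enhancer)
      } else {
        if (truth$enh_state[g] != "none")
          bump(index$enh[[g]], config$deplete_enhancer_5mc)
      }
    }
  } else if (mark %in% c("H3K4me1", "H3K27ac")) {
    for (g in seq_len(nrow(truth))) {
      if ((mark == "H3K4me1" && truth$enh_state[g] != "none") ||
          (mark == "H3K27ac" && truth$enh_state[g] == "active"))
        bump(index$enh[[g]], config$enrich_enhancer)
      if (truth$genic_expr[g])   # active promoters carry both marks
        bump(index$prom[[g]], config$enrich_promoter)
    }
  } else stop("unknown mark: ", mark)
  mult
}

#' Simulate one sample's read set
#'
#' Per-bin counts are drawn from `Poisson(background_rate x multiplier x
#' depth_factor)` where the multiplier is the product of enrichments of
#' planted features overlapping the bin and the depth factor models
#' library-size variation (`Normal(1, library_size_cv)`, truncated to
#' `[0.5, 1.5]`).  Reads are emitted as fixed-length intervals anchored in
#' their generating bin, so the read midpoint always falls back in that bin
#' and [bin_reads()] is exactly invertible on simulated data.
#'
#' @param truth A `TruthTable`.
#' @param grid The simulation `BinGrid`.
#' @param config The [sim_config()].
#' @param mark One of `"5mC"`, `"5hmC"`, `"H3K4me1"`, `"H3K27ac"`, `"input"`.
#' @param strain `"sd"` or `"wistar"`.
#' @param gender `"male"` or `"female"`.
#' @param stream Integer sub-stream offset making each sample's randomness
#'   distinct while fully determined by `config$seed`.
#' @param index Optional precomputed [plant_bin_index()] (shared across
#'   samples for speed).
#' @return `data.table` of reads (`chrom`, `start`, `end`) with attributes
#'   `depth_factor` and `library_size`.
#' @export
simulate_sample_reads <- function(truth, grid, config, mark, strain, gender,
                                  stream = 0L, index = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (!mark %in% c("5mC", "5hmC", "H3K4me1", "H3K27ac", "input"))
    stop("unknown mark: ", mark)
  if (!strain %in% c("sd", "wistar")) stop("unknown strain: ", strain)
  if (!gender %in% c("male", "female")) stop("unknown gender: ", gender)
  set.seed(config$seed + 10L + as.integer(stream))
  mult <- rate_multipliers(truth, grid, config, mark, strain, gender, index)
  f <- min(max(stats::rnorm(1, 1, config$library_size_cv), 0.5), 1.5)
  counts <- stats::rpois(grid$total_bins, config$background_rate * f * mult)
  bins <- grid_bins(grid)
  nz <- which(counts > 0L)
  bw <- bins$end[nz] - bins$start[nz]
  rl <- pmin(config$read_length, bw)
  s <- bins$start[nz] + (bw - rl) %/% 2L
  len <- grid$chrom_sizes[bins$chrom[nz]]
  s <- pmax(0L, pmin(s, as.integer(len - rl)))
  reads <- data.table::data.table(
    chrom = rep(bins$chrom[nz], counts[nz]),
    start = rep(s, counts[nz]),
    end = rep(s + rl, counts[nz]))
  data.table::setattr(reads, "depth_factor", f)
  data.table::setattr(reads, "library_size", nrow(reads))
  reads[]
}

#' Simulate the liver expression matrix
#'
#' log2 expression = per-gene baseline + gender effect
#' (`+expr_log2fc_gender` in the biased gender) + per-animal noise
#' (`Normal(0, expr_noise_sd)`), for `n_animals_expr` animals per gender.
#'
#' @param truth A `TruthTable` (provides baselines and gender-bias labels).
#' @param config The [sim_config()].
#' @return Numeric matrix genes x samples with a `gender` attribute giving
#'   each column's gender.
#' @export
simulate_expression <- function(truth, config) {
  set.seed(config$seed + 2L)
  na <- config$n_animals_expr
  gender <- rep(c("male", "female"), each = na)
  samples <- sprintf("wistar_%s_%d", gender, rep(seq_len(na), 2L))
  n <- nrow(truth)
  effect <- outer(truth$gender_bias, gender,
                  function(b, g) ifelse(b == g, config$expr_log2fc_gender, 0))
  mat <- truth$baseline_expr + effect +
    matrix(stats::rnorm(n * 2L * na, 0, config$expr_noise_sd), n)
  dimnames(mat) <- list(truth$gene_id, samples)
  attr(mat, "gender") <- gender
  mat
}

#' Simulate a multi-tissue expression panel
#'
#' Small panel (four tissues x two genders, one sample each) with planted
#' tissue-specific genes (induced in exactly one tissue) and housekeeping
#' genes (uniformly high, low variability), for exercising the
#' tissue-specific and housekeeping gene-set selectors.
#'
#' @param truth A `TruthTable` (supplies gene ids).
#' @param config The [sim_config()].
#' @param n_specific,n_housekeeping Planted genes per class (default 10%
#'   of the gene set each).
#' @return List with `log2` (matrix genes x samples), `tissue` and `gender`
#'   per column, and `labels` (`data.table` gene_id, class).
#' @export
simulate_tissue_panel <- function(truth, config,
                                  n_specific = max(2L, round(0.1 * nrow(truth))),
                                  n_housekeeping = max(2L, round(0.1 * nrow(truth)))) {
  set.seed(config$seed + 3L)
  tissues <- c("liver", "lung", "kidney", "heart")
  tissue <- rep(tissues, each = 2L)
  gender <- rep(c("male", "female"), 4L)
  samples <- paste(tissue, gender, sep = "_")
  n <- nrow(truth)
  if (n < 4L * n_specific + n_housekeeping)
    stop("too few genes for the requested planted classes")
  pool <- sample.int(n)
  class <- rep("none", n)
  for (ti in seq_along(tissues)) {
    sel <- pool[seq_len(n_specific) + (ti - 1L) * n_specific]
    class[sel] <- tissues[ti]
  }
  hk <- pool[seq_len(n_housekeeping) + 4L * n_specific]
  class[hk] <- "housekeeping"
  mat <- matrix(stats::runif(n, 2, 6), n, 8L) +
    matrix(stats::rnorm(n * 8L, 0, 0.3), n)
  for (ti in seq_along(tissues))
    mat[class == tissues[ti], tissue == tissues[ti]] <-
      mat[class == tissues[ti], tissue == tissues[ti]] + 4
  mat[class == "housekeeping", ] <-
    10 + matrix(stats::rnorm(sum(class == "housekeeping") * 8L, 0, 0.1),
                sum(class == "housekeeping"))
  dimnames(mat) <- list(truth$gene_id, samples)
  list(log2 = mat, tissue = tissue, gender = gender,
       labels = data.table::data.table(gene_id = truth$gene_id, class = class))
}

#' Cohort sample sheet implied by a configuration
#'
#' DNA marks: `n_animals_dna` animals per strain x gender, each paired to
#' one of two shared input libraries per strain x gender.  Chromatin marks:
#' `n_animals_chip` animals per gender, Wistar only, paired to the matching
#' Wistar input.
#'
#' @param config A [sim_config()].
#' @return `data.table` with `sample`, `strain`, `gender`, `animal`,
#'   `mark`, `input` (paired input sample id, `NA` for inputs) and
#'   `stream` (RNG sub-stream).
#' @export
sample_sheet <- function(config) {
  rows <- list()
  add <- function(strain, gender, animal, mark) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      sample = paste(strain, gender, animal, mark, sep = "_"),
      strain = strain, gender = gender, animal = animal, mark = mark)
  }
  for (strain in c("sd", "wistar"))
    for (gender in c("male", "female")) {
      for (animal in seq_len(2L)) add(strain, gender, animal, "input")
      for (mark in c("5mC", "5hmC"))
        for (animal in seq_len(config$n_animals_dna))
          add(strain, gender, animal, mark)
    }
  for (gender in c("male", "female"))
    for (mark in c("H3K4me1", "H3K27ac"))
      for (animal in seq_len(config$n_animals_chip))
        add("wistar", gender, animal, mark)
  sheet <- data.table::rbindlist(rows)
  sheet$input <- ifelse(
    sheet$mark == "input", NA_character_,
    paste(sheet$strain, sheet$gender, (sheet$animal - 1L) %% 2L + 1L,
          "input", sep = "_"))
  sheet$stream <- seq_len(nrow(sheet))
  sheet[]
}

#' Simulate a full cohort (and optionally write it to disk)
#'
#' Runs [build_toy_genome()], [plant_epigenome()], [simulate_sample_reads()]
#' for every sample in the [sample_sheet()], [simulate_expression()] and
#' [simulate_tissue_panel()].  With `dir` set, writes `chrom.sizes`,
#' `genes.bed` (BED12), `truth.tsv`, `sample_sheet.tsv`, `expression.tsv`,
#' `expression_samples.tsv`, `tissue_panel.tsv`, `tissue_samples.tsv` and
#' one BED3 read file per sample under `reads/`, named
#' `{strain}_{gender}_{animal}_{mark}.bed`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return (Invisibly when writing) list with `config`, `chrom_sizes`,
#'   `grid`, `genes`, `truth`, `samples`, `reads` (named list of
#'   data.tables), `expr`, `tissue`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  genome <- build_toy_genome(config)
  grid <- bin_grid(genome$chrom_sizes, config$bin_size)
  truth <- plant_epigenome(genome$genes, config)
  index <- plant_bin_index(truth, grid)
  sheet <- sample_sheet(config)
  reads <- vector("list", nrow(sheet))
  names(reads) <- sheet$sample
  for (i in seq_len(nrow(sheet)))
    reads[[i]] <- simulate_sample_reads(
      truth, grid, config, mark = sheet$mark[i], strain = sheet$strain[i],
      gender = sheet$gender[i], stream = sheet$stream[i], index = index)
  expr <- simulate_expression(truth, config)
  tissue <- simulate_tissue_panel(truth, config)
  out <- list(config = config, chrom_sizes = genome$chrom_sizes, grid = grid,
              genes = genome$genes, truth = truth, samples = sheet,
              reads = reads, expr = expr, tissue = tissue)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
    write_chrom_sizes(genome$chrom_sizes, file.path(dir, "chrom.sizes"))
    write_genes_bed12(genome$genes, file.path(dir, "genes.bed"))
    write_tsv(truth, file.path(dir, "truth.tsv"))
    write_tsv(sheet, file.path(dir, "sample_sheet.tsv"))
    write_tsv(data.table::data.table(gene_id = rownames(expr), expr),
              file.path(dir, "expression.tsv"))
    write_tsv(data.table::data.table(sample = colnames(expr),
                                     gender = attr(expr, "gender"),
                                     tissue = "liver"),
              file.path(dir, "expression_samples.tsv"))
    write_tsv(data.table::data.table(gene_id = rownames(tissue$log2),
                                     tissue$log2),
              file.path(dir, "tissue_panel.tsv"))
    write_tsv(data.table::data.table(sample = colnames(tissue$log2),
                                     tissue = tissue$tissue,
                                     gender = tissue$gender),
              file.path(dir, "tissue_samples.tsv"))
    for (s in sheet$sample)
      write_reads_bed(reads[[s]], file.path(dir, "reads", paste0(s, ".bed")))
    return(invisible(out))
  }
  out
}
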