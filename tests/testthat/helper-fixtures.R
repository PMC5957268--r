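# Shared fixtures, built once per test run.  The "small" cohort keeps the
# full study design (2 strains x 2 genders, both DNA marks, chromatin marks,
# shared inputs) at a reduced scale so module tests stay fast; acceptance
# tests build the default-scale cohort themselves.

small_cfg <- function(seed = 5L) {
  sim_config(seed = seed, n_chrom = 1L, chrom_length = 1.5e6, n_genes = 50L,
             n_animals_dna = 3L, n_animals_chip = 2L)
}

.fixtures <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixtures$cohort)) .fixtures$cohort <- simulate_cohort(small_cfg())
  .fixtures$cohort
}

small_tracks <- function() {
  if (is.null(.fixtures$tracks)) {
    co <- small_cohort()
    .fixtures$tracks <- build_tracks(co$reads, co$samples, co$grid)
  }
  .fixtures$tracks
}

# cohort written to disk for pipeline tests (one shared copy)
small_cohort_dir <- function() {
  if (is.null(.fixtures$dir)) {
    d <- file.path(tempdir(), "epibase-small-cohort")
    if (!dir.exists(d)) simulate_cohort(small_cfg(), dir = d)
    .fixtures$dir <- d
  }
  .fixtures$dir
}

small_pipeline_config <- function(out_dir) {
  d <- small_cohort_dir()
  pipeline_config(
    reads_dir = file.path(d, "reads"),
    genes_file = file.path(d, "genes.bed"),
    chrom_sizes_file = file.path(d, "chrom.sizes"),
    sample_sheet_file = file.path(d, "sample_sheet.tsv"),
    expression_file = file.path(d, "expression.tsv"),
    expression_samples_file = file.path(d, "expression_samples.tsv"),
    out_dir = out_dir)
}

# single-chromosome grid + track helpers for synthetic score vectors
toy_grid <- function(n_bins, bin_size = 150L, chrom = "chrT") {
  bin_grid(stats::setNames(n_bins * bin_size, chrom), bin_size)
}

toy_track <- function(score, bin_size = 150L, chrom = "chrT") {
  binned_track(score, toy_grid(length(score), bin_size, chrom),
               library_size = max(1, sum(score)))
}
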