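#' Pipeline configuration
#'
#' Collects the file paths and every numeric parameter of the end-to-end
#' analysis.  All thresholds default to the values the analysis is defined
#' with: 150 bp bins, 98th-percentile peaks of at least 2 bins (300 bp),
#' promoter threshold 5 over TSS +/- 250 bp, fivefold gene-body rule with
#' pseudocount 1, enhancer window 1-5 kb from the TSS, gender-bias
#' threshold log2 1.5, top-250 gene sets.
#'
#' @param reads_dir Directory of per-sample BED3 read files named
#'   `<sample>.bed`.
#' @param genes_file BED12 gene annotation.
#' @param chrom_sizes_file chrom.sizes file.
#' @param sample_sheet_file TSV with columns `sample`, `strain`, `gender`,
#'   `animal`, `mark`, `input` (paired input sample id; `NA` for inputs).
#' @param expression_file,expression_samples_file Expression matrix TSV and
#'   its sample table (`sample`, `gender`).
#' @param out_dir Output directory.
#' @param bin_size,target_depth,percentile,min_peak_bins,promoter_threshold,promoter_half_window,fold,pseudocount,enhancer_near,enhancer_far,log2fc,top_n,n_interior
#'   Analysis parameters; `target_depth = NULL` normalizes to the cohort
#'   mean library size.
#' @param input_pooling Background correction mode, see [build_tracks()].
#' @return Validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(reads_dir, genes_file, chrom_sizes_file,
                            sample_sheet_file, expression_file,
                            expression_samples_file, out_dir,
                            bin_size = 150L, target_depth = NULL,
                            percentile = 98, min_peak_bins = 2L,
                            promoter_threshold = 5,
                            promoter_half_window = 250L,
                            fold = 5, pseudocount = 1,
                            enhancer_near = 5000L, enhancer_far = 1000L,
                            log2fc = 1.5, top_n = 250L, n_interior = 100L,
                            input_pooling = c("group", "paired")) {
  cfg <- as.list(environment())
  cfg$input_pooling <- match.arg(input_pooling)
  for (p in c("bin_size", "percentile", "min_peak_bins", "promoter_threshold",
              "promoter_half_window", "fold", "pseudocount", "enhancer_near",
              "enhancer_far", "log2fc", "top_n", "n_interior"))
    if (cfg[[p]] < 0) stop(p, " must be non-negative")
  for (f in c("genes_file", "chrom_sizes_file", "sample_sheet_file",
              "expression_file", "expression_samples_file"))
    if (!file.exists(cfg[[f]])) stop("missing file: ", cfg[[f]])
  if (!dir.exists(reads_dir)) stop("missing reads directory: ", reads_dir)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end analysis
#'
#' Stages: binning, depth normalization, input subtraction and bedGraph
#' export for every sample; per-group average tracks; compartment
#' summaries; peak calling, gender overlap and enhancer definition for the
#' chromatin marks; promoter-group classification, within-gender
#' strain-differential gene calling and Z-score matrices for the DNA
#' marks; gender-biased gene calling, expression quintiles and metagene /
#' differential profiles; per-mark correlation matrices and Ward trees; a
#' run manifest and a tabular report.  Deterministic given the inputs: no
#' stage draws random numbers.  On error, partial outputs are removed.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) list of in-memory results mirroring the main output
#'   files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  created <- !dir.exists(config$out_dir)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(config$out_dir, recursive = TRUE))
  out <- config$out_dir
  for (d in c("tracks", "peaks", "classify", "profiles", "compare"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)

  grid <- bin_grid(read_chrom_sizes(config$chrom_sizes_file),
                   config$bin_size)
  genes <- read_genes_bed12(config$genes_file)
  sheet <- data.table::fread(config$sample_sheet_file)
  sheet$input[!is.na(sheet$input) & sheet$input == ""] <- NA_character_
  missing_pair <- !is.na(sheet$input) & !(sheet$input %in% sheet$sample)
  if (any(missing_pair))
    stop("sample(s) with unresolved input pairing: ",
         paste(sheet$sample[missing_pair], collapse = ", "))

  ## --- coverage ---------------------------------------------------------
  reads <- lapply(sheet$sample, function(s) {
    f <- file.path(config$reads_dir, paste0(s, ".bed"))
    if (!file.exists(f)) stop("missing reads file: ", f)
    read_reads_bed(f)
  })
  names(reads) <- sheet$sample
  built <- build_tracks(reads, sheet, grid,
                        target_depth = config$target_depth,
                        input_pooling = config$input_pooling)
  tracks <- built$tracks
  libs <- built$library_sizes
  target <- built$target_depth
  assay <- names(tracks)
  for (s in assay)
    write_bedgraph(tracks[[s]], file.path(out, "tracks", paste0(s, ".bedGraph")))

  meta_of <- function(s) sheet[match(s, sheet$sample), ]
  marks <- unique(sheet$mark[!is.na(sheet$input)])
  dna_marks <- intersect(c("5mC", "5hmC"), marks)
  chip_marks <- intersect(c("H3K4me1", "H3K27ac"), marks)

  ## per strain x gender average tracks
  averages <- list()
  for (mk in marks) {
    sub <- sheet[sheet$mark == mk, ]
    for (st in unique(sub$strain)) for (gd in unique(sub$gender)) {
      ids <- sub$sample[sub$strain == st & sub$gender == gd]
      if (!length(ids)) next
      key <- paste(mk, st, gd, sep = "_")
      averages[[key]] <- average_tracks(tracks[ids],
                                        meta = list(sample = key, mark = mk,
                                                    strain = st, gender = gd))
      write_bedgraph(averages[[key]],
                     file.path(out, "tracks", paste0("avg_", key, ".bedGraph")))
    }
  }

  ## --- compartments -----------------------------------------------------
  compartments <- assign_compartments(genes, grid)
  comp_tabs <- lapply(names(averages), function(key)
    data.table::data.table(track = key,
                           compartment_summary(averages[[key]], compartments)))
  write_tsv(data.table::rbindlist(comp_tabs),
            file.path(out, "compare", "compartment_summary.tsv"))

  ## --- peaks and enhancers (chromatin marks) ----------------------------
  peaks <- list()
  enhancers <- list()
  overlaps <- list()
  if (length(chip_marks)) {
    chip_strain <- unique(sheet$strain[sheet$mark %in% chip_marks])[1L]
    for (mk in chip_marks) for (gd in c("male", "female")) {
      key <- paste(mk, chip_strain, gd, sep = "_")
      if (is.null(averages[[key]])) next
      pk <- call_peaks(averages[[key]], percentile = config$percentile,
                       min_bins = config$min_peak_bins)
      peaks[[paste(mk, gd, sep = "_")]] <- pk
      write_peaks_bed(pk, file.path(out, "peaks", paste0(mk, "_", gd, ".bed")))
      write_tsv(pk, file.path(out, "peaks", paste0(mk, "_", gd, ".tsv")))
      write_tsv(peak_density(pk, grid$chrom_sizes),
                file.path(out, "peaks", paste0(mk, "_", gd, "_density.tsv")))
    }
    for (mk in chip_marks) {
      a <- peaks[[paste(mk, "male", sep = "_")]]
      b <- peaks[[paste(mk, "female", sep = "_")]]
      if (!is.null(a) && !is.null(b))
        overlaps[[paste0(mk, "_male_vs_female")]] <- overlap_peaks(a, b)
    }
    for (gd in c("male", "female")) {
      k4 <- peaks[[paste("H3K4me1", gd, sep = "_")]]
      k27 <- peaks[[paste("H3K27ac", gd, sep = "_")]]
      if (is.null(k4) || is.null(k27)) next
      overlaps[[paste0("k4_vs_k27_", gd)]] <- overlap_peaks(k4, k27)
      enhancers[[gd]] <- define_enhancers(
        k4, k27, genes, near = config$enhancer_near,
        far_excl = config$enhancer_far)
      write_tsv(enhancers[[gd]],
                file.path(out, "classify", paste0("enhancers_", gd, ".tsv")))
    }
    write_tsv(data.table::rbindlist(lapply(names(overlaps), function(nm)
      data.table::data.table(comparison = nm, overlaps[[nm]]))),
      file.path(out, "peaks", "overlap_stats.tsv"))
  }

  ## --- promoter groups and differential genes (DNA marks) ---------------
  promoter_calls <- list()
  diff_calls <- list()
  for (mk in dna_marks) {
    ids <- sheet$sample[sheet$mark == mk]
    pc <- classify_promoters(tracks[ids], genes,
                             strains = sheet$strain[match(ids, sheet$sample)],
                             threshold = config$promoter_threshold,
                             half_window = config$promoter_half_window)
    promoter_calls[[mk]] <- pc
    write_tsv(pc, file.path(out, "classify", paste0("promoters_", mk, ".tsv")))
    for (gd in c("male", "female")) {
      wi <- sheet$sample[sheet$mark == mk & sheet$gender == gd &
                           sheet$strain == "wistar"]
      sd <- sheet$sample[sheet$mark == mk & sheet$gender == gd &
                           sheet$strain == "sd"]
      if (length(wi) < 2L || length(sd) < 2L) next
      dc <- call_differential_genes(tracks[wi], tracks[sd], genes,
                                    fold = config$fold,
                                    pseudocount = config$pseudocount,
                                    labels = c("wistar_up", "sd_up"))
      diff_calls[[paste(mk, gd, sep = "_")]] <- dc
      write_tsv(dc, file.path(out, "classify",
                              paste0("diffgenes_", mk, "_", gd, ".tsv")))
      if (nrow(dc)) {
        gm <- cbind(attr(dc, "scores_a"), attr(dc, "scores_b"))
        z <- zscore_matrix(gm[dc$gene_id, , drop = FALSE])
        write_tsv(data.table::data.table(gene_id = rownames(z), z),
                  file.path(out, "classify",
                            paste0("zscore_", mk, "_", gd, ".tsv")))
      }
      writeLines(sort(unique(dc$gene_id)),
                 file.path(out, "classify",
                           paste0("genelist_diff_", mk, "_", gd, ".txt")))
    }
  }

  ## --- expression integration -------------------------------------------
  expr <- read_expression(config$expression_file)
  expr_samples <- data.table::fread(config$expression_samples_file)
  gender <- expr_samples$gender[match(colnames(expr), expr_samples$sample)]
  gender_calls <- call_gender_biased_genes(expr, gender,
                                           log2fc = config$log2fc)
  write_tsv(gender_calls,
            file.path(out, "classify", "gender_biased_genes.tsv"))
  quint <- expression_quintiles(rowMeans(expr))
  write_tsv(data.table::data.table(
    gene_id = unlist(quint),
    quintile = rep(names(quint), lengths(quint))),
    file.path(out, "classify", "expression_quintiles.tsv"))

  ## --- profiles ----------------------------------------------------------
  gene_regions <- data.frame(chrom = genes$chrom, start = genes$start,
                             end = genes$end, strand = genes$strand)
  rownames(gene_regions) <- genes$gene_id
  profiles <- list()
  for (key in names(averages)) {
    pr <- metagene_profile(averages[[key]], gene_regions,
                           n_interior = config$n_interior, flank_frac = 0.25)
    profiles[[paste0("genebody_", key)]] <- pr
    write_tsv(pr, file.path(out, "profiles",
                            paste0("genebody_", key, ".tsv")))
  }
  ## expression-quintile profiles on the all-sample mark averages
  for (mk in dna_marks) {
    keys <- grep(paste0("^", mk, "_"), names(averages), value = TRUE)
    mark_avg <- average_tracks(averages[keys], meta = list(mark = mk))
    for (q in names(quint)) {
      sel <- intersect(quint[[q]], rownames(gene_regions))
      if (!length(sel)) next
      pr <- metagene_profile(mark_avg, gene_regions[sel, , drop = FALSE],
                             n_interior = config$n_interior,
                             flank_frac = 0.25)
      profiles[[paste0("quintile_", q, "_", mk)]] <- pr
      write_tsv(pr, file.path(out, "profiles",
                              paste0("quintile_", q, "_", mk, ".tsv")))
    }
    ## enhancer-centered DNA modification profiles (male calls)
    if (!is.null(enhancers$male) && nrow(enhancers$male)) {
      for (st in c("poised", "active")) {
        e <- enhancers$male[enhancers$male$state == st, ]
        if (!nrow(e)) next
        pr <- metagene_profile(mark_avg,
                               data.frame(chrom = e$chrom, start = e$start,
                                          end = e$end, strand = "+"),
                               n_interior = config$n_interior,
                               flank_frac = 1)
        profiles[[paste0("enhancer_", st, "_", mk)]] <- pr
        write_tsv(pr, file.path(out, "profiles",
                                paste0("enhancer_", st, "_", mk, ".tsv")))
      }
    }
    ## male - female differential profile over gender-biased genes
    mkeys <- grep("_male$", keys, value = TRUE)
    fkeys <- grep("_female$", keys, value = TRUE)
    sel <- intersect(gender_calls$gene_id, rownames(gene_regions))
    if (length(mkeys) && length(fkeys) && length(sel)) {
      male_avg <- average_tracks(averages[mkeys])
      female_avg <- average_tracks(averages[fkeys])
      dp <- differential_profile(
        metagene_profile(male_avg, gene_regions[sel, , drop = FALSE],
                         n_interior = config$n_interior, flank_frac = 0.25),
        metagene_profile(female_avg, gene_regions[sel, , drop = FALSE],
                         n_interior = config$n_interior, flank_frac = 0.25))
      profiles[[paste0("gender_diff_", mk)]] <- dp
      write_tsv(dp, file.path(out, "profiles",
                              paste0("gender_diff_", mk, ".tsv")))
    }
  }

  ## --- similarity and clustering ----------------------------------------
  clusterings <- list()
  for (mk in marks) {
    ids <- sheet$sample[sheet$mark == mk]
    if (length(ids) < 2L) next
    sim <- pearson_matrix(tracks[ids])
    cl <- hcluster_samples(sim)
    clusterings[[mk]] <- list(similarity = sim, clustering = cl)
    write_tsv(data.table::data.table(sample = rownames(sim$cor), sim$cor),
              file.path(out, "compare", paste0("cor_", mk, ".tsv")))
    writeLines(cl$newick, file.path(out, "compare", paste0("tree_", mk, ".nwk")))
    write_tsv(data.table::data.table(merge_step = seq_along(cl$merge_heights),
                                     height = cl$merge_heights),
              file.path(out, "compare", paste0("merges_", mk, ".tsv")))
  }
  ## replicate variance by coding status, per DNA-mark group
  var_tabs <- list()
  for (mk in dna_marks) {
    sub <- sheet[sheet$mark == mk, ]
    for (st in unique(sub$strain)) for (gd in unique(sub$gender)) {
      ids <- sub$sample[sub$strain == st & sub$gender == gd]
      if (length(ids) < 2L) next
      vp <- variance_partition(tracks[ids], compartments)
      var_tabs[[paste(mk, st, gd, sep = "_")]] <-
        data.table::data.table(group = paste(mk, st, gd, sep = "_"),
                               vp$summary)
    }
  }
  if (length(var_tabs))
    write_tsv(data.table::rbindlist(var_tabs),
              file.path(out, "compare", "variance_partition.tsv"))

  ## --- manifest and report ----------------------------------------------
  params <- config[setdiff(names(config), c("target_depth", "out_dir"))]
  params$target_depth <- target
  manifest <- list(
    parameters = lapply(params, function(x) if (is.numeric(x)) unname(x) else x),
    library_sizes = as.list(stats::setNames(unname(libs), names(libs))),
    inputs = as.list(tools::md5sum(c(config$genes_file,
                                     config$chrom_sizes_file,
                                     config$sample_sheet_file,
                                     config$expression_file))))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  make_report(out)
  ok <- TRUE
  invisible(list(grid = grid, genes = genes, sheet = sheet, tracks = tracks,
                 averages = averages, compartments = compartments,
                 peaks = peaks, overlaps = overlaps, enhancers = enhancers,
                 promoter_calls = promoter_calls, diff_calls = diff_calls,
                 gender_calls = gender_calls, quintiles = quint,
                 profiles = profiles, clusterings = clusterings,
                 target_depth = target))
}

#' Summarize a pipeline output tree into a report
#'
#' Writes `report.md` with tabular analogues of the main figures: promoter
#' group counts, differential-gene counts, enhancer counts by state,
#' gender-biased gene counts, peak overlap fractions, compartment medians
#' and cluster leaf orders.  Missing stages are skipped with a notice.
#' Regeneration is idempotent.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @return Path to `report.md`, invisibly.
#' @export
make_report <- function(out_dir) {
  lines <- c("# Pipeline report", "")
  tab <- function(dt) {
    c(paste0("| ", paste(names(dt), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(dt)), collapse = "|"), "|"),
      vapply(seq_len(nrow(dt)), function(i)
        paste0("| ", paste(vapply(dt[i, ], function(x)
          if (is.numeric(x)) format(x, digits = 4) else as.character(x),
          character(1)), collapse = " | "), " |"), character(1)),
      "")
  }
  section <- function(title, glob, render) {
    files <- sort(Sys.glob(file.path(out_dir, glob)))
    lines <<- c(lines, paste("##", title), "")
    if (!length(files)) {
      lines <<- c(lines, "_Stage missing; section skipped._", "")
      return(invisible())
    }
    for (f in files) render(f)
  }
  section("Promoter groups", "classify/promoters_*.tsv", function(f) {
    x <- data.table::fread(f)
    cnt <- x[, .N, by = "group"][order(group)]
    lines <<- c(lines, paste0("**", basename(f), "**"), "", tab(cnt))
  })
  section("Strain-differential genes", "classify/diffgenes_*.tsv", function(f) {
    x <- data.table::fread(f)
    cnt <- if (nrow(x)) x[, .N, by = "direction"][order(direction)] else
      data.table::data.table(direction = "none", N = 0L)
    lines <<- c(lines, paste0("**", basename(f), "**"), "", tab(cnt))
  })
  section("Enhancers", "classify/enhancers_*.tsv", function(f) {
    x <- data.table::fread(f)
    cnt <- if (nrow(x)) x[, .N, by = "state"][order(state)] else
      data.table::data.table(state = "none called", N = 0L)
    lines <<- c(lines, paste0("**", basename(f), "**"), "", tab(cnt))
  })
  section("Gender-biased genes", "classify/gender_biased_genes.tsv",
          function(f) {
    x <- data.table::fread(f)
    cnt <- if (nrow(x)) x[, .N, by = "direction"][order(direction)] else
      data.table::data.table(direction = "none", N = 0L)
    lines <<- c(lines, tab(cnt))
  })
  section("Peak overlaps", "peaks/overlap_stats.tsv", function(f) {
    lines <<- c(lines, tab(data.table::fread(f)))
  })
  section("Compartment medians", "compare/compartment_summary.tsv",
          function(f) {
    x <- data.table::fread(f)
    lines <<- c(lines, tab(x[, c("track", "compartment", "median", "mean")]))
  })
  section("Sample clustering", "compare/tree_*.nwk", function(f) {
    lines <<- c(lines, paste0("**", basename(f), "**"), "", "```",
                readLines(f), "```", "")
  })
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(file.path(out_dir, "report.md"))
}
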