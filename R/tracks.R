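#' Build normalized, input-subtracted tracks for a cohort
#'
#' Convenience wrapper around [bin_reads()], [normalize_track()] and
#' [subtract_input()] for a whole sample sheet.  Every track is normalized
#' to `target_depth` (default: the cohort mean library size).  Background
#' correction uses either the group-matched input set (`input_pooling =
#' "group"`, default: the average of the normalized input tracks with the
#' same strain and gender) or the single paired input named in the sheet's
#' `input` column (`"paired"`).  Pooling the matched inputs uses all the
#' background sequencing available to a group and avoids tying each assay
#' track to one input library's private noise.
#'
#' @param reads Named list of read `data.table`s (BED3 columns), one per
#'   sample in `sheet`.
#' @param sheet Sample sheet (`sample`, `strain`, `gender`, `animal`,
#'   `mark`, `input`).
#' @param grid A `BinGrid`.
#' @param target_depth Normalization depth; `NULL` = cohort mean library.
#' @param input_pooling `"group"` or `"paired"`.
#' @return List: `tracks` (input-subtracted `BinnedTrack`s for all assay
#'   samples), `inputs` (normalized input tracks), `library_sizes`,
#'   `target_depth`.
#' @export
build_tracks <- function(reads, sheet, grid, target_depth = NULL,
                         input_pooling = c("group", "paired")) {
  input_pooling <- match.arg(input_pooling)
  raw <- lapply(sheet$sample, function(s)
    bin_reads(reads[[s]], grid, meta = as.list(sheet[sheet$sample == s, ])))
  names(raw) <- sheet$sample
  libs <- vapply(raw, function(t) t$library_size, numeric(1))
  target <- target_depth %||% mean(libs)
  norm <- lapply(raw, normalize_track, target_depth = target)
  is_input <- is.na(sheet$input)
  assay <- sheet$sample[!is_input]
  input_of <- function(s) {
    i <- match(s, sheet$sample)
    if (input_pooling == "paired")
      return(norm[[sheet$input[i]]])
    grp <- is_input & sheet$strain == sheet$strain[i] &
      sheet$gender == sheet$gender[i]
    average_tracks(norm[sheet$sample[grp]],
                   meta = list(sample = paste0(sheet$strain[i], "_",
                                               sheet$gender[i], "_input")))
  }
  tracks <- lapply(assay, function(s) subtract_input(norm[[s]], input_of(s)))
  names(tracks) <- assay
  list(tracks = tracks, inputs = norm[sheet$sample[is_input]],
       library_sizes = libs, target_depth = target)
}
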