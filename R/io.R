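#' Read and write the pipeline's tab-separated tables
#'
#' Segment tables use 1-based inclusive coordinates (SEG convention);
#' BED-style half-open input can be converted on read with
#' `zero_based = TRUE` (adds 1 to `start`). Column layouts:
#' segments `sample, chrom, start, end, copy, loh`; SNVs
#' `sample, chrom, pos, ref, alt, context96, alt_reads, depth`;
#' SVs `sample, chrom_a, pos_a, chrom_b, pos_b, type`;
#' metadata `sample, age_years, stage, timepoint, purity, ...`.
#' Loaders fill per-chromosome coverage gaps in segment profiles at the
#' sample's median copy level so downstream grid sampling never hits a
#' hole.
#'
#' @param path File path.
#' @param zero_based Segment input uses BED-style half-open coordinates.
#' @param fill_gaps Fill coverage gaps at the sample median copy.
#' @return A tibble.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
read_segments <- function(path, zero_based = FALSE, fill_gaps = TRUE) {
  seg <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(chrom = readr::col_character())) |>
    mutate(loh = as.logical(.data$loh))
  if (zero_based) seg <- seg |> mutate(start = .data$start + 1)
  check_profile(seg)
  if (fill_gaps) seg <- fill_profile_gaps(seg)
  seg
}

# close internal coverage gaps with median-copy filler segments
fill_profile_gaps <- function(profile) {
  profile |>
    group_by(.data$sample) |>
    group_modify(function(df, key) {
      med <- median(df$copy)
      filled <- df |> group_by(.data$chrom) |>
        group_modify(function(cd, ck) {
          cd <- cd |> arrange(.data$start)
          gaps <- which(cd$start[-1] > cd$end[-nrow(cd)] + 1)
          if (length(gaps) == 0) return(cd)
          filler <- tibble(start = cd$end[gaps] + 1, end = cd$start[gaps + 1] - 1,
                           copy = med, loh = FALSE)
          extra <- setdiff(names(cd), names(filler))
          for (nm in extra) filler[[nm]] <- cd[[nm]][gaps]
          bind_rows(cd, filler) |> arrange(.data$start)
        }) |> ungroup()
      filled
    }) |>
    ungroup()
}

#' @rdname cohort-io
#' @param x Tibble to write.
#' @export
write_segments <- function(x, path) { readr::write_tsv(x, path); invisible(path) }

#' @rdname cohort-io
#' @export
read_snvs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = readr::col_character()))
}

#' @rdname cohort-io
#' @export
read_svs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom_a = readr::col_character(),
                                          chrom_b = readr::col_character()))
}

#' @rdname cohort-io
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a simulated cohort to standard-format files
#'
#' Emits `segments.tsv`, `snvs.tsv`, `svs.tsv`, `metadata.tsv`,
#' `alterations.tsv`, `boundaries.tsv` and `truth.json` under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$profiles, file.path(dir, "segments.tsv"))
  readr::write_tsv(cohort$snvs, file.path(dir, "snvs.tsv"))
  readr::write_tsv(cohort$svs, file.path(dir, "svs.tsv"))
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(cohort$alterations, file.path(dir, "alterations.tsv"))
  readr::write_tsv(cohort$boundaries, file.path(dir, "boundaries.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         dataframe = "columns", digits = NA)
  } else {
    warn("jsonlite not installed; truth.json not written")
  }
  invisible(dir)
}
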