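#' Segment profiles
#'
#' A segment profile is a tibble with columns `sample`, `chrom`, `start`,
#' `end` (1-based inclusive), `copy` (absolute, non-logged copy units where
#' 2.0 is diploid) and `loh` (logical). Segments on one chromosome must not
#' overlap. All copy-number functions accept multi-sample profiles and
#' return per-sample results.
#' @name segment-profiles
#' @keywords internal
NULL

check_profile <- function(profile) {
  stopifnot(all(c("sample", "chrom", "start", "end", "copy", "loh") %in% names(profile)))
  stopifnot(all(profile$start <= profile$end), all(profile$copy >= 0))
  invisible(profile)
}

# copy level at each position, from the containing segment (NA in gaps)
copy_at <- function(segs, positions) {
  segs <- segs[order(segs$start), , drop = FALSE]
  idx <- findInterval(positions, segs$start)
  ok <- idx > 0
  ok[ok] <- positions[ok] <= segs$end[idx[ok]]
  out <- rep(NA_real_, length(positions))
  out[ok] <- segs$copy[idx[ok]]
  out
}

#' Sample the copy level of a profile on a fixed-step grid
#'
#' Copy levels are read from the containing segment at `step`-spaced
#' positions across a window, the grid the arm caller computes its medians
#' on. The grid is anchored at one end of the window (`anchor`), so that
#' when a window represents the terminal part of a chromosome arm the
#' telomeric base is always sampled.
#'
#' @param profile Single-sample segment profile (see [segment-profiles]).
#' @param chrom Chromosome name.
#' @param window Numeric `c(start, end)` in bp, 1-based inclusive.
#' @param step Grid spacing in bp (250 kb by default).
#' @param anchor `"start"` or `"end"`: which end of the window the grid is
#'   anchored at.
#' @return Numeric vector of `floor((end - start) / step) + 1` copy values
#'   (NA where the profile has a gap).
#' @export
sample_copy_grid <- function(profile, chrom, window, step = 250000, anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  check_profile(profile)
  stopifnot(length(unique(profile$sample)) == 1, length(window) == 2, window[1] <= window[2])
  segs <- profile[profile$chrom == chrom, , drop = FALSE]
  if (nrow(segs) == 0) abort(sprintf("chromosome %s absent from profile", chrom))
  if (window[1] > max(segs$end) || window[2] < min(segs$start)) {
    abort("window lies outside the profile extent")
  }
  pos <- if (anchor == "start") {
    seq(window[1], window[2], by = step)
  } else {
    rev(seq(window[2], window[1], by = -step))
  }
  copy_at(segs, pos)
}

#' Recenter a segment profile to a diploid baseline
#'
#' Automates diploid centering. Presumed-diploid regions are those at the
#' lowest substantial non-LOH copy level: copy values of non-LOH segments
#' are rounded to the nearest 0.1 and weighted by segment length, bins
#' carrying at least `min_frac` of the non-LOH genome are kept, adjacent
#' kept bins are merged into runs (one run per underlying copy state once
#' noise spreads a state over neighbouring bins), and the baseline is the
#' weighted peak of the lowest run. The whole profile is shifted so that
#' this baseline sits at 2.0. Taking the lowest level rather than the
#' modal one matters for hyperdiploid genomes, where gained chromosomes
#' can dominate the genome by length; LOH segments are excluded because
#' in shifted profiles the presumed haploid and triploid levels
#' obligately carry LOH. Idempotent on centered profiles.
#'
#' @param profile Segment profile (multi-sample allowed).
#' @param min_frac Minimum fraction of non-LOH length for a 0.1-copy bin
#'   to anchor the baseline (guards against small noisy dips).
#' @return The shifted profile, with per-sample offsets (amount added to
#'   `copy`) in attribute `"centering_offset"` and as column `offset` of
#'   attribute `"centering"`.
#' @export
recenter_profile <- function(profile, min_frac = 0.05) {
  check_profile(profile)
  shifted <- profile |>
    group_by(.data$sample) |>
    group_modify(function(df, key) {
      non_loh <- df[!df$loh, , drop = FALSE]
      if (nrow(non_loh) == 0) {
        abort(sprintf("sample %s: all segments are LOH; profile is uncenterable", key$sample))
      }
      lev <- round(non_loh$copy * 10) / 10
      w <- tapply(as.numeric(non_loh$end - non_loh$start + 1), lev, sum)
      levels <- as.numeric(names(w))
      keep <- w / sum(w) >= min_frac
      if (!any(keep)) keep <- rep(TRUE, length(w))
      lv <- levels[keep]; wv <- as.numeric(w[keep])
      ord <- order(lv); lv <- lv[ord]; wv <- wv[ord]
      run <- cumsum(c(TRUE, diff(lv) > 0.1 + 1e-9))
      low <- run == run[1]
      baseline <- min(lv[low][wv[low] == max(wv[low])])
      df$copy <- pmax(df$copy + (2 - baseline), 0)
      df$.offset <- 2 - baseline
      df
    }) |>
    ungroup()
  offsets <- shifted |> distinct(.data$sample, offset = .data$.offset)
  shifted <- shifted |> select(-".offset")
  attr(shifted, "centering") <- offsets
  attr(shifted, "centering_offset") <- setNames(offsets$offset, offsets$sample)
  shifted
}

# grid median over all autosomal arms, terminus-anchored (the "sample
# median copy value" used by the loss rule)
sample_median_copy <- function(profile, spec, step = 250000) {
  arms <- arm_table(spec)
  vals <- unlist(lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    if (!a$chrom %in% profile$chrom) return(numeric(0))
    sample_copy_grid(profile, a$chrom, c(a$start, a$end), step,
                     anchor = if (a$arm == "p") "start" else "end")
  }))
  median(vals, na.rm = TRUE)
}

arm_grid_median <- function(profile, spec, chrom, arm, step = 250000) {
  a <- arm_row(spec, chrom, arm)
  vals <- sample_copy_grid(profile, chrom, c(a$start, a$end), step,
                           anchor = if (arm == "p") "start" else "end")
  median(vals, na.rm = TRUE)
}

#' Call a segmental gain or loss on one chromosome arm
#'
#' Implements the terminal-window rule for segmental (arm-level) copy
#' alterations. The copy level is sampled every `step` bp over the
#' terminal `window_mb` of the arm (the whole arm when shorter;
#' `acro_window_mb` for acrocentric q arms). The arm is called
#' **gained** when the window median is at least 2.3 (2.0 = diploid) and
#' the opposing (control) arm's grid median is at least 0.3 copies below
#' the window median; **lost** when the window median is at least 0.3
#' below the sample's median copy value and the control arm median is at
#' least 0.3 above the window median. The control-arm requirement is what
#' excludes whole-chromosome gains and losses from the segmental calls.
#'
#' @param profile Single-sample, recentered segment profile.
#' @param chrom,arm Arm to query (`arm` is `"p"` or `"q"`).
#' @param spec Genome spec ([genome_spec()]).
#' @param step Grid spacing in bp.
#' @param window_mb Terminal window length in Mb (30 per the rule).
#' @param acro_window_mb Query window for acrocentric q arms, Mb
#'   (configurable 15-25; default 20).
#' @param gain_level Minimum window median for a gain (2.3).
#' @param margin Control-arm / sample-median separation (0.3).
#' @param sample_median Precomputed sample median copy (computed when NULL).
#' @return One-row tibble: `sample`, `chrom`, `arm`, `direction`
#'   (`"gain"`, `"loss"`, `"none"`), `window_median`, `control_median`,
#'   `sample_median`, `window_start`, `window_end`, `note`.
#' @export
call_arm_alteration <- function(profile, chrom, arm, spec, step = 250000,
                                window_mb = 30, acro_window_mb = 20,
                                gain_level = 2.3, margin = 0.3,
                                sample_median = NULL) {
  check_profile(profile)
  stopifnot(length(unique(profile$sample)) == 1)
  a <- arm_row(spec, chrom, arm)
  wmb <- if (a$acrocentric && arm == "q") acro_window_mb else window_mb
  wlen <- min(wmb * 1e6, a$arm_length)
  window <- if (arm == "p") c(a$start, a$start + wlen - 1) else c(a$end - wlen + 1, a$end)
  wvals <- sample_copy_grid(profile, chrom, window, step,
                            anchor = if (arm == "p") "start" else "end")
  wmed <- median(wvals, na.rm = TRUE)
  other <- if (arm == "p") "q" else "p"
  note <- NA_character_
  cmed <- tryCatch(arm_grid_median(profile, spec, chrom, other, step),
                   error = function(e) NA_real_)
  if (is.na(cmed)) note <- "no_control_arm_data"
  if (is.null(sample_median)) sample_median <- sample_median_copy(profile, spec, step)

  direction <- "none"
  if (!is.na(cmed) && !is.na(wmed)) {
    if (wmed >= gain_level && cmed <= wmed - margin) {
      direction <- "gain"
    } else if (wmed <= sample_median - margin && cmed >= wmed + margin) {
      direction <- "loss"
    }
  }
  tibble(
    sample = profile$sample[1], chrom = chrom, arm = arm, direction = direction,
    window_median = wmed, control_median = cmed, sample_median = sample_median,
    window_start = window[1], window_end = window[2], note = note
  )
}

#' Call the 11q13.3 gain
#'
#' The queried window is chromosome 11 from 68.5 to 69.5 Mb (GRCh37), the
#' minimally gained hotspot region. Because 11q13.3 gains frequently
#' extend into the p arm, the control region is not the opposing arm but
#' the terminal 30 Mb of 11q itself: a gain is called when the window
#' grid median is at least `gain_level` and the terminal-30 Mb control
#' median is at least `margin` below it.
#'
#' @inheritParams call_arm_alteration
#' @export
call_11q13_gain <- function(profile, spec, step = 250000,
                            gain_level = 2.3, margin = 0.3) {
  check_profile(profile)
  stopifnot(length(unique(profile$sample)) == 1)
  if (!"11" %in% profile$chrom) abort("chromosome 11 absent from profile")
  a <- arm_row(spec, "11", "q")
  window <- c(68.5e6, 69.5e6)
  wmed <- median(sample_copy_grid(profile, "11", window, step), na.rm = TRUE)
  ctrl_window <- c(a$end - 30e6 + 1, a$end)
  cmed <- median(sample_copy_grid(profile, "11", ctrl_window, step, anchor = "end"),
                 na.rm = TRUE)
  direction <- if (!is.na(wmed) && !is.na(cmed) &&
                   wmed >= gain_level && cmed <= wmed - margin) "gain" else "none"
  tibble(
    sample = profile$sample[1], chrom = "11", arm = "11q13.3", direction = direction,
    window_median = wmed, control_median = cmed, sample_median = NA_real_,
    window_start = window[1], window_end = window[2], note = NA_character_
  )
}

#' Count whole-chromosome gains and classify the 9+ WC class
#'
#' An arm is copy-gained when at least `arm_fraction` of its 250 kb grid
#' points lie at or above `gain_level` (2.25); a whole chromosome is
#' gained when both arms meet the criterion; a sample belongs to the 9+
#' whole-chromosome-gain class when at least nine chromosomes are gained.
#'
#' @param profile Segment profile (multi-sample allowed), recentered.
#' @param spec Genome spec.
#' @param step Grid spacing in bp.
#' @param gain_level Grid-point threshold (2.25).
#' @param arm_fraction Minimum fraction of grid points at or above
#'   `gain_level` (0.8).
#' @param min_chroms Whole chromosomes gained needed for the 9+ class (9).
#' @return Tibble with one row per sample: `sample`, `n_wc_gains`,
#'   `is_9plus`, and `gained_chroms` (list-column of chromosome names).
#' @export
classify_9plus_wc <- function(profile, spec, step = 250000, gain_level = 2.25,
                              arm_fraction = 0.8, min_chroms = 9) {
  check_profile(profile)
  arms <- arm_table(spec)
  profile |>
    group_by(.data$sample) |>
    group_modify(function(df, key) {
      arm_gained <- map_lgl(seq_len(nrow(arms)), function(i) {
        a <- arms[i, ]
        if (!a$chrom %in% df$chrom) return(FALSE)
        vals <- sample_copy_grid(df |> mutate(sample = key$sample),
                                 a$chrom, c(a$start, a$end), step,
                                 anchor = if (a$arm == "p") "start" else "end")
        mean(vals >= gain_level, na.rm = TRUE) >= arm_fraction
      })
      by_chrom <- tapply(arm_gained, arms$chrom, all)
      gained <- names(by_chrom)[by_chrom]
      tibble(n_wc_gains = length(gained), is_9plus = length(gained) >= min_chroms,
             gained_chroms = list(gained))
    }) |>
    ungroup()
}

#' Test a locus for focal amplification
#'
#' A locus is amplified when any overlapping segment exceeds a log2 fold
#' change over the diploid germline of `log2fc_threshold` — at the
#' default 2.0, an absolute copy number above 8.
#'
#' @param profile Segment profile (multi-sample allowed).
#' @param locus `c(chrom, start, end)` (chrom as character, positions bp).
#' @param log2fc_threshold Strict lower bound on `log2(copy / 2)`.
#' @return Tibble per sample: `amplified`, `max_copy` over the locus.
#' @export
focal_amplification <- function(profile, locus, log2fc_threshold = 2.0) {
  check_profile(profile)
  chrom <- as.character(locus[[1]])
  start <- as.numeric(locus[[2]]); end <- as.numeric(locus[[3]])
  profile |>
    group_by(.data$sample) |>
    group_modify(function(df, key) {
      ov <- df[df$chrom == chrom & df$start <= end & df$end >= start, , drop = FALSE]
      if (nrow(ov) == 0) abort(sprintf("sample %s: locus overlaps no segment", key$sample))
      mx <- max(ov$copy)
      tibble(amplified = log2(mx / 2) > log2fc_threshold, max_copy = mx)
    }) |>
    ungroup()
}

#' Call all segmental arm alterations for every sample
#'
#' Drives [call_arm_alteration()] over every autosomal arm (skipping the
#' p arms of acrocentric chromosomes, which carry no unique sequence) and
#' appends the [call_11q13_gain()] call when chromosome 11 spans the
#' hotspot window.
#'
#' @inheritParams call_arm_alteration
#' @param include_11q13 Add the 11q13.3 call when possible.
#' @return Tidy tibble of arm calls (one row per sample x arm).
#' @export
call_all_arms <- function(profile, spec, step = 250000, window_mb = 30,
                          acro_window_mb = 20, include_11q13 = TRUE) {
  check_profile(profile)
  arms <- arm_table(spec) |> filter(!(.data$acrocentric & .data$arm == "p"))
  profile |>
    group_by(.data$sample) |>
    group_modify(function(df, key) {
      prof <- df |> mutate(sample = key$sample)
      med <- sample_median_copy(prof, spec, step)
      calls <- map(seq_len(nrow(arms)), function(i) {
        a <- arms[i, ]
        if (!a$chrom %in% prof$chrom) return(NULL)
        call_arm_alteration(prof, a$chrom, a$arm, spec, step, window_mb,
                            acro_window_mb, sample_median = med)
      }) |> list_rbind()
      if (include_11q13 && "11" %in% spec$chrom && "11" %in% prof$chrom &&
          arm_row(spec, "11", "q")$end >= 69.5e6) {
        calls <- bind_rows(calls, call_11q13_gain(prof, spec, step))
      }
      calls |> select(-"sample")
    }) |>
    ungroup()
}

#' Annotate SNVs with the local copy number of their host segment
#'
#' Joins each SNV to the containing segment of its sample's profile and
#' adds `tumor_copies`, the segment copy level rounded to the nearest
#' integer — the copy-state input of the timing analysis.
#'
#' @param snvs SNV tibble with `sample`, `chrom`, `pos`.
#' @param profile Segment profile covering those samples.
#' @return `snvs` with `tumor_copies` (NA where no segment contains the
#'   position) and `vaf` (from `alt_reads`/`depth` when absent).
#' @export
annotate_snv_copy <- function(snvs, profile) {
  check_profile(profile)
  out <- snvs
  out$tumor_copies <- NA_real_
  for (s in unique(snvs$sample)) {
    prof <- profile[profile$sample == s, , drop = FALSE]
    idx_s <- which(snvs$sample == s)
    for (ch in unique(snvs$chrom[idx_s])) {
      idx <- idx_s[snvs$chrom[idx_s] == ch]
      segs <- prof[prof$chrom == ch, c("start", "end", "copy")]
      if (nrow(segs) == 0) next
      out$tumor_copies[idx] <- round(copy_at(segs, snvs$pos[idx]))
    }
  }
  if (!"vaf" %in% names(out) && all(c("alt_reads", "depth") %in% names(out))) {
    out$vaf <- out$alt_reads / out$depth
  }
  out
}
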