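#' Configuration for the synthetic tumor-cohort generator
#'
#' Bundles and validates every knob of [simulate_cohort()]. Defaults
#' describe a neuroblastoma-like whole-genome cohort: age groups A
#' (under 1.5 years), B (1.5-5) and C (over 5) with weights matching a
#' large diagnosis cohort; tumor purity uniform on 0.5-0.95 so that
#' roughly half the cohort passes the 70%-purity timing filter;
#' age-dependent alteration prevalences that reproduce the qualitative
#' landscape (MYCN amplification and hyperdiploidy young, ATRX and TERT
#' old, 17q gain common throughout); mutation burdens drawn per
#' signature; 80x read depth; and an equal pre-/post-gain molecular-time
#' split (`fraction_pre_gain = 0.5`).
#'
#' @param n_samples Number of tumors.
#' @param seed Global seed; per-sample substreams are derived from it so
#'   that changing `n_samples` never perturbs earlier samples.
#' @param purity_range Uniform purity range (fractions in (0, 1]).
#' @param age_weights Named weights for groups A/B/C.
#' @param event_prevalences Data frame `alteration`, `A`, `B`, `C`
#'   (per-group probabilities); see [default_prevalences()].
#' @param exposure_ranges Named list of `c(min, max)` SNV counts per
#'   signature.
#' @param signatures 96 x K signature matrix used to draw mutation
#'   contexts.
#' @param coverage_depth Sequencing depth (reads) per site.
#' @param fraction_pre_gain Fraction of 3-copy-region mutations arising
#'   before the gain.
#' @param noise_sd Gaussian noise sd on segment copy levels.
#' @param centering_offset_range Uniform range of the ploidy-centering
#'   shift applied to emitted profiles (tests recentering).
#' @param relapse_fraction Fraction of samples labelled relapse.
#' @export
cohort_config <- function(n_samples = 60, seed = 1,
                          purity_range = c(0.5, 0.95),
                          age_weights = c(A = 0.30, B = 0.47, C = 0.23),
                          event_prevalences = default_prevalences(),
                          exposure_ranges = list(
                            SBS18 = c(150, 700), SBS1 = c(40, 150),
                            SBS5 = c(80, 300), SBS3 = c(0, 200)),
                          signatures = example_signatures(),
                          coverage_depth = 80,
                          fraction_pre_gain = 0.5,
                          noise_sd = 0.05,
                          centering_offset_range = c(0, 0),
                          relapse_fraction = 0) {
  stopifnot(n_samples >= 1, coverage_depth >= 1,
            all(purity_range > 0), all(purity_range <= 1),
            fraction_pre_gain >= 0, fraction_pre_gain <= 1,
            setequal(names(age_weights), c("A", "B", "C")),
            all(unlist(event_prevalences[c("A", "B", "C")]) >= 0),
            all(unlist(event_prevalences[c("A", "B", "C")]) <= 1),
            all(names(exposure_ranges) %in% colnames(signatures)))
  structure(as.list(environment()), class = "cohort_config")
}

#' Default age-dependent alteration prevalences
#'
#' Stylised per-age-group probabilities for the recurrent alterations of
#' the simulated landscape. `class` is `"cna"` for events realised in
#' the copy profile, `"sv"` for the t(11;17) translocation and `"gene"`
#' for gene-level point alterations (no genomic placement).
#' @export
default_prevalences <- function() {
  tibble(
    alteration = c("MYCN_amp", "gain_17q", "gain_7q", "gain_2p", "gain_11q13.3",
                   "del_1p", "del_3p", "del_4p", "del_11q",
                   "t_11_17", "wc_9plus", "ATRX", "TERT", "ALK_F1174L"),
    class = c("cna", "cna", "cna", "cna", "cna",
              "cna", "cna", "cna", "cna",
              "sv", "cna", "gene", "gene", "gene"),
    A = c(0.35, 0.45, 0.15, 0.15, 0.08, 0.20, 0.12, 0.10, 0.10, 0.05, 0.50, 0.02, 0.05, 0.10),
    B = c(0.25, 0.55, 0.20, 0.15, 0.10, 0.25, 0.15, 0.12, 0.30, 0.08, 0.25, 0.10, 0.15, 0.10),
    C = c(0.05, 0.55, 0.20, 0.10, 0.10, 0.25, 0.15, 0.12, 0.40, 0.08, 0.15, 0.45, 0.30, 0.10)
  )
}

# deterministic per-sample substream seed, independent of cohort size
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 7919) %% 2147483647)
}

# map an alteration name to copy events on the genome (GRCh37 names)
alteration_events <- function(alteration, arm_span_mb = 40) {
  switch(alteration,
    MYCN_amp     = tibble(type = "focal_amp", chrom = "2", arm = NA,
                          start = 15.5e6, end = 16.5e6, copy = 30),
    gain_17q     = tibble(type = "arm_gain", chrom = "17", arm = "q",
                          start = NA, end = NA, copy = 3),
    gain_7q      = tibble(type = "arm_gain", chrom = "7", arm = "q",
                          start = NA, end = NA, copy = 3),
    gain_2p      = tibble(type = "arm_gain", chrom = "2", arm = "p",
                          start = NA, end = NA, copy = 3),
    gain_11q13.3 = tibble(type = "window_gain", chrom = "11", arm = NA,
                          start = 68.5e6, end = 69.5e6, copy = 4),
    del_1p       = tibble(type = "arm_loss", chrom = "1", arm = "p",
                          start = NA, end = NA, copy = 1),
    del_3p       = tibble(type = "arm_loss", chrom = "3", arm = "p",
                          start = NA, end = NA, copy = 1),
    del_4p       = tibble(type = "arm_loss", chrom = "4", arm = "p",
                          start = NA, end = NA, copy = 1),
    del_11q      = tibble(type = "arm_loss", chrom = "11", arm = "q",
                          start = NA, end = NA, copy = 1),
    NULL
  )
}

# expand arm/wc events to explicit windows and check for contradictions
realize_events <- function(spec, events, arm_span_mb = 40) {
  if (nrow(events) == 0) {
    return(events |> mutate(layer = integer(0)))
  }
  at <- arm_table(spec)
  rows <- map(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    if (e$type == "wc_gain") {
      ch <- spec[spec$chrom == e$chrom, ]
      stopifnot(nrow(ch) == 1)
      e$start <- 1; e$end <- ch$length; e$layer <- 1L
    } else if (e$type %in% c("arm_gain", "arm_loss")) {
      a <- arm_row(spec, e$chrom, e$arm)
      span <- min(arm_span_mb * 1e6, a$arm_length)
      if (e$arm == "p") { e$start <- a$start; e$end <- a$start + span - 1 }
      else { e$start <- a$end - span + 1; e$end <- a$end }
      e$layer <- 2L
    } else if (e$type %in% c("window_gain", "window_loss")) {
      e$layer <- 3L
    } else if (e$type == "focal_amp") {
      e$layer <- 4L
    } else abort(sprintf("unknown event type %s", e$type))
    a2 <- at[at$chrom == e$chrom, ]
    if (nrow(a2) == 0) abort(sprintf("event references unknown chromosome %s", e$chrom))
    if (e$start < 1 || e$end > max(a2$end)) abort("event window outside chromosome bounds")
    e
  }) |> list_rbind()
  # same-layer overlaps with conflicting copy are contradictory
  for (ch in unique(rows$chrom)) {
    sub <- rows |> filter(.data$chrom == ch)
    if (nrow(sub) > 1) {
      for (i in seq_len(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
        if (sub$layer[i] == sub$layer[j] &&
            sub$start[i] <= sub$end[j] && sub$end[i] >= sub$start[j] &&
            sub$copy[i] != sub$copy[j]) {
          abort(sprintf("overlapping contradictory events on chromosome %s", ch))
        }
      }
    }
  }
  rows
}

#' Simulate one tumor's copy-number segment profile
#'
#' Tiles every chromosome of the genome spec with segments, injects the
#' requested copy events (whole-chromosome gains, terminal arm gains and
#' losses, window gains, focal amplifications; higher-specificity events
#' override broader ones), adds per-segment Gaussian noise and a global
#' centering offset, and flags LOH on regions whose true copy number is
#' below 2. The noise-free integer truth and the event boundary table
#' (for SV simulation) are attached as attributes.
#'
#' @param spec Genome spec.
#' @param events Tibble of events: `type` (`wc_gain`, `arm_gain`,
#'   `arm_loss`, `window_gain`, `window_loss`, `focal_amp`), `chrom`,
#'   `arm`, `start`, `end`, `copy`; `alteration` (a name) optional.
#' @param centering_offset Copy units added to every segment.
#' @param noise_sd Gaussian noise sd per segment.
#' @param sample_id Sample name.
#' @param arm_span_mb Extent of injected arm events (terminal Mb).
#' @param seed Optional seed for reproducible noise.
#' @return Observed segment profile tibble; attributes `truth`
#'   (noise-free profile with `true_copy`) and `event_boundaries`
#'   (tibble `alteration`, `chrom`, `pos`, `side`).
#' @export
simulate_copy_profile <- function(spec, events = NULL, centering_offset = 0,
                                  noise_sd = 0.05, sample_id = "S1",
                                  arm_span_mb = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(events)) {
    events <- tibble(type = character(0), chrom = character(0), arm = character(0),
                     start = numeric(0), end = numeric(0), copy = numeric(0))
  }
  if (!"alteration" %in% names(events)) {
    events$alteration <- if (nrow(events)) paste0("event", seq_len(nrow(events))) else character(0)
  }
  ev <- realize_events(spec, events, arm_span_mb)
  segs <- map(seq_len(nrow(spec)), function(i) {
    ch <- spec[i, ]
    chev <- ev |> filter(.data$chrom == ch$chrom) |> arrange(.data$layer)
    bp <- sort(unique(c(1, ch$length + 1, chev$start, chev$end + 1)))
    bp <- bp[bp >= 1 & bp <= ch$length + 1]
    starts <- bp[-length(bp)]; ends <- bp[-1] - 1
    copy <- rep(2, length(starts))
    if (nrow(chev) > 0) {
      for (k in seq_len(nrow(chev))) {  # ascending layer: later overrides
        cover <- starts >= chev$start[k] & ends <= chev$end[k]
        copy[cover] <- chev$copy[k]
      }
    }
    tibble(sample = sample_id, chrom = ch$chrom, start = starts, end = ends,
           true_copy = copy)
  }) |> list_rbind()
  observed <- segs |>
    mutate(copy = pmax(.data$true_copy + rnorm(n(), 0, noise_sd) + centering_offset, 0),
           loh = .data$true_copy < 2) |>
    select("sample", "chrom", "start", "end", "copy", "loh")
  truth <- segs |> mutate(loh = .data$true_copy < 2)
  boundaries <- ev |>
    filter(.data$type != "wc_gain") |>
    (\(d) bind_rows(
      d |> select("alteration", "chrom", pos = "start") |> mutate(side = "start"),
      d |> select("alteration", "chrom", pos = "end") |> mutate(side = "end")
    ))() |>
    mutate(sample = sample_id, class = "cna")
  attr(observed, "truth") <- truth
  attr(observed, "event_boundaries") <- boundaries
  observed
}

#' Simulate somatic SNVs with signature-driven contexts and VAFs
#'
#' Draws each SNV's trinucleotide class from its generating signature's
#' spectrum, places it uniformly on the genome, assigns allele
#' multiplicity (in 3-copy regions a pre-gain mutation lies on the
#' duplicated chromosome with probability 1/2, hence multiplicity 2;
#' post-gain mutations always have multiplicity 1), and samples read
#' counts binomially around the purity-adjusted expected VAF.
#'
#' @param exposures Named non-negative integer vector: SNVs per signature.
#' @param signatures 96 x K signature matrix covering those names.
#' @param truth_profile Noise-free profile (attribute `truth` of
#'   [simulate_copy_profile()]) with `true_copy`.
#' @param purity Tumor purity in (0, 1].
#' @param fraction_pre_gain Probability a 3-copy-region mutation predates
#'   the gain.
#' @param depth Read depth per site.
#' @param sample_id Sample name.
#' @param seed Optional seed.
#' @return Observed SNV tibble (`sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `context96`, `alt_reads`, `depth`); attribute `truth` adds the true
#'   signature, local copies, multiplicity, pre-gain flag and expected
#'   VAF per SNV.
#' @export
simulate_snvs <- function(exposures, signatures, truth_profile, purity,
                          fraction_pre_gain = 0.5, depth = 80,
                          sample_id = "S1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- as_signature_matrix(signatures)
  stopifnot(all(names(exposures) %in% colnames(m)), all(exposures >= 0),
            purity > 0, purity <= 1, depth >= 1)
  exposures <- exposures[exposures > 0]
  n <- sum(exposures)
  if (n == 0) {
    out <- tibble(sample = character(0), chrom = character(0), pos = numeric(0),
                  ref = character(0), alt = character(0), context96 = character(0),
                  alt_reads = integer(0), depth = integer(0))
    attr(out, "truth") <- out
    return(out)
  }
  sig_of <- rep(names(exposures), times = exposures)
  classes <- sbs96_classes()
  class_of <- unlist(lapply(names(exposures), function(k) {
    sample(classes, exposures[[k]], replace = TRUE, prob = m[, k])
  }))
  chrom_len <- truth_profile |> group_by(.data$chrom) |>
    summarise(len = max(.data$end), .groups = "drop")
  chrom <- sample(chrom_len$chrom, n, replace = TRUE,
                  prob = chrom_len$len / sum(chrom_len$len))
  pos <- floor(runif(n, 1, chrom_len$len[match(chrom, chrom_len$chrom)] + 1))
  tcopy <- numeric(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    segs <- truth_profile[truth_profile$chrom == ch, c("start", "end", "true_copy")] |>
      rename(copy = "true_copy")
    tcopy[idx] <- copy_at(segs, pos[idx])
  }
  tcopy <- round(tcopy)
  pre_gain <- tcopy == 3 & runif(n) < fraction_pre_gain
  mult <- rep(1L, n)
  mult[pre_gain] <- 1L + rbinom(sum(pre_gain), 1, 0.5)
  tt <- pmax(tcopy, 1)
  evaf <- expected_vaf(purity, tt, pmin(mult, tt))
  alt_reads <- rbinom(n, depth, evaf)
  out <- tibble(
    sample = sample_id, chrom = chrom, pos = pos,
    ref = substr(class_of, 3, 3), alt = substr(class_of, 5, 5),
    context96 = class_of, alt_reads = alt_reads, depth = as.integer(depth)
  )
  attr(out, "truth") <- out |>
    mutate(signature = sig_of, tumor_copies = tcopy, multiplicity = mult,
           pre_gain = pre_gain, expected_vaf = evaf, purity = purity)
  out
}

#' Simulate structural variants that link (or fail to link) alterations
#'
#' Emits SV records from a plan of three move types: `direct` joins two
#' alteration boundaries with a single SV (breakpoints jittered within
#' the matching window), `chain` joins them through an intervening
#' chromosome with `n_hops` hops whose same-chromosome gaps equal
#' `hop_spacing` (spacing above 15 Mb breaks the chain), and `hotspot`
#' emits a t(11;17)-range translocation (17q at/above 30 Mb to 11q
#' 60-80 Mb), anchored to boundaries when `alt_a`/`alt_b` are given.
#'
#' @param boundaries Boundary tibble (`alteration`, `chrom`, `pos`,
#'   `side`) as produced by [simulate_copy_profile()].
#' @param plan Tibble: `type` (`direct`/`chain`/`hotspot`), `alt_a`,
#'   `side_a`, `alt_b`, `side_b`, `n_hops`, `hop_chrom`, `hop_spacing`.
#' @param jitter Max absolute breakpoint offset from the boundary, bp.
#' @param sample_id Sample name.
#' @param seed Optional seed.
#' @return SV tibble: `sample`, `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `type`, `plan_row`.
#' @export
simulate_svs <- function(boundaries, plan, jitter = 2000, sample_id = "S1",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bpos <- function(alt, side) {
    row <- boundaries[boundaries$alteration == alt & boundaries$side == side, ]
    if (nrow(row) != 1) abort(sprintf("plan references unknown boundary %s/%s", alt, side))
    list(chrom = row$chrom, pos = row$pos)
  }
  jit <- function(p) pmax(1, round(p + runif(1, -jitter, jitter)))
  map(seq_len(nrow(plan)), function(i) {
    pl <- plan[i, ]
    if (pl$type == "direct") {
      a <- bpos(pl$alt_a, pl$side_a); b <- bpos(pl$alt_b, pl$side_b)
      tibble(chrom_a = a$chrom, pos_a = jit(a$pos), chrom_b = b$chrom, pos_b = jit(b$pos),
             type = if (a$chrom == b$chrom) "other" else "translocation", plan_row = i)
    } else if (pl$type == "chain") {
      a <- bpos(pl$alt_a, pl$side_a); b <- bpos(pl$alt_b, pl$side_b)
      stopifnot(pl$n_hops >= 1, !is.na(pl$hop_chrom), !is.na(pl$hop_spacing))
      land <- 10e6
      svs <- list(tibble(chrom_a = a$chrom, pos_a = jit(a$pos),
                         chrom_b = pl$hop_chrom, pos_b = land,
                         type = "translocation", plan_row = i))
      if (pl$n_hops > 1) {
        for (k in seq_len(pl$n_hops - 1)) {
          nxt <- land + pl$hop_spacing + 25e6
          svs <- c(svs, list(tibble(chrom_a = pl$hop_chrom, pos_a = land + pl$hop_spacing,
                                    chrom_b = pl$hop_chrom, pos_b = nxt,
                                    type = "other", plan_row = i)))
          land <- nxt
        }
      }
      svs <- c(svs, list(tibble(chrom_a = pl$hop_chrom, pos_a = land + pl$hop_spacing,
                                chrom_b = b$chrom, pos_b = jit(b$pos),
                                type = "translocation", plan_row = i)))
      list_rbind(svs)
    } else if (pl$type == "hotspot") {
      if (!is.na(pl$alt_a) && !is.na(pl$alt_b)) {
        a <- bpos(pl$alt_a, pl$side_a); b <- bpos(pl$alt_b, pl$side_b)
        tibble(chrom_a = a$chrom, pos_a = jit(a$pos), chrom_b = b$chrom, pos_b = jit(b$pos),
               type = "translocation", plan_row = i)
      } else {
        tibble(chrom_a = "17", pos_a = 45e6, chrom_b = "11", pos_b = 70e6,
               type = "translocation", plan_row = i)
      }
    } else abort(sprintf("unknown plan type %s", pl$type))
  }) |> list_rbind() |> mutate(sample = sample_id, .before = 1)
}

#' Simulate a full tumor cohort with ground truth
#'
#' Draws, per sample: an age group and age, purity, alteration statuses
#' from the configured age-dependent prevalences, a copy profile
#' realising the copy-class alterations (plus 9+ whole-chromosome gains
#' when drawn), signature exposures and the corresponding SNV catalog,
#' and SVs — including a hotspot t(11;17) that directly joins the ends
#' of co-occurring 11q13.3 and 17q gains, making the three events
#' non-independent, as rearrangement-coupled alterations are in real
#' tumors. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `sim_cohort` list: `profiles`, `snvs`, `svs`, `metadata`,
#'   `alterations` (long truth statuses), `boundaries`, and `truth`
#'   (per-sample event, exposure and per-SNV truth tables).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  spec <- genome_spec("grch37-arms")
  prev <- config$event_prevalences
  groups <- c("A", "B", "C")
  res <- map(seq_len(config$n_samples), function(i) {
    set.seed(substream_seed(config$seed, i))
    sid <- sprintf("S%03d", i)
    grp <- sample(groups, 1, prob = config$age_weights[groups])
    age <- switch(grp, A = runif(1, 0, 1.5), B = runif(1, 1.5, 5), C = runif(1, 5, 12))
    purity <- runif(1, config$purity_range[1], config$purity_range[2])
    status <- setNames(runif(nrow(prev)) < prev[[grp]], prev$alteration)

    events <- map(prev$alteration[status & prev$class == "cna" &
                                    prev$alteration != "wc_9plus"],
                  function(a) alteration_events(a) |> mutate(alteration = a)) |>
      list_rbind()
    if (is.null(events) || nrow(events) == 0) {
      events <- tibble(type = character(0), chrom = character(0), arm = character(0),
                       start = numeric(0), end = numeric(0), copy = numeric(0),
                       alteration = character(0))
    }
    if (isTRUE(unname(status["wc_9plus"]))) {
      used <- unique(events$chrom)
      free <- setdiff(spec$chrom, used)
      k <- min(sample(9:11, 1), length(free))
      wc <- sample(free, k)
      events <- bind_rows(events,
                          tibble(type = "wc_gain", chrom = wc, arm = NA,
                                 start = NA, end = NA, copy = 3,
                                 alteration = paste0("wc_", wc)))
    }
    offset <- runif(1, config$centering_offset_range[1], config$centering_offset_range[2])
    profile <- simulate_copy_profile(spec, events, centering_offset = offset,
                                     noise_sd = config$noise_sd, sample_id = sid)
    truth_prof <- attr(profile, "truth")
    boundaries <- attr(profile, "event_boundaries")

    exposures <- map_int(config$exposure_ranges, function(r) {
      as.integer(round(runif(1, r[1], r[2])))
    })
    snvs <- simulate_snvs(exposures, config$signatures, truth_prof, purity,
                          config$fraction_pre_gain, config$coverage_depth,
                          sample_id = sid)
    snv_truth <- attr(snvs, "truth")

    plan <- NULL
    if (isTRUE(unname(status["t_11_17"]))) {
      plan <- if (isTRUE(unname(status["gain_11q13.3"])) &&
                  isTRUE(unname(status["gain_17q"]))) {
        tibble(type = "hotspot", alt_a = "gain_17q", side_a = "start",
               alt_b = "gain_11q13.3", side_b = "end",
               n_hops = NA, hop_chrom = NA, hop_spacing = NA)
      } else {
        tibble(type = "hotspot", alt_a = NA, side_a = NA, alt_b = NA, side_b = NA,
               n_hops = NA, hop_chrom = NA, hop_spacing = NA)
      }
    }
    svs <- if (!is.null(plan)) {
      simulate_svs(boundaries, plan, sample_id = sid)
    } else {
      tibble(sample = character(0), chrom_a = character(0), pos_a = numeric(0),
             chrom_b = character(0), pos_b = numeric(0), type = character(0),
             plan_row = integer(0))
    }

    burden <- stats::rpois(1, max(1, sum(exposures) * 0.01))
    list(
      profile = profile, truth_profile = truth_prof, boundaries = boundaries,
      snvs = snvs, snv_truth = snv_truth, svs = svs,
      events = events |> mutate(sample = sid),
      metadata = tibble(
        sample = sid, age_years = age, age_group = grp,
        stage = sample(c(4L, 3L, 2L, 1L), 1, prob = c(0.5, 0.2, 0.15, 0.15)),
        timepoint = if (runif(1) < config$relapse_fraction) "relapse" else "diagnosis",
        purity = purity, centering_offset = offset,
        n_coding_snvs = burden, n_snvs = sum(exposures)),
      exposures = tibble(sample = sid, signature = names(exposures),
                         exposure = as.numeric(exposures)),
      alterations = tibble(sample = sid, alteration = prev$alteration,
                           class = prev$class, altered = unname(status))
    )
  })
  structure(list(
    genome = spec,
    profiles = map(res, "profile") |> list_rbind(),
    truth_profiles = map(res, "truth_profile") |> list_rbind(),
    snvs = map(res, "snvs") |> list_rbind(),
    svs = map(res, "svs") |> list_rbind(),
    metadata = map(res, "metadata") |> list_rbind(),
    alterations = map(res, "alterations") |> list_rbind(),
    boundaries = map(res, "boundaries") |> list_rbind(),
    truth = list(
      events = map(res, "events") |> list_rbind(),
      exposures = map(res, "exposures") |> list_rbind(),
      snvs = map(res, "snv_truth") |> list_rbind()),
    config = config
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", nrow(x$metadata), "samples,",
      nrow(x$snvs), "SNVs,", nrow(x$svs), "SVs\n")
  invisible(x)
}
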