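spec37 <- genome_spec("grch37-arms")
sigs <- example_signatures()

test_that("cohorts are deterministic and substream-stable", {
  c1 <- simulate_cohort(cohort_config(n_samples = 6, seed = 7))
  c2 <- simulate_cohort(cohort_config(n_samples = 6, seed = 7))
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$snvs, c2$snvs)
  expect_identical(c1$svs, c2$svs)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$truth, c2$truth)
  # growing the cohort never perturbs earlier samples
  c3 <- simulate_cohort(cohort_config(n_samples = 8, seed = 7))
  expect_identical(c3$snvs |> dplyr::filter(sample %in% c1$metadata$sample), c1$snvs)
})

test_that("event-free profiles are flat diploid; injected events are callable", {
  flat <- simulate_copy_profile(spec37, NULL, noise_sd = 0.03)
  expect_true(all(abs(flat$copy - 2) < 0.2))
  expect_true(all(!flat$loh))
  # coverage tiles every chromosome without gaps or overlaps
  tiles <- flat |> dplyr::group_by(chrom) |>
    dplyr::summarise(ok = all(start[-1] == head(end, -1) + 1), len = max(end))
  expect_true(all(tiles$ok))
  expect_equal(tiles$len[match(spec37$chrom, tiles$chrom)], spec37$length)

  ev <- tibble::tibble(type = "arm_gain", chrom = "17", arm = "q",
                       start = NA, end = NA, copy = 3)
  prof <- simulate_copy_profile(spec37, ev, noise_sd = 0.05, seed = 2)
  calls <- call_all_arms(recenter_profile(prof), spec37) |>
    dplyr::filter(direction != "none")
  expect_equal(paste0(calls$chrom, calls$arm), "17q")

  # applied centering offset is recovered by the recentering step
  shifted <- simulate_copy_profile(spec37, NULL, centering_offset = 0.7,
                                   noise_sd = 0.02, seed = 3)
  expect_equal(unname(attr(recenter_profile(shifted), "centering_offset")), -0.7)
})

test_that("nine injected whole-chromosome gains classify as 9+ WC", {
  ev <- tibble::tibble(type = "wc_gain", chrom = as.character(1:9), arm = NA,
                       start = NA, end = NA, copy = 3)
  prof <- simulate_copy_profile(spec37, ev, noise_sd = 0.05, seed = 4)
  pc <- classify_9plus_wc(recenter_profile(prof), spec37)
  expect_true(pc$is_9plus)
  expect_equal(pc$n_wc_gains, 9)
})

test_that("contradictory overlapping events are rejected", {
  ev <- tibble::tibble(type = c("arm_gain", "arm_loss"), chrom = "17",
                       arm = "q", start = NA, end = NA, copy = c(3, 1))
  expect_error(simulate_copy_profile(spec37, ev), "contradictory")
})

test_that("simulated spectra follow the exposure-weighted signature mixture", {
  truth_prof <- attr(simulate_copy_profile(spec37, NULL, noise_sd = 0), "truth")
  expos <- c(SBS18 = 1500, SBS1 = 500, SBS5 = 500)
  snvs <- simulate_snvs(expos, sigs, truth_prof, purity = 1, depth = 80, seed = 9)
  counts <- spectrum_matrix(build_spectrum(snvs))[1, ]
  probs <- as.vector(sigs[, names(expos)] %*% (expos / sum(expos)))
  gof <- suppressWarnings(stats::chisq.test(counts, p = probs))
  expect_gt(gof$p.value, 0.001)
  # pure-signature cosine check
  pure <- simulate_snvs(c(SBS18 = 500), sigs, truth_prof, purity = 1, seed = 10)
  v <- spectrum_matrix(build_spectrum(pure))[1, ]
  expect_gte(sum(v * sigs[, "SBS18"]) / sqrt(sum(v^2) * sum(sigs[, "SBS18"]^2)), 0.95)
  expect_error(simulate_snvs(c(NOPE = 10), sigs, truth_prof, purity = 1), "names")
})

test_that("VAFs follow the purity/copy/multiplicity model per stratum", {
  ev <- tibble::tibble(type = "wc_gain", chrom = as.character(1:8), arm = NA,
                       start = NA, end = NA, copy = 3)
  truth_prof <- attr(simulate_copy_profile(spec37, ev, noise_sd = 0), "truth")
  purity <- 0.8
  snvs <- simulate_snvs(c(SBS18 = 3000), sigs, truth_prof, purity = purity,
                        fraction_pre_gain = 0.5, depth = 100, seed = 12)
  tr <- attr(snvs, "truth")
  strata <- tr |>
    dplyr::group_by(tumor_copies, multiplicity) |>
    dplyr::summarise(mean_vaf = mean(alt_reads / depth), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(n >= 30)
  expect_gte(nrow(strata), 2)
  for (i in seq_len(nrow(strata))) {
    ev_vaf <- expected_vaf(purity, strata$tumor_copies[i], strata$multiplicity[i])
    se <- sqrt(ev_vaf * (1 - ev_vaf) / (100 * strata$n[i]))
    expect_lt(abs(strata$mean_vaf[i] - ev_vaf), 3 * se + 0.003)
  }
})

test_that("pre-gain mutations split 50/50 across duplicated alleles", {
  ev <- tibble::tibble(type = "wc_gain", chrom = as.character(1:10), arm = NA,
                       start = NA, end = NA, copy = 3)
  truth_prof <- attr(simulate_copy_profile(spec37, ev, noise_sd = 0), "truth")
  all_pre <- attr(simulate_snvs(c(SBS18 = 2000), sigs, truth_prof, purity = 1,
                                fraction_pre_gain = 1, seed = 13), "truth") |>
    dplyr::filter(tumor_copies == 3)
  f1 <- mean(all_pre$multiplicity == 1)
  se <- sqrt(0.25 / nrow(all_pre))
  expect_lt(abs(f1 - 0.5), 3 * se)
  all_post <- attr(simulate_snvs(c(SBS18 = 500), sigs, truth_prof, purity = 1,
                                 fraction_pre_gain = 0, seed = 14), "truth")
  expect_true(all(all_post$multiplicity == 1))
})

test_that("truth tables account for every emitted record exactly once", {
  coh <- simulate_cohort(cohort_config(n_samples = 5, seed = 3))
  key <- function(d) paste(d$sample, d$chrom, d$pos)
  expect_identical(sort(key(coh$snvs)), sort(key(coh$truth$snvs)))
  expect_equal(nrow(coh$snvs), nrow(coh$truth$snvs))
  # exposures in truth match emitted SNV counts per sample
  per <- coh$snvs |> dplyr::count(sample)
  tru <- coh$truth$exposures |> dplyr::group_by(sample) |>
    dplyr::summarise(n = sum(exposure))
  expect_equal(per$n[match(tru$sample, per$sample)], as.integer(tru$n))
  # per-SNV signatures aggregate back to the exposure totals
  by_sig <- coh$truth$snvs |> dplyr::count(sample, signature)
  j <- dplyr::inner_join(coh$truth$exposures, by_sig, by = c("sample", "signature"))
  expect_equal(j$exposure, as.numeric(j$n))
})

test_that("a fixed-purity cohort passes the timing purity filter throughout", {
  coh <- simulate_cohort(cohort_config(n_samples = 6, seed = 21,
                                       purity_range = c(0.7, 0.7)))
  expect_true(all(coh$metadata$purity == 0.7))
  expect_true(all(coh$metadata$purity >= 0.70))
})

test_that("simulated SV plans drive the independence filter as designed", {
  ev <- tibble::tibble(
    type = c("arm_gain", "window_gain"), chrom = c("17", "11"),
    arm = c("q", NA), start = c(NA, 68.5e6), end = c(NA, 69.5e6), copy = c(3, 4),
    alteration = c("gain_17q", "gain_11q13.3"))
  prof <- simulate_copy_profile(spec37, ev, noise_sd = 0.03, seed = 6)
  b <- attr(prof, "event_boundaries")
  direct <- simulate_svs(b, tibble::tibble(
    type = "direct", alt_a = "gain_17q", side_a = "start",
    alt_b = "gain_11q13.3", side_b = "end",
    n_hops = NA, hop_chrom = NA, hop_spacing = NA), seed = 1)
  g <- build_linkage_graph(direct, b)
  expect_equal(independent_pair_filter(g, "gain_17q", "gain_11q13.3"), "linked")
  far <- simulate_svs(b, tibble::tibble(
    type = "chain", alt_a = "gain_17q", side_a = "start",
    alt_b = "gain_11q13.3", side_b = "end",
    n_hops = 1, hop_chrom = "5", hop_spacing = 20e6), seed = 1)
  g2 <- build_linkage_graph(far, b)
  expect_equal(independent_pair_filter(g2, "gain_17q", "gain_11q13.3"), "independent")
  hot <- simulate_svs(b, tibble::tibble(
    type = "hotspot", alt_a = "gain_17q", side_a = "start",
    alt_b = "gain_11q13.3", side_b = "end",
    n_hops = NA, hop_chrom = NA, hop_spacing = NA), seed = 1)
  expect_true(all(classify_t11_17(hot)))
})

test_that("cohorts write to standard text formats and read back", {
  coh <- simulate_cohort(cohort_config(n_samples = 3, seed = 5))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("segments.tsv", "snvs.tsv", "svs.tsv",
                                               "metadata.tsv", "truth.json")))))
  seg <- read_segments(file.path(dir, "segments.tsv"))
  expect_equal(nrow(seg), nrow(coh$profiles))
  expect_equal(read_snvs(file.path(dir, "snvs.tsv"))$pos, coh$snvs$pos)
})

test_that("segment loader converts BED-style input and fills coverage gaps", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample = "S1", chrom = c("1", "1"), start = c(0, 60e6), end = c(50e6, 100e6),
    copy = c(2, 3), loh = FALSE), path)
  seg <- read_segments(path, zero_based = TRUE)
  expect_equal(seg$start[1], 1)
  gap <- seg |> dplyr::filter(start == 50e6 + 1)
  expect_equal(nrow(gap), 1)
  expect_equal(gap$end, 60e6)
  expect_equal(gap$copy, 2.5)  # sample median filler
})
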