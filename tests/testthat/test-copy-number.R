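seg <- function(chrom, start, end, copy, loh = FALSE, sample = "S1") {
  tibble::tibble(sample = sample, chrom = chrom, start = start, end = end,
                 copy = copy, loh = loh)
}

test_that("recentering shifts the modal non-LOH level to diploid and is idempotent", {
  spec <- genome_spec("toy")
  prof <- uniform_profile(spec, copy = 2.7)
  out <- recenter_profile(prof)
  expect_equal(unname(attr(out, "centering_offset")), -0.7)
  expect_equal(out$copy, rep(2, nrow(out)))
  again <- recenter_profile(out)
  expect_equal(unname(attr(again, "centering_offset")), 0)
  expect_equal(again$copy, out$copy)
})

test_that("LOH regions are excluded from the centering baseline", {
  # shifted triploid tumor: bulk at 3.0 (non-LOH), haploid LOH regions at 1.0
  prof <- dplyr::bind_rows(
    seg("t1", 1, 120e6, 3.0),
    seg("t1", 120e6 + 1, 140e6, 1.0, loh = TRUE),
    seg("t2", 1, 60e6, 3.0))
  out <- recenter_profile(prof)
  expect_equal(unname(attr(out, "centering_offset")), -1)
  expect_equal(out$copy[out$loh], 0)   # haploid LOH level follows the shift
  expect_equal(unique(out$copy[!out$loh]), 2)
})

test_that("fully-LOH profiles are refused as uncenterable", {
  prof <- seg("t1", 1, 1e6, 1.4, loh = TRUE)
  expect_error(recenter_profile(prof), "uncenterable")
})

test_that("the copy grid samples the containing segment at 250 kb steps", {
  prof <- dplyr::bind_rows(seg("t1", 1, 50e6, 2.0), seg("t1", 50e6 + 1, 140e6, 3.0))
  vals <- sample_copy_grid(prof, "t1", c(10e6, 40e6))
  expect_length(vals, floor(30e6 / 250e3) + 1)
  expect_length(sample_copy_grid(prof, "t1", c(10e6, 40e6), anchor = "end"), 121)
  expect_equal(unique(sample_copy_grid(prof, "t1", c(60e6, 80e6))), 3.0)
  strad <- sample_copy_grid(prof, "t1", c(45e6, 55e6))
  expect_setequal(unique(strad), c(2.0, 3.0))
  expect_error(sample_copy_grid(prof, "t1", c(200e6, 210e6)), "outside")
})

test_that("segmental arm calls follow the window/control/sample-median rules", {
  spec <- genome_spec("toy")
  # t1: p 60 Mb, q 80 Mb
  gain <- dplyr::bind_rows(
    seg("t1", 1, 100e6, 2.0), seg("t1", 100e6 + 1, 140e6, 3.0),
    seg("t2", 1, 60e6, 2.0), seg("t3", 1, 70e6, 2.0), seg("t4", 1, 58e6, 2.0))
  call <- call_arm_alteration(gain, "t1", "q", spec)
  expect_equal(call$direction, "gain")
  expect_equal(call$window_median, 3.0)
  expect_equal(call$control_median, 2.0)

  # whole-chromosome gain is excluded by the control-arm criterion
  wc <- dplyr::bind_rows(
    seg("t1", 1, 140e6, 3.0),
    seg("t2", 1, 60e6, 2.0), seg("t3", 1, 70e6, 2.0), seg("t4", 1, 58e6, 2.0))
  expect_equal(call_arm_alteration(wc, "t1", "q", spec)$direction, "none")

  loss <- dplyr::bind_rows(
    seg("t1", 1, 100e6, 2.0), seg("t1", 100e6 + 1, 140e6, 1.6, loh = TRUE),
    seg("t2", 1, 60e6, 2.0), seg("t3", 1, 70e6, 2.0), seg("t4", 1, 58e6, 2.0))
  lc <- call_arm_alteration(loss, "t1", "q", spec)
  expect_equal(lc$direction, "loss")   # 1.6 <= 2.0 - 0.3 and control 2.0 >= 1.9
})

test_that("short and acrocentric arms use reduced query windows", {
  spec <- genome_spec("toy")
  prof <- uniform_profile(spec)
  # t2 q arm is 20 Mb (< 30 Mb): window is the whole arm
  c2 <- call_arm_alteration(prof |> dplyr::filter(chrom == "t2"), "t2", "q", spec,
                            sample_median = 2)
  expect_equal(c2$window_end - c2$window_start + 1, 20e6)
  # acrocentric q arm queries 20 Mb by default, configurable
  c4 <- call_arm_alteration(prof |> dplyr::filter(chrom == "t4"), "t4", "q", spec,
                            sample_median = 2)
  expect_equal(c4$window_end - c4$window_start + 1, 20e6)
  c4b <- call_arm_alteration(prof |> dplyr::filter(chrom == "t4"), "t4", "q", spec,
                             acro_window_mb = 15, sample_median = 2)
  expect_equal(c4b$window_end - c4b$window_start + 1, 15e6)
})

test_that("the 11q13.3 hotspot call uses the distal-11q control", {
  spec <- genome_spec("grch37-arms")
  len11 <- spec$length[spec$chrom == "11"]
  flat <- seg("11", 1, len11, 2.0)
  expect_equal(call_11q13_gain(flat, spec)$direction, "none")

  focal <- dplyr::bind_rows(
    seg("11", 1, 68e6, 2.0), seg("11", 68e6 + 1, 70e6, 4.0),
    seg("11", 70e6 + 1, len11, 2.0))
  fc <- call_11q13_gain(focal, spec)
  expect_equal(fc$direction, "gain")
  expect_equal(fc$window_median, 4.0)

  # gain extending through the 11q terminus leaves no control contrast
  whole_q <- dplyr::bind_rows(seg("11", 1, 54e6, 2.0), seg("11", 54e6 + 1, len11, 3.0))
  expect_equal(call_11q13_gain(whole_q, spec)$direction, "none")
})

test_that("whole-chromosome gain counting enforces the both-arms 80% rule", {
  spec <- genome_spec("grch37-arms")
  prof9 <- uniform_profile(spec)
  gained <- as.character(1:9)
  prof9$copy[prof9$chrom %in% gained] <- 3.0
  pc <- classify_9plus_wc(prof9, spec)
  expect_true(pc$is_9plus)
  expect_equal(pc$n_wc_gains, 9)
  expect_setequal(pc$gained_chroms[[1]], gained)

  prof8 <- uniform_profile(spec)
  prof8$copy[prof8$chrom %in% as.character(1:8)] <- 3.0
  expect_false(classify_9plus_wc(prof8, spec)$is_9plus)

  # q-arm-only gain is not a whole-chromosome gain
  qonly <- dplyr::bind_rows(
    seg("1", 1, 125e6, 2.0), seg("1", 125e6 + 1, 249250621, 3.0),
    uniform_profile(spec[-1, ], sample_id = "S1"))
  expect_equal(classify_9plus_wc(qonly, spec)$n_wc_gains, 0)
})

test_that("focal amplification uses a strict log2 fold-change threshold", {
  prof <- dplyr::bind_rows(seg("2", 1, 15e6, 2.0), seg("2", 15e6 + 1, 16e6, 30),
                           seg("2", 16e6 + 1, 240e6, 2.0))
  amp <- focal_amplification(prof, list("2", 15.5e6, 16.5e6))
  expect_true(amp$amplified)
  expect_equal(amp$max_copy, 30)
  at8 <- focal_amplification(seg("2", 1, 240e6, 8.0), list("2", 15.5e6, 16.5e6))
  expect_false(at8$amplified)  # strict inequality at exactly 8 copies
  expect_error(focal_amplification(prof, list("9", 1e6, 2e6)), "no segment")
})

test_that("the all-arms driver is quiet on flat profiles and finds joint events", {
  spec <- genome_spec("grch37-arms")
  flat <- uniform_profile(spec)
  calls <- call_all_arms(flat, spec)
  expect_true(all(calls$direction == "none"))
  # acrocentric p arms are not queried
  expect_false(any(calls$chrom %in% c("13", "14", "15", "21", "22") & calls$arm == "p"))

  ev <- tibble::tibble(
    type = c("arm_gain", "window_gain"), chrom = c("17", "11"),
    arm = c("q", NA), start = c(NA, 68.5e6), end = c(NA, 69.5e6), copy = c(3, 4))
  prof <- simulate_copy_profile(spec, ev, noise_sd = 0, sample_id = "J1")
  jc <- call_all_arms(prof, spec)
  hits <- jc |> dplyr::filter(direction != "none")
  expect_setequal(paste0(hits$chrom, hits$arm), c("17q", "1111q13.3"))
})

test_that("SNVs are annotated with the rounded local copy state", {
  prof <- dplyr::bind_rows(seg("1", 1, 50e6, 2.04), seg("1", 50e6 + 1, 90e6, 2.97))
  snvs <- tibble::tibble(sample = "S1", chrom = "1", pos = c(10e6, 60e6, 95e6),
                         alt_reads = c(10L, 20L, 5L), depth = 40L)
  ann <- annotate_snv_copy(snvs, prof)
  expect_equal(ann$tumor_copies, c(2, 3, NA))
  expect_equal(ann$vaf, c(0.25, 0.5, 0.125))
})
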