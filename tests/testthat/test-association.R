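meta_n <- function(n, prefix = "S") {
  tibble::tibble(sample = sprintf("%s%03d", prefix, seq_len(n)),
                 age_years = rep(c(1, 3, 7), length.out = n),
                 timepoint = "diagnosis")
}

test_that("alteration matrix enforces the five-sample recurrence rule", {
  meta <- meta_n(20)
  alts <- dplyr::bind_rows(
    tibble::tibble(sample = meta$sample[1:5], alteration = "kept5"),
    tibble::tibble(sample = meta$sample[1:4], alteration = "dropped4"))
  m <- build_alteration_matrix(alts, meta)
  expect_true("kept5" %in% names(m))
  expect_false("dropped4" %in% names(m))
  expect_equal(attr(m, "dropped")$alteration, "dropped4")
  expect_error(build_alteration_matrix(dplyr::bind_rows(alts, alts[1, ]), meta),
               "duplicate")
})

test_that("relapse samples are excluded from the analysis matrix by default", {
  meta <- meta_n(12) |> dplyr::mutate(timepoint = rep(c("diagnosis", "relapse"), 6))
  alts <- tibble::tibble(sample = meta$sample[1:10], alteration = "X")
  m <- build_alteration_matrix(alts, meta)
  expect_equal(nrow(m), 6)
  expect_true(all(m$timepoint == "diagnosis"))
})

test_that("pairwise Fisher p-values match exact hypergeometric enumeration", {
  tables <- list(c(10, 0, 0, 10), c(3, 7, 6, 4), c(1, 11, 2, 8), c(5, 5, 5, 5),
                 c(0, 10, 10, 0), c(2, 2, 8, 8))
  for (tb in tables) {
    expect_equal(stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 fisher_enumeration_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
  }
  # and through the pipeline: a perfectly co-occurring pattern
  meta <- meta_n(20)
  alts <- dplyr::bind_rows(
    tibble::tibble(sample = meta$sample[1:10], alteration = "A"),
    tibble::tibble(sample = meta$sample[1:10], alteration = "B"))
  res <- pairwise_fisher(build_alteration_matrix(alts, meta))
  expect_equal(res$direction, "co-occurrence")
  expect_equal(res$p_value, fisher_enumeration_p(10, 0, 0, 10), tolerance = 1e-9)

  # perfectly exclusive pattern
  alts2 <- dplyr::bind_rows(
    tibble::tibble(sample = meta$sample[1:10], alteration = "A"),
    tibble::tibble(sample = meta$sample[11:20], alteration = "B"))
  res2 <- pairwise_fisher(build_alteration_matrix(alts2, meta))
  expect_equal(res2$direction, "exclusivity")
})

test_that("SV-linked co-occurrences are excluded and never raise the joint count", {
  meta <- meta_n(30)
  both <- meta$sample[1:8]
  alts <- dplyr::bind_rows(
    tibble::tibble(sample = c(both, meta$sample[9:12]), alteration = "gain_17q"),
    tibble::tibble(sample = c(both, meta$sample[13:17]), alteration = "gain_11q13.3"))
  m <- build_alteration_matrix(alts, meta)
  unfiltered <- pairwise_fisher(m)
  linked <- tibble::tibble(sample = both[1:3],
                           alt_a = "gain_11q13.3", alt_b = "gain_17q")
  filtered <- pairwise_fisher(m, linked)
  expect_equal(filtered$n_excluded_linked, 3)
  expect_equal(filtered$n11, unfiltered$n11 - 3)
  expect_lte(filtered$n11, unfiltered$n11)
  # non-joint cells untouched
  expect_equal(filtered$n10, unfiltered$n10)
  expect_equal(filtered$n01, unfiltered$n01)
})

test_that("degenerate tables return p = 1 with a flag", {
  meta <- meta_n(10)
  alts <- dplyr::bind_rows(
    tibble::tibble(sample = meta$sample, alteration = "everywhere"),
    tibble::tibble(sample = meta$sample[1:5], alteration = "half"))
  res <- pairwise_fisher(build_alteration_matrix(alts, meta))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("age groups partition the age axis with B-inclusive bounds", {
  expect_equal(assign_age_group(1.2), "A")
  expect_equal(assign_age_group(1.5), "B")
  expect_equal(assign_age_group(5.0), "B")
  expect_equal(assign_age_group(5.6), "C")
  ages <- seq(0, 20, by = 0.1)
  g <- assign_age_group(ages)
  expect_true(all(g %in% c("A", "B", "C")))
  expect_error(assign_age_group(-1))
})

test_that("age-group prevalence test separates stratified from flat alterations", {
  set.seed(14)
  meta <- tibble::tibble(sample = sprintf("S%03d", 1:150),
                         age_years = rep(c(1, 3, 7), each = 50))
  m <- meta
  m$flat <- stats::runif(150) < 0.5
  m$young <- stats::runif(150) < rep(c(0.9, 0.1, 0.1), each = 50)
  attr(m, "alterations") <- c("flat", "young")
  expect_gt(age_group_prevalence_test(m, "flat")$p_value, 0.05)
  strat <- age_group_prevalence_test(m, "young")
  expect_lt(strat$p_value, 0.001)
  expect_equal(strat$prevalence$group, c("A", "B", "C"))
  expect_equal(nrow(strat$pairwise), 3)
  single <- m[m$age_years == 1, ]
  expect_error(age_group_prevalence_test(single, "young"), "two non-empty")
})

test_that("age-distribution comparison recovers separated medians", {
  set.seed(15)
  m <- tibble::tibble(sample = sprintf("S%03d", 1:80),
                      age_years = c(pmax(0, stats::rnorm(40, 2.3, 0.5)),
                                    stats::rnorm(40, 5.6, 0.5)))
  m$MYCN <- rep(c(TRUE, FALSE), c(40, 40))
  m$ATRX <- !m$MYCN
  res <- age_distribution_test(m, list(MYCN = "MYCN", ATRX = "ATRX"))
  expect_equal(res$medians$median_age, c(2.3, 5.6), tolerance = 0.15)
  expect_lt(res$pairwise$p_value, 1e-3)
  expect_equal(max(res$ecdf$fraction_at_or_before), 1)
  same <- age_distribution_test(m, list(a = "MYCN", b = "MYCN"))
  expect_equal(same$pairwise$p_value, 1)
  expect_error(age_distribution_test(m, list(none = rep(FALSE, 80))), "empty")
})

test_that("Bonferroni adjustment reproduces the 17-test threshold", {
  expect_equal(signif(bonferroni_alpha(0.05, 17), 3), 2.94e-3)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_error(bonferroni_alpha(0.05, 0))
})

test_that("burden comparison separates Poisson burdens and flags tiny groups", {
  set.seed(16)
  m <- tibble::tibble(sample = sprintf("S%03d", 1:200),
                      age_years = rep(c(1, 7), each = 100))
  burden <- c(stats::rpois(100, 5), stats::rpois(100, 15))
  res <- burden_comparison(m, burden)
  expect_lt(res$pairwise$p_value, 1e-6)
  expect_equal(res$summary$median, c(5, 15), tolerance = 0.2)

  m2 <- tibble::tibble(sample = c("a", "b", "c"), age_years = c(1, 1, 7))
  res2 <- burden_comparison(m2, c(3, 4, 10))
  expect_true(res2$summary$low_n[res2$summary$group == "C"])

  same <- burden_comparison(m, rep(5, 200))
  expect_equal(same$pairwise$p_value, 1)
})
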