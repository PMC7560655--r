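#' Build the samples x alterations matrix for cohort statistics
#'
#' Converts long per-sample alteration calls into a wide logical matrix
#' joined to sample metadata, dropping alterations observed in fewer
#' than `min_recurrence` samples (five by default: rarer events lack
#' power). By default only diagnosis samples are retained, since relapse
#' samples are excluded from the co-occurrence and age analyses.
#'
#' @param alterations Long tibble `sample`, `alteration` (one row per
#'   altered sample; an optional logical `altered` column is honoured).
#' @param metadata Tibble with `sample` and optionally `age_years`,
#'   `timepoint` ("diagnosis"/"relapse"), `stage`, `purity`.
#' @param min_recurrence Minimum altered-sample count to keep a column.
#' @param diagnosis_only Drop samples whose `timepoint` is not
#'   "diagnosis" (when the column exists).
#' @param stage4_only Optionally restrict to stage-4 samples (sensitivity
#'   reruns).
#' @return Tibble: one row per sample, metadata columns, then one
#'   logical column per retained alteration. Attributes: `alterations`
#'   (kept names) and `dropped` (tibble of dropped alterations with
#'   counts).
#' @export
build_alteration_matrix <- function(alterations, metadata, min_recurrence = 5,
                                    diagnosis_only = TRUE, stage4_only = FALSE) {
  stopifnot(all(c("sample", "alteration") %in% names(alterations)))
  if ("altered" %in% names(alterations)) {
    alterations <- alterations |> filter(.data$altered)
  }
  if (anyDuplicated(alterations[c("sample", "alteration")])) {
    abort("duplicate sample/alteration entries")
  }
  if (diagnosis_only && "timepoint" %in% names(metadata)) {
    metadata <- metadata |> filter(.data$timepoint == "diagnosis")
  }
  if (stage4_only && "stage" %in% names(metadata)) {
    metadata <- metadata |> filter(.data$stage == 4)
  }
  alterations <- alterations |> filter(.data$sample %in% metadata$sample)
  counts <- alterations |> count(.data$alteration)
  kept <- counts |> filter(.data$n >= min_recurrence) |> pull("alteration")
  dropped <- counts |> filter(.data$n < min_recurrence)

  wide <- metadata
  for (alt in kept) {
    wide[[alt]] <- wide$sample %in%
      alterations$sample[alterations$alteration == alt]
  }
  attr(wide, "alterations") <- kept
  attr(wide, "dropped") <- dropped
  wide
}

alteration_names <- function(matrix) {
  attr(matrix, "alterations") %||%
    names(matrix)[map_lgl(matrix, is.logical)]
}

#' Pairwise mutual-exclusivity / co-occurrence Fisher tests
#'
#' For every pair of alterations, builds the 2 x 2 table of sample
#' counts by joint status and applies a two-sided Fisher's exact test.
#' Before tabulating, samples in which the two alterations co-occur
#' *and* are SV-linked (non-independent, per `linked`) are removed from
#' that pair's table entirely, so rearrangement-coupled events cannot
#' masquerade as biological co-occurrence. Direction is read from the
#' conditional odds ratio: above 1 is co-occurrence, below 1 mutual
#' exclusivity. Degenerate tables (an empty margin) return p = 1 with a
#' flag.
#'
#' @param matrix Alteration matrix from [build_alteration_matrix()].
#' @param linked Optional tibble `sample`, `alt_a`, `alt_b` of SV-linked
#'   pairs per sample ([linked_pairs_by_sample()]).
#' @return Tibble per pair: table cells `n11` (both), `n10`, `n01`,
#'   `n00`, `n_excluded_linked`, `odds_ratio`, `direction`, `p_value`,
#'   `degenerate`.
#' @export
pairwise_fisher <- function(matrix, linked = NULL) {
  alts <- alteration_names(matrix)
  if (length(alts) < 2) abort("need at least two alterations")
  pairs <- utils::combn(alts, 2)
  map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dat <- matrix[, c("sample", a, b)]
    excl <- character(0)
    if (!is.null(linked) && nrow(linked) > 0) {
      key <- paste(pmin(linked$alt_a, linked$alt_b), pmax(linked$alt_a, linked$alt_b))
      excl <- linked$sample[key == paste(min(a, b), max(a, b))]
      excl <- intersect(excl, dat$sample[dat[[a]] & dat[[b]]])
      dat <- dat[!dat$sample %in% excl, , drop = FALSE]
    }
    tab <- matrix(c(sum(dat[[a]] & dat[[b]]), sum(dat[[a]] & !dat[[b]]),
                    sum(!dat[[a]] & dat[[b]]), sum(!dat[[a]] & !dat[[b]])),
                  nrow = 2, byrow = TRUE)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      p <- 1; or <- NA_real_
    } else {
      ft <- fisher.test(tab, alternative = "two.sided")
      p <- ft$p.value; or <- unname(ft$estimate)
    }
    tibble(alt_a = a, alt_b = b,
           n11 = tab[1, 1], n10 = tab[1, 2], n01 = tab[2, 1], n00 = tab[2, 2],
           n_excluded_linked = length(excl),
           odds_ratio = or,
           direction = dplyr::case_when(
             degenerate ~ NA_character_,
             or > 1 ~ "co-occurrence",
             or < 1 ~ "exclusivity",
             TRUE ~ "none"),
           p_value = p, degenerate = degenerate)
  }) |> list_rbind()
}

#' Assign diagnosis ages to age groups A / B / C
#'
#' Group A is under 1.5 years, group B 1.5 to 5 years (both bounds
#' inclusive to B), group C over 5 years.
#'
#' @param age_years Non-negative ages in years; vectorised.
#' @export
assign_age_group <- function(age_years) {
  stopifnot(all(age_years >= 0))
  dplyr::case_when(age_years < 1.5 ~ "A",
                   age_years <= 5 ~ "B",
                   TRUE ~ "C")
}

#' Test an alteration's prevalence across age groups
#'
#' A single exact test on the age-group x altered/unaltered contingency
#' table (Fisher's exact test, exact network algorithm; falls back to a
#' simulated p-value with a fixed seed if the exact computation is
#' infeasible). Pairwise group-vs-group 2 x 2 tests are also returned
#' for transparency.
#'
#' @param matrix Alteration matrix with `age_years` metadata.
#' @param alteration Alteration column name.
#' @param sim_B Replicates for the simulated fallback.
#' @return List with `p_value`, `prevalence` (tibble per group) and
#'   `pairwise` (tibble of 2 x 2 tests).
#' @export
age_group_prevalence_test <- function(matrix, alteration, sim_B = 1e5) {
  stopifnot(alteration %in% names(matrix), "age_years" %in% names(matrix))
  grp <- assign_age_group(matrix$age_years)
  present <- sort(unique(grp))
  if (length(present) < 2) abort("need at least two non-empty age groups")
  tab <- table(factor(grp, levels = present), factor(matrix[[alteration]], levels = c(FALSE, TRUE)))
  if (any(colSums(tab) == 0)) abort("degenerate margins: alteration constant across samples")
  p <- tryCatch(fisher.test(tab, workspace = 2e7)$p.value,
                error = function(e) {
                  withr::with_seed(20230101L,
                    fisher.test(tab, simulate.p.value = TRUE, B = sim_B)$p.value)
                })
  prevalence <- tibble(group = present,
                       n = as.integer(rowSums(tab)),
                       n_altered = as.integer(tab[, "TRUE"]),
                       prevalence = as.numeric(tab[, "TRUE"] / rowSums(tab)))
  pw <- utils::combn(present, 2)
  pairwise <- map(seq_len(ncol(pw)), function(j) {
    sel <- grp %in% pw[, j]
    t2 <- table(factor(grp[sel], levels = pw[, j]),
                factor(matrix[[alteration]][sel], levels = c(FALSE, TRUE)))
    tibble(group_a = pw[1, j], group_b = pw[2, j],
           p_value = fisher.test(t2)$p.value)
  }) |> list_rbind()
  list(p_value = p, prevalence = prevalence, pairwise = pairwise)
}

#' Compare diagnosis-age distributions between alteration sets
#'
#' For named, mutually comparable sets of samples (e.g. MYCN-altered,
#' ATRX-altered, neither), computes per-set median ages, all pairwise
#' two-sided Wilcoxon rank-sum tests, and the empirical cumulative
#' distribution of age (fraction of each set diagnosed at or before
#' each age).
#'
#' @param matrix Alteration matrix with `age_years`.
#' @param sets Named list of either alteration column names or logical
#'   vectors/sample-id vectors selecting each set.
#' @return List: `medians` tibble, `pairwise` Wilcoxon tibble, `ecdf`
#'   tibble (`set`, `age_years`, `fraction_at_or_before`).
#' @export
age_distribution_test <- function(matrix, sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)), "age_years" %in% names(matrix))
  ages <- imap(sets, function(sel, nm) {
    idx <- if (is.character(sel) && length(sel) == 1 && sel %in% names(matrix)) {
      matrix[[sel]]
    } else if (is.logical(sel)) sel else matrix$sample %in% sel
    a <- matrix$age_years[idx]
    if (length(a) == 0) abort(sprintf("set %s is empty", nm))
    a
  })
  medians <- tibble(set = names(ages),
                    n = unname(map_int(ages, length)),
                    median_age = unname(map_dbl(ages, median)))
  pairwise <- NULL
  if (length(ages) >= 2) {
    pw <- utils::combn(names(ages), 2)
    pairwise <- map(seq_len(ncol(pw)), function(j) {
      tibble(set_a = pw[1, j], set_b = pw[2, j],
             p_value = wilcox_p(ages[[pw[1, j]]], ages[[pw[2, j]]]))
    }) |> list_rbind()
  }
  ecdf_tbl <- imap(ages, function(a, nm) {
    xs <- sort(unique(a))
    tibble(set = nm, age_years = xs, fraction_at_or_before = ecdf(a)(xs))
  }) |> list_rbind()
  list(medians = medians, pairwise = pairwise, ecdf = ecdf_tbl)
}

#' Bonferroni-adjusted significance level
#'
#' `family_alpha / n_tests`; 0.05 over the 17 recurrent alterations gives
#' 2.94e-3.
#'
#' @param family_alpha Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  family_alpha / n_tests
}

#' Compare coding mutation burden between age groups
#'
#' @param matrix Alteration matrix with `age_years` metadata.
#' @param burden Per-sample non-negative mutation counts, or the name of
#'   a count column in `matrix`.
#' @return List: `summary` tibble per group (n, median, IQR, low-n
#'   flag), `pairwise` two-sided Wilcoxon rank-sum tibble.
#' @export
burden_comparison <- function(matrix, burden = "n_coding_snvs") {
  b <- if (is.character(burden) && length(burden) == 1) matrix[[burden]] else burden
  stopifnot(!is.null(b), all(b >= 0), length(b) == nrow(matrix))
  grp <- assign_age_group(matrix$age_years)
  present <- sort(unique(grp))
  if (any(tapply(b, grp, length) == 0)) abort("empty age group")
  summary <- tibble(
    group = present,
    n = as.integer(tapply(b, grp, length)[present]),
    median = as.numeric(tapply(b, grp, median)[present]),
    q25 = as.numeric(tapply(b, grp, quantile, probs = 0.25)[present]),
    q75 = as.numeric(tapply(b, grp, quantile, probs = 0.75)[present]),
    low_n = as.integer(tapply(b, grp, length)[present]) < 2
  )
  pw <- utils::combn(present, 2)
  pairwise <- map(seq_len(ncol(pw)), function(j) {
    tibble(group_a = pw[1, j], group_b = pw[2, j],
           p_value = wilcox_p(b[grp == pw[1, j]], b[grp == pw[2, j]]))
  }) |> list_rbind()
  list(summary = summary, pairwise = pairwise)
}

# two-sided rank-sum p; fully tied comparisons carry no evidence (p = 1)
wilcox_p <- function(x, y) {
  p <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  if (is.nan(p)) 1 else p
}
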