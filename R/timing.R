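#' Expected variant allele fraction under the purity-adjusted copy model
#'
#' For a clonal somatic mutation carried on `mutated_copies` of
#' `tumor_copies` tumor chromosomes in a specimen of purity `purity`
#' (fraction of cells that are tumor), with `normal_copies` chromosomes
#' in admixed normal cells, the expected VAF is
#' `m * rho / (T * rho + N * (1 - rho))`. At purity 1 this reduces to
#' `m / T`: 1 of 3 copies gives 0.33, 2 of 3 gives 0.67.
#'
#' @param purity Tumor purity in (0, 1]. Vectorised.
#' @param tumor_copies Total tumor copy number T (positive integer).
#' @param mutated_copies Copies carrying the mutation, 1..T.
#' @param normal_copies Copy number in normal cells (2 for autosomes).
#' @return Expected VAF in (0, 1].
#' @examples
#' expected_vaf(1, 3, 1)    # 0.333...
#' expected_vaf(1, 3, 2)    # 0.667...
#' expected_vaf(0.5, 3, 1)  # 0.20
#' @export
expected_vaf <- function(purity, tumor_copies, mutated_copies, normal_copies = 2) {
  stopifnot(all(purity > 0), all(purity <= 1),
            all(tumor_copies >= 1), all(mutated_copies >= 1),
            all(mutated_copies <= tumor_copies), all(normal_copies >= 0))
  mutated_copies * purity / (tumor_copies * purity + normal_copies * (1 - purity))
}

#' VAF cutoff between single- and multi-allele mutations in gained regions
#'
#' The midpoint of the expected VAFs for mutations on 1 of T and 2 of T
#' copies at the sample's purity: 0.5 at purity 1 for 3-copy regions.
#' Mutations at or below the cutoff are classified as lying on a single
#' allele; above it, on 2 or more alleles.
#'
#' @inheritParams expected_vaf
#' @export
vaf_cutoff <- function(purity, tumor_copies = 3, normal_copies = 2) {
  (expected_vaf(purity, tumor_copies, 1, normal_copies) +
     expected_vaf(purity, tumor_copies, 2, normal_copies)) / 2
}

#' Classify allele multiplicity of mutations in copy-gained regions
#'
#' @param vaf Observed variant allele fraction(s) in \[0, 1\].
#' @inheritParams expected_vaf
#' @return `"single_allele"` (VAF at or below the purity-adjusted cutoff,
#'   inclusive) or `"multi_allele"`.
#' @export
classify_multiplicity <- function(vaf, purity, tumor_copies = 3, normal_copies = 2) {
  stopifnot(all(vaf >= 0), all(vaf <= 1))
  cut <- vaf_cutoff(purity, tumor_copies, normal_copies)
  if_else(vaf <= cut, "single_allele", "multi_allele")
}

#' Expected single-allele mutation fraction in 3-copy regions
#'
#' Forward model for the timing analysis. Mutations accumulating before
#' the copy gain arise at an equal rate on the chromosome that is later
#' duplicated and on the one that is not, so immediately after the
#' duplication half of the pre-existing mutations sit on 2 of 3 alleles;
#' every post-gain mutation sits on 1 of 3. If a fraction `pre` of the
#' region's mutations predate the gain, the expected single-allele
#' fraction is `1 - pre / 2`: 0.5 when everything predates the gain, and
#' 0.75 when the pre- and post-gain molecular times (mutation counts)
#' are equal.
#'
#' @param fraction_pre_gain Fraction of 3-copy-region mutations that arose
#'   before the gain, in \[0, 1\].
#' @export
single_allele_fraction <- function(fraction_pre_gain) {
  stopifnot(all(fraction_pre_gain >= 0), all(fraction_pre_gain <= 1))
  1 - fraction_pre_gain / 2
}

#' Invert the timing model: molecular-time split from an observed fraction
#'
#' `pre_gain_fraction = 2 * (1 - f)` where `f` is the single-allele
#' fraction; f = 0.75 maps to an equal pre/post split (0.5), f = 1 to a
#' gain preceding all retained mutations (0), and f = 0.5 to all
#' mutations predating the gain (1). Values of `f` below 0.5 violate the
#' model and are clipped to 1 with a warning.
#'
#' @param fraction_single_allele Observed fraction of 3-copy-region
#'   mutations on a single allele.
#' @export
pre_gain_fraction_estimate <- function(fraction_single_allele) {
  f <- fraction_single_allele
  stopifnot(all(f >= 0), all(f <= 1))
  if (any(f < 0.5)) {
    warn("single-allele fraction below 0.5 violates the timing model; clipping estimate to 1")
  }
  pmin(pmax(2 * (1 - f), 0), 1)
}

#' Time copy gains from mutations in 3-copy regions
#'
#' For each sample, classifies its 3-copy-region mutations into single-
#' vs multi-allele by the purity-adjusted VAF cutoff and summarises the
#' timing evidence. A sample is eligible for timing when its purity is
#' at least `min_purity` (0.70) and it carries at least `min_snvs` (20)
#' mutations in autosomal 3-copy regions; the copy gain is called early
#' (`gain_early`) when more than 75% of those mutations lie on a single
#' allele — more single-allele mutations than the equal-time expectation.
#'
#' @param snvs Tibble with columns `sample`, `vaf` (or `alt_reads` +
#'   `depth`), and `tumor_copies` (local total copy number; only rows at
#'   3 are used).
#' @param metadata Tibble with `sample` and `purity`.
#' @param min_purity,min_snvs Eligibility filters.
#' @param early_threshold Strict lower bound on the single-allele
#'   fraction for `gain_early` (0.75 = equal molecular time).
#' @return Tibble per sample: `n_3copy_snvs`, `fraction_single_allele`,
#'   `cutoff_used`, `eligible`, `gain_early` (NA when ineligible), and
#'   `pre_gain_fraction` (model inversion, NA when ineligible).
#' @export
timing_fraction <- function(snvs, metadata, min_purity = 0.70, min_snvs = 20,
                            early_threshold = 0.75) {
  stopifnot(all(c("sample", "tumor_copies") %in% names(snvs)),
            all(c("sample", "purity") %in% names(metadata)))
  if (!"vaf" %in% names(snvs)) {
    snvs <- snvs |> mutate(vaf = .data$alt_reads / .data$depth)
  }
  metadata |>
    distinct(.data$sample, .data$purity) |>
    group_by(.data$sample, .data$purity) |>
    group_modify(function(key_df, key) {
      rows <- snvs[snvs$sample == key$sample & snvs$tumor_copies == 3, , drop = FALSE]
      n <- nrow(rows)
      cut <- vaf_cutoff(key$purity)
      frac <- if (n > 0) {
        mean(classify_multiplicity(rows$vaf, key$purity) == "single_allele")
      } else NA_real_
      eligible <- key$purity >= min_purity && n >= min_snvs
      tibble(
        n_3copy_snvs = n,
        fraction_single_allele = frac,
        cutoff_used = cut,
        eligible = eligible,
        gain_early = if (eligible) frac > early_threshold else NA,
        pre_gain_fraction = if (eligible) {
          suppressWarnings(pre_gain_fraction_estimate(frac))
        } else NA_real_
      )
    }) |>
    ungroup()
}

#' Classify a mutation as clonal or subclonal
#'
#' Generalises the clinical rule of thumb that a diploid-region mutation
#' with VAF above 0.4 at full purity is clonal: a mutation is called
#' clonal when its VAF exceeds `factor` (default 0.8) times the expected
#' VAF of a heterozygous-equivalent clonal mutation at the local copy
#' number and sample purity (`m = floor(copies / 2)`, at least 1). At
#' purity 1 this gives a threshold of 0.8 x 0.5 = 0.4 for both 2- and
#' 4-copy regions, and 0.8 x 1/3 = 0.267 at 3 copies, so the 3-copy
#' VAF-0.32 case classifies clonal.
#'
#' @param vaf Observed VAF(s).
#' @param purity Tumor purity.
#' @param tumor_copies Local total copy number.
#' @param factor Fraction of the expected single-allele VAF required
#'   (configurable; lower values tolerate purity/copy estimation error).
#' @param normal_copies Normal-cell copy number.
#' @return `"clonal"` or `"subclonal"`.
#' @export
classify_clonality <- function(vaf, purity, tumor_copies = 2, factor = 0.8,
                               normal_copies = 2) {
  stopifnot(all(vaf >= 0), all(vaf <= 1))
  m_het <- pmax(1, floor(tumor_copies / 2))
  exp_het <- expected_vaf(purity, tumor_copies, m_het, normal_copies)
  if_else(vaf > factor * exp_het, "clonal", "subclonal")
}
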