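#' Chromosome arm geometry for the copy-number caller
#'
#' Builds the table of autosomal chromosome arms that the segmental
#' copy-number caller queries. Two modes are available:
#'
#' * `"grch37-arms"`: the 22 human autosomes with GRCh37 chromosome lengths
#'   and centromere positions (p arm = `[1, centromere]`, q arm =
#'   `(centromere, length]`). The five acrocentric autosomes
#'   (13, 14, 15, 21, 22) are flagged: their p arms carry no unique
#'   sequence and are excluded from segmental arm calling, and their q
#'   arms use a shorter query window (see [call_arm_alteration()]).
#' * `"toy"`: four small synthetic chromosomes with mixed arm lengths,
#'   including an arm shorter than the 30 Mb query window and one
#'   acrocentric chromosome, for fast tests and examples.
#'
#' @param mode `"toy"` or `"grch37-arms"`.
#' @return A tibble with one row per chromosome: `chrom`, `p_length`,
#'   `q_length`, `length`, `acrocentric`.
#' @examples
#' genome_spec("toy")
#' genome_spec("grch37-arms")
#' @export
genome_spec <- function(mode = c("grch37-arms", "toy")) {
  mode <- match.arg(mode)
  spec <- if (mode == "toy") toy_genome_tbl() else grch37_genome_tbl()
  stopifnot(!anyDuplicated(spec$chrom), all(spec$p_length > 0), all(spec$q_length > 0))
  spec
}

toy_genome_tbl <- function() {
  tibble(
    chrom       = c("t1", "t2", "t3", "t4"),
    p_length    = c(60e6, 40e6, 25e6, 8e6),
    q_length    = c(80e6, 20e6, 45e6, 50e6),
    acrocentric = c(FALSE, FALSE, FALSE, TRUE)
  ) |>
    mutate(length = .data$p_length + .data$q_length)
}

# GRCh37 (hg19) autosome lengths and approximate centromere midpoints (bp).
grch37_genome_tbl <- function() {
  len <- c(
    249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
    159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
    115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
    59128983, 63025520, 48129895, 51304566
  )
  cen <- c(
    125000000, 93300000, 91000000, 50400000, 48400000, 61000000,
    59900000, 45600000, 49000000, 40200000, 53700000, 35800000,
    17900000, 17600000, 19000000, 36600000, 24000000, 17200000,
    26500000, 27500000, 13200000, 14700000
  )
  tibble(
    chrom       = as.character(1:22),
    p_length    = cen,
    q_length    = len - cen,
    length      = len,
    acrocentric = as.character(1:22) %in% c("13", "14", "15", "21", "22")
  )
}

#' Expand a genome spec into one row per chromosome arm
#'
#' @param spec A genome spec tibble from [genome_spec()].
#' @return A tibble with `chrom`, `arm` ("p"/"q"), `start`, `end` (1-based
#'   inclusive), `arm_length`, `terminus` (the telomeric end of the arm),
#'   and `acrocentric`.
#' @export
arm_table <- function(spec) {
  bind_rows(
    spec |> mutate(arm = "p", start = 1, end = .data$p_length,
                   terminus = 1),
    spec |> mutate(arm = "q", start = .data$p_length + 1, end = .data$length,
                   terminus = .data$length)
  ) |>
    mutate(arm_length = .data$end - .data$start + 1) |>
    select("chrom", "arm", "start", "end", "arm_length", "terminus", "acrocentric") |>
    arrange(match(.data$chrom, spec$chrom), .data$arm)
}

# single arm row, with a clear error when absent
arm_row <- function(spec, chrom, arm) {
  at <- arm_table(spec)
  row <- at[at$chrom == chrom & at$arm == arm, ]
  if (nrow(row) != 1L) {
    abort(sprintf("arm %s%s not present in genome spec", chrom, arm))
  }
  row
}
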