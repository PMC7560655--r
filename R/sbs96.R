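#' The 96 single-base-substitution trinucleotide classes
#'
#' Class labels follow the COSMIC convention: substitutions are expressed
#' on the pyrimidine strand (mutated base C or T), giving 6 substitution
#' types times 16 flanking-base combinations, ordered by substitution type
#' (C>A, C>G, C>T, T>A, T>C, T>G) and then by 5' and 3' flank.
#'
#' @return Character vector of length 96, e.g. `"T[C>A]A"`.
#' @export
sbs96_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r) paste0(l, "[", s, "]", r))))
  }))
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a substitution into its 96-class trinucleotide context
#'
#' Purine-reference mutations (ref A or G) are reverse-complemented so the
#' mutated base is reported on the pyrimidine strand; the flanks swap and
#' complement accordingly. Vectorised over all four arguments.
#'
#' @param ref,alt Reference and alternate base (`A`/`C`/`G`/`T`, `ref != alt`).
#' @param left,right The 5' and 3' flanking bases on the same strand as
#'   `ref`.
#' @return Character vector of class labels; `NA` (with a warning counting
#'   rejects) for records with ambiguous bases.
#' @examples
#' classify_context("C", "A", "T", "A")  # "T[C>A]A"
#' classify_context("G", "T", "T", "A")  # same class, read off the other strand
#' @export
classify_context <- function(ref, alt, left, right) {
  n <- max(length(ref), length(alt), length(left), length(right))
  ref <- toupper(rep_len(ref, n)); alt <- toupper(rep_len(alt, n))
  left <- toupper(rep_len(left, n)); right <- toupper(rep_len(right, n))
  valid <- ref %in% names(REVCOMP) & alt %in% names(REVCOMP) &
    left %in% names(REVCOMP) & right %in% names(REVCOMP) & ref != alt
  if (any(!valid)) {
    warn(sprintf("rejected %d record(s) with ambiguous or invalid bases", sum(!valid)))
  }
  flip <- valid & ref %in% c("A", "G")
  r <- ref; a <- alt; l <- left; rt <- right
  r[flip] <- REVCOMP[ref[flip]]
  a[flip] <- REVCOMP[alt[flip]]
  l[flip] <- REVCOMP[right[flip]]
  rt[flip] <- REVCOMP[left[flip]]
  out <- paste0(l, "[", r, ">", a, "]", rt)
  out[!valid] <- NA_character_
  out
}

#' Build per-sample 96-class mutation spectra
#'
#' Counts SNVs into the 96 trinucleotide classes. Contexts are taken from
#' a `context96` column if present, otherwise derived with
#' [classify_context()] from `ref`, `alt`, `left`, `right` columns.
#'
#' @param snvs Tibble of SNVs with a `sample` column.
#' @param samples Sample ids to tabulate (defaults to those present;
#'   supply explicitly to emit all-zero spectra for mutation-free
#'   samples).
#' @return Tibble with `sample`, `class` (all 96 classes for every sample,
#'   in COSMIC order) and `count`.
#' @export
build_spectrum <- function(snvs, samples = unique(snvs$sample)) {
  classes <- sbs96_classes()
  if (nrow(snvs) > 0 && !("context96" %in% names(snvs))) {
    snvs <- snvs |>
      mutate(context96 = classify_context(.data$ref, .data$alt, .data$left, .data$right))
  }
  grid <- tidyr::expand_grid(sample = samples, class = classes)
  if (nrow(snvs) == 0) {
    return(grid |> mutate(count = 0L))
  }
  bad <- !snvs$context96 %in% classes
  if (any(bad)) {
    warn(sprintf("dropping %d SNV(s) with unrecognised context", sum(bad)))
    snvs <- snvs[!bad, , drop = FALSE]
  }
  counts <- snvs |> count(.data$sample, class = .data$context96, name = "count")
  grid |>
    left_join(counts, by = c("sample", "class")) |>
    mutate(count = if_else(is.na(.data$count), 0L, as.integer(.data$count)))
}

#' Convert a long spectrum tibble to a samples x 96 count matrix
#'
#' @param spectrum Output of [build_spectrum()].
#' @return Numeric matrix, rows = samples, columns = the 96 classes.
#' @export
spectrum_matrix <- function(spectrum) {
  classes <- sbs96_classes()
  wide <- spectrum |>
    tidyr::pivot_wider(names_from = "class", values_from = "count", values_fill = 0)
  m <- as.matrix(wide[, classes, drop = FALSE])
  rownames(m) <- wide$sample
  m
}

#' Fraction of a spectrum in the C>A substitution classes
#'
#' @param spectrum Long spectrum tibble ([build_spectrum()]) or a named
#'   96-vector of counts.
#' @return For a tibble, a tibble `sample`, `c_to_a_fraction`; for a
#'   vector, a single fraction. Zero-count spectra give `NA` with a warning.
#' @export
c_to_a_fraction <- function(spectrum) {
  is_ca <- grepl("\\[C>A\\]", sbs96_classes())
  if (is.numeric(spectrum)) {
    v <- spectrum_vector(spectrum)
    tot <- sum(v)
    if (tot == 0) { warn("zero-count spectrum"); return(NA_real_) }
    return(sum(v[is_ca]) / tot)
  }
  spectrum |>
    group_by(.data$sample) |>
    summarise(
      c_to_a_fraction = {
        tot <- sum(.data$count)
        if (tot == 0) NA_real_ else sum(.data$count[grepl("\\[C>A\\]", .data$class)]) / tot
      },
      .groups = "drop"
    )
}

# coerce a (possibly unordered) named 96-vector into COSMIC class order
spectrum_vector <- function(x) {
  classes <- sbs96_classes()
  if (!is.null(names(x))) {
    stopifnot(all(classes %in% names(x)))
    x <- x[classes]
  } else {
    stopifnot(length(x) == 96)
    names(x) <- classes
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
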