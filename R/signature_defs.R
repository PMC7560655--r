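#' Bundled synthetic signature definitions for examples and tests
#'
#' A small, deterministic set of stylised single-base-substitution
#' signatures over the 96 trinucleotide classes. They are synthetic:
#' constructed to mimic the qualitative shape of well-known mutational
#' processes (not the published COSMIC probabilities), so that the
#' refitting and attribution machinery can be exercised without any
#' external download. Shapes:
#'
#' * `SBS1`: clock-like C>T concentrated at NpCpG contexts.
#' * `SBS3`: broad, featureless ("flat") spectrum.
#' * `SBS5`: flat with a mild T>C tilt.
#' * `SBS18`: dominated by C>A classes with its strongest peak at
#'   `T[C>A]A` (reactive-oxygen-species style).
#' * `SBS31`: C>T at CpC/CpT dinucleotides (platinum-therapy style).
#'
#' Every signature assigns non-zero probability to every class, so
#' per-mutation attribution is always defined.
#'
#' @param signatures Which of the bundled signatures to return.
#' @return A 96 x K numeric matrix; rows named by class in COSMIC order,
#'   columns by signature; each column sums to 1.
#' @export
example_signatures <- function(signatures = c("SBS1", "SBS3", "SBS5", "SBS18", "SBS31")) {
  classes <- sbs96_classes()
  sub <- sub(".*\\[(.+)\\].*", "\\1", classes)
  l <- substr(classes, 1, 1)
  r <- substr(classes, 7, 7)

  base <- rep(1, 96)  # floor so every class is reachable
  build <- function(extra) { w <- base + extra; w / sum(w) }

  defs <- list(
    SBS1  = build(ifelse(sub == "C>T" & r == "G", c(A = 60, C = 40, G = 30, T = 45)[l], 0)),
    SBS3  = build(rep(0.25, 96)),
    SBS5  = build(ifelse(sub == "T>C", 4, 0.5)),
    SBS18 = build(ifelse(sub == "C>A", ifelse(l == "T" & r == "A", 90,
                                              ifelse(l %in% c("G", "T"), 25, 12)), 0)),
    SBS31 = build(ifelse(sub == "C>T" & l == "C" & r %in% c("C", "T"), 55, 0))
  )
  signatures <- match.arg(signatures, names(defs), several.ok = TRUE)
  m <- do.call(cbind, defs[signatures])
  rownames(m) <- classes
  m
}

#' Read / write signature definition matrices
#'
#' The on-disk layout is the COSMIC v3 tab-delimited format: a `Type`
#' column of 96 class labels followed by one column per signature.
#'
#' @param path File path.
#' @return `read_signature_matrix()` returns a 96 x K matrix with class
#'   rownames in COSMIC order; columns renormalised to sum to 1 if they
#'   do not already (within 1e-6 a warning is not raised).
#' @export
read_signature_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(nrow(df) == 96)
  classes <- sbs96_classes()
  type_col <- names(df)[1]
  stopifnot(setequal(df[[type_col]], classes))
  m <- as.matrix(df[match(classes, df[[type_col]]), -1, drop = FALSE])
  rownames(m) <- classes
  storage.mode(m) <- "double"
  stopifnot(all(m >= 0), all(colSums(m) > 0))
  sweep(m, 2, colSums(m), "/")
}

#' @rdname read_signature_matrix
#' @param signatures A 96 x K signature matrix.
#' @export
write_signature_matrix <- function(signatures, path) {
  df <- tibble(Type = rownames(signatures)) |>
    bind_cols(as_tibble(signatures))
  readr::write_tsv(df, path)
  invisible(path)
}

# validate a 96 x K signature matrix and order its rows canonically
as_signature_matrix <- function(signatures) {
  classes <- sbs96_classes()
  stopifnot(is.matrix(signatures), nrow(signatures) == 96,
            !is.null(rownames(signatures)), !is.null(colnames(signatures)))
  stopifnot(setequal(rownames(signatures), classes))
  m <- signatures[classes, , drop = FALSE]
  stopifnot(all(m >= 0))
  csums <- colSums(m)
  stopifnot(all(abs(csums - 1) < 1e-6))
  m
}
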