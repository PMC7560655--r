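cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Refit known signature definitions to a single mutation spectrum
#'
#' Estimates how many of a sample's SNVs each signature caused. The
#' 96-class count vector is decomposed on the signature columns by
#' non-negative least squares, followed by greedy backward elimination:
#' the non-forced signature whose removal costs the least reconstruction
#' cosine is dropped while the cost stays below `drop_tol` (0.01),
#' enforcing sparsity. Forced signatures (by default SBS1, SBS3 and SBS5
#' when present: ubiquitous or flat processes that are real but hard to
#' detect) are never eliminated. Exposures are rescaled so they sum
#' exactly to the sample's SNV total, and the reconstruction cosine
#' (observed vs fitted spectrum) is attached as the quality score; the
#' conventional reliability gate for downstream per-mutation attribution
#' is cosine >= 0.9.
#'
#' @param counts Named 96-vector of class counts, or a one-sample long
#'   spectrum tibble from [build_spectrum()].
#' @param signatures 96 x K signature probability matrix (columns sum
#'   to 1), e.g. [example_signatures()].
#' @param forced Signature names kept in every fit regardless of
#'   sparsification.
#' @param drop_tol Maximum reconstruction-cosine drop tolerated when
#'   eliminating a signature.
#' @return An object of class `sig_fit`: exposures (SNV counts per
#'   signature, zero for eliminated ones), the active set, the
#'   reconstruction cosine and the fitted spectrum. Zero-count spectra
#'   return all-zero exposures with `cosine = NA` and `flag =
#'   "empty_spectrum"`. See [tidy.sig_fit()] and [glance.sig_fit()].
#' @export
refit_exposures <- function(counts, signatures,
                            forced = intersect(c("SBS1", "SBS3", "SBS5"),
                                               colnames(signatures)),
                            drop_tol = 0.01) {
  sample_id <- NA_character_
  if (is.data.frame(counts)) {
    stopifnot(length(unique(counts$sample)) == 1)
    sample_id <- counts$sample[1]
    counts <- setNames(counts$count, counts$class)
  }
  y <- spectrum_vector(counts)
  m <- as_signature_matrix(signatures)
  stopifnot(all(forced %in% colnames(m)))
  total <- sum(y)

  if (total == 0) {
    fit <- structure(list(
      sample = sample_id, exposures = setNames(rep(0, ncol(m)), colnames(m)),
      active = character(0), cosine = NA_real_, total = 0,
      fitted = setNames(rep(0, 96), rownames(m)), observed = y,
      signatures = m, flag = "empty_spectrum"), class = "sig_fit")
    return(fit)
  }

  nnls_fit <- function(active) {
    x <- pracma::lsqnonneg(m[, active, drop = FALSE], as.numeric(y))$x
    ex <- setNames(x, active)
    list(exposures = ex, cosine = cosine_sim(y, m[, active, drop = FALSE] %*% x))
  }

  active <- colnames(m)
  cur <- nnls_fit(active)
  repeat {
    candidates <- setdiff(active, forced)
    if (length(candidates) == 0) break
    trials <- map(candidates, function(drop) nnls_fit(setdiff(active, drop)))
    cosines <- map_dbl(trials, "cosine")
    best <- which.max(cosines)
    if (cur$cosine - cosines[best] < drop_tol) {
      active <- setdiff(active, candidates[best])
      cur <- trials[[best]]
    } else break
  }

  exposures <- setNames(rep(0, ncol(m)), colnames(m))
  ssum <- sum(cur$exposures)
  exposures[active] <- if (ssum > 0) cur$exposures * total / ssum else 0
  fitted <- as.numeric(m %*% exposures)
  structure(list(
    sample = sample_id, exposures = exposures,
    active = names(exposures)[exposures > 0],
    cosine = cur$cosine, total = total,
    fitted = setNames(fitted, rownames(m)), observed = y,
    signatures = m, flag = NA_character_), class = "sig_fit")
}

#' @export
print.sig_fit <- function(x, ...) {
  cat("<sig_fit>", if (!is.na(x$sample)) x$sample else "", "\n")
  cat("  SNVs:", x$total, " reconstruction cosine:", round(x$cosine, 4), "\n")
  on <- x$exposures[x$exposures > 0]
  for (k in names(on)) cat(sprintf("  %-8s %8.1f (%4.1f%%)\n", k, on[[k]], 100 * on[[k]] / x$total))
  invisible(x)
}

#' Tidy and summarise signature fits
#'
#' @param x A `sig_fit` from [refit_exposures()].
#' @param ... Unused.
#' @return `tidy()` gives one row per signature with `exposure` (SNV
#'   count) and `proportion`; `glance()` a one-row summary with the SNV
#'   total, reconstruction cosine, active-signature count and the
#'   `reliable` flag (cosine >= 0.9).
#' @export
tidy.sig_fit <- function(x, ...) {
  tibble(sample = x$sample, signature = names(x$exposures),
         exposure = unname(x$exposures),
         proportion = if (x$total > 0) unname(x$exposures) / x$total else NA_real_)
}

#' @rdname tidy.sig_fit
#' @export
glance.sig_fit <- function(x, ...) {
  tibble(sample = x$sample, n_snvs = x$total, cosine = x$cosine,
         n_active = length(x$active), reliable = !is.na(x$cosine) && x$cosine >= 0.9)
}

#' Refit signatures for every sample of a cohort spectrum
#'
#' @param spectrum Long spectrum tibble ([build_spectrum()]).
#' @inheritParams refit_exposures
#' @return Tibble with one row per sample: `fit` (list-column of
#'   `sig_fit`), `n_snvs`, `cosine`, `n_active`, `reliable`.
#' @export
fit_cohort <- function(spectrum, signatures,
                       forced = intersect(c("SBS1", "SBS3", "SBS5"),
                                          colnames(signatures)),
                       drop_tol = 0.01) {
  spectrum |>
    group_by(sample = .data$sample) |>
    group_modify(function(df, key) {
      fit <- refit_exposures(df |> mutate(sample = key$sample), signatures,
                             forced = forced, drop_tol = drop_tol)
      glance(fit) |> select(-"sample") |> mutate(fit = list(fit), .before = 1)
    }) |>
    ungroup()
}

#' Per-sample exposures of a cohort fit, long format
#'
#' @param fits Output of [fit_cohort()].
#' @export
cohort_exposures <- function(fits) {
  fits$fit |> map(tidy) |> list_rbind()
}

#' Probability that a mutation was caused by each fitted signature
#'
#' For a mutation at trinucleotide context `c` in a sample with fitted
#' exposures `s`, the probability that signature `i` caused it is
#' `s_i * P[c, i] / sum_k s_k * P[c, k]`, the share of the expected
#' mutation count at that context contributed by signature `i`. The sum
#' runs over the signatures detected in the sample (positive exposure).
#'
#' @param context A 96-class label (e.g. `"T[C>A]A"`); vectorised.
#' @param exposures A `sig_fit`, or a named non-negative vector of
#'   exposures (then `signatures` must be supplied).
#' @param signatures 96 x K signature matrix; taken from the fit when
#'   omitted.
#' @return Tibble with one row per context x active signature:
#'   `probability` (summing to 1 within each context) and `is_best`.
#'   A context that no active signature can produce is an error.
#' @examples
#' fit <- refit_exposures(500 * example_signatures()[, "SBS18"],
#'                        example_signatures())
#' attribute_mutation("T[C>A]A", fit)
#' @export
attribute_mutation <- function(context, exposures, signatures = NULL) {
  if (inherits(exposures, "sig_fit")) {
    signatures <- signatures %||% exposures$signatures
    exposures <- exposures$exposures
  }
  m <- as_signature_matrix(signatures)
  stopifnot(!is.null(names(exposures)), all(names(exposures) %in% colnames(m)))
  s <- exposures[exposures > 0]
  if (length(s) == 0) abort("no active signatures: all exposures are zero")
  stopifnot(all(context %in% rownames(m)))
  map(context, function(cc) {
    w <- s * m[cc, names(s)]
    den <- sum(w)
    if (den <= 0) {
      abort(sprintf("no active signature can produce context %s; attribution undefined", cc))
    }
    p <- w / den
    tibble(context = cc, signature = names(p), probability = unname(p),
           is_best = seq_along(p) == which.max(p))
  }) |> list_rbind()
}

#' Attribute driver mutations to signatures, with reliability gating
#'
#' Applies [attribute_mutation()] to a table of driver SNVs, restricted
#' to samples whose signature refit reconstructed the spectrum with
#' cosine at or above `min_cosine` (0.9), the gate for trustworthy
#' per-mutation attribution. Mutations whose best signature carries more
#' than `confident_prob` (0.5) of the probability are flagged confident.
#'
#' @param drivers Tibble with `sample` and either `context96` or
#'   `ref`/`alt`/`left`/`right`; an optional `mutation_id` column is
#'   carried through.
#' @param fits Cohort fit table from [fit_cohort()].
#' @param min_cosine Reconstruction-cosine gate (inclusive).
#' @param confident_prob Strict threshold for the confident flag.
#' @return Tibble, one row per retained driver: context, best signature
#'   and probability, the confident flag, and a `probabilities`
#'   list-column with the full attribution row.
#' @export
attribute_drivers <- function(drivers, fits, min_cosine = 0.9, confident_prob = 0.5) {
  if (!"context96" %in% names(drivers)) {
    drivers <- drivers |>
      mutate(context96 = classify_context(.data$ref, .data$alt, .data$left, .data$right))
  }
  if (!"mutation_id" %in% names(drivers)) {
    drivers <- drivers |> mutate(mutation_id = paste0(.data$sample, "_m", row_number()))
  }
  keep <- fits |> filter(!is.na(.data$cosine), .data$cosine >= min_cosine)
  drivers |>
    inner_join(keep |> select("sample", "fit", "cosine"), by = "sample") |>
    group_by(.data$sample, .data$mutation_id, .data$context96, .data$cosine) |>
    group_modify(function(df, key) {
      at <- attribute_mutation(key$context96, df$fit[[1]])
      best <- at[at$is_best, ][1, ]
      tibble(best_signature = best$signature, best_probability = best$probability,
             confident = best$probability > confident_prob,
             probabilities = list(at))
    }) |>
    ungroup() |>
    rename(context = "context96")
}

#' Signature activity proportions per sample
#'
#' @param fits Cohort fit table from [fit_cohort()], or a single
#'   `sig_fit`.
#' @return Long tibble `sample`, `signature`, `proportion` (summing to 1
#'   per sample with any SNVs).
#' @export
signature_proportions <- function(fits) {
  tbl <- if (inherits(fits, "sig_fit")) tidy(fits) else cohort_exposures(fits)
  tbl |> select("sample", "signature", "proportion")
}
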