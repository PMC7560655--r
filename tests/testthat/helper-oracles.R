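# Independent oracles and fixture builders shared across test files.

# Two-sided Fisher exact p by direct enumeration of the hypergeometric
# distribution over all tables with the observed margins (sum of the
# probabilities of tables at most as probable as the observed one).
fisher_enumeration_p <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10; c1 <- n11 + n01; n <- n11 + n10 + n01 + n00
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(n11, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo oracle for per-mutation attribution: simulate n mutations
# signature-then-context and return, among those landing at context cc,
# the fraction generated by each signature plus its standard error.
mc_attribution <- function(exposures, signatures, cc, n = 1e6) {
  w <- exposures / sum(exposures)
  n_k <- as.vector(rmultinom(1, n, w))
  hits <- rbinom(length(n_k), n_k, signatures[cc, names(exposures)])
  total <- sum(hits)
  list(prob = hits / total, se = sqrt(pmax(hits / total * (1 - hits / total), 1e-12) / total),
       n_at_context = total)
}

# flat single-sample profile over a genome spec
uniform_profile <- function(spec, copy = 2, sample_id = "U1", loh = FALSE) {
  tibble::tibble(sample = sample_id, chrom = spec$chrom, start = 1,
                 end = spec$length, copy = copy, loh = loh)
}

# multinomial draw of a spectrum from a signature mixture, as named counts
sample_spectrum <- function(exposures, signatures, n = sum(exposures)) {
  probs <- as.vector(signatures[, names(exposures)] %*% (exposures / sum(exposures)))
  stats::setNames(as.vector(rmultinom(1, n, probs)), rownames(signatures))
}

# tiny two-signature matrix with chosen probabilities at one class and the
# remaining mass spread evenly over the other 95 classes
two_sig_matrix <- function(cc, p1, p2, names = c("sigA", "sigB")) {
  classes <- oncocohort::sbs96_classes()
  m <- cbind(rep((1 - p1) / 95, 96), rep((1 - p2) / 95, 96))
  rownames(m) <- classes
  m[cc, ] <- c(p1, p2)
  colnames(m) <- names
  m
}
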