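---
title: "Models and methods behind oncocohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oncocohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncocohort)
library(dplyr)
```

oncocohort implements a set of rule-based cohort genomics analyses for
pediatric solid tumors — neuroblastoma-style whole-genome data in
particular — together with a synthetic cohort generator that provides
ground truth for every stage. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
tests do and do not establish about real data.

## Segmental copy-number calling

Profiles are absolute-scale segment tables (2.0 = diploid). The caller
asks, arm by arm, whether the *terminal* part of the arm is gained or
lost relative to the rest of the genome:

* The copy level is sampled on a 250 kb grid over the terminal 30 Mb of
  the arm (the whole arm when shorter than 30 Mb; 20 Mb for acrocentric
  q arms, configurable 15–25 Mb, since their informative portion is
  short). The grid is anchored at the telomeric end so the terminus is
  always sampled.
* **Gain**: window grid median ≥ 2.3 *and* opposing-arm grid median at
  least 0.3 copies below the window median.
* **Loss**: window median at least 0.3 below the sample's median copy
  value *and* opposing-arm median at least 0.3 above the window median.

The opposing-arm (control) requirement is what separates *segmental*
alterations from whole-chromosome events: a uniformly trisomic
chromosome fails the control contrast on both arms. The sample median
copy used by the loss rule is the median over all autosomal grid points,
which is equivalent to length weighting because the grid is uniform.
The 11q13.3 gain is a special case: the queried window is chromosome 11
at 68.5–69.5 Mb (GRCh37), and because such gains often extend into 11p,
the control is the terminal 30 Mb of 11q rather than the p arm.

Whole-chromosome gains use a separate rule: an arm is gained when at
least 80% of its grid points sit at or above 2.25; a chromosome is
gained when both arms qualify; nine or more gained chromosomes place the
sample in the hyperdiploid "9+ WC" class. Focal amplification is a
strict log2 fold change above 2.0 over diploid germline, i.e. more than
8 absolute copies.

Because every median is computed from grid lookups into the containing
segment, calls are exactly invariant to subdividing segments, and
raising copy inside a called gain (or deepening a called loss) can never
revoke the call — both properties are enforced in the test suite.

### Recentering

Real pipelines center profiles manually by inspection; oncocohort
automates this. Presumed-diploid regions are those at the *lowest
substantial non-LOH copy level*: non-LOH segment copies are rounded to
0.1, weighted by length, bins below 5% of the non-LOH genome are
discarded as noise, adjacent surviving bins are merged into runs, and
the weighted peak of the lowest run becomes the baseline shifted to 2.0.
The lowest level — not the modal one — is the right anchor because in
hyperdiploid genomes the gained state can dominate the genome by
length; the LOH exclusion reflects that once a profile is shifted, the
presumed haploid and triploid levels obligately carry LOH. The applied
offset is returned for audit, and recentering is idempotent.

## Mutational signature refitting and attribution

SNVs are classified into the 96 trinucleotide classes on the pyrimidine
strand. Per-sample spectra are decomposed on a user-supplied signature
matrix (COSMIC v3 layout) by non-negative least squares, followed by
greedy backward elimination: the non-forced signature whose removal
costs the least reconstruction cosine is dropped while the cost stays
below 0.01. This sparsification approximates the inclusion rules of
single-sample refitting tools whose exact heuristics are proprietary;
numeric parity with any particular tool is not promised — only the
recovery properties demonstrated on synthetic mixtures. Signatures 1, 3
and 5 are forced by default, being ubiquitous or flat processes that
are real but easily starved by sparsity rules. Exposures are rescaled
to sum exactly to the sample's SNV count, and the reconstruction cosine
gates downstream use: per-mutation attribution requires cosine ≥ 0.9.

The probability that signature $i$ caused a mutation at context $c$ in
a sample with exposures $s$ is

$$P(i \mid m) = \frac{s_i \, P_{c,i}}{\sum_k s_k \, P_{c,k}},$$

the share of the expected mutation count at that context contributed by
signature $i$, with the sum running over the signatures detected in the
sample (positive exposure after refitting). A context that no active
signature can produce raises an explicit error rather than a silent
NaN. The implementation is checked against a generative Monte-Carlo
oracle (simulate mutations signature-then-context; condition on the
context) within three standard errors.

The bundled `example_signatures()` are deliberately synthetic: stylised
shapes (clock-like C>T at CpG, flat, C>A-dominated with a T[C>A]A peak,
platinum-like) built from explicit weight rules so that tests need no
external download. Analyses of real data should supply published
signature definitions via `read_signature_matrix()`.

## Purity-adjusted VAF model and copy-gain timing

For a clonal mutation on $m$ of $T$ tumor copies at purity $\rho$ with
diploid normal admixture,

$$\mathrm{E[VAF]} = \frac{m\rho}{T\rho + 2(1-\rho)}.$$

The exact mixture denominator is used rather than literal proportional
scaling; the two agree at $\rho = 1$, where all the model's landmark
values live (1 of 3 → 0.33, 2 of 3 → 0.67). The midpoint of the two
expected VAFs is the single- vs multi-allele cutoff (0.5 at full
purity), with the single-allele side inclusive.

Timing rests on 3-copy regions — the most frequent gain level and the
one with the fewest allelic configurations. Pre-gain mutations sit on
the later-duplicated chromosome with probability 1/2 (equal per-allele
rates), so if a fraction $p$ of a region's mutations predate the gain,
the expected single-allele fraction is $f = 1 - p/2$: 0.5 immediately
after the duplication, 0.75 at equal pre/post molecular time (time
measured in mutation counts). The inverse map $\hat p = 2(1-f)$,
clipped to $[0,1]$, estimates the molecular-time split; observed
$f < 0.5$ violates the model and is clipped with a warning. A sample is
timing-eligible with purity ≥ 0.70 and ≥ 20 mutations in autosomal
3-copy regions, and its gain is called early when $f$ strictly exceeds
0.75. Clonality generalises the diploid VAF > 0.4 rule: a mutation is
clonal when its VAF exceeds 0.8 × the expected VAF of a
heterozygous-equivalent mutation ($m = \lfloor T/2 \rfloor$, at least
1) at the local copy state; the 0.8 factor is configurable because
printed relapse cases show tolerance below it.

## SV linkage and independence-aware co-occurrence

Copy alterations and translocations are non-independent when a
structural variant joins them directly (one breakpoint within 5 kb of
each event's boundary, inclusive) or when a chain of SVs connects them
with consecutive same-chromosome breakpoints at most 15 Mb apart
(inclusive). Linkage is implemented as connectivity in a graph whose
nodes are SV breakpoints and alteration identifiers; chains of any
depth therefore link transitively, which reads the rule's chain
description as path semantics. Point mutations are never nodes: SNVs
and indels are always independent of everything.

Pairwise mutual-exclusivity/co-occurrence testing drops alterations
seen in fewer than five samples (no power), excludes relapse samples by
default, and — the key step — removes from each pair's 2×2 table every
sample in which the pair co-occurs *and* is SV-linked, so that a single
rearrangement event cannot masquerade as biological co-occurrence.
Two-sided Fisher's exact tests are used throughout, with direction read
from the odds ratio; degenerate tables return p = 1 with a flag. The
age-group prevalence test is a single exact test on the group ×
status table (2×3 by default), with pairwise 2×2 tests emitted for
transparency. Bonferroni control is plain `alpha / n_tests`.

Age groups follow the clinical convention: A below 1.5 years, B from
1.5 to 5 years, C above 5. Both boundaries are assigned to group B;
the handling of exactly 5.0 years is ambiguous in common usage, so the
boundary is centralised in `assign_age_group()` where it can be
audited.

## The synthetic cohort generator

The generator exists so every caller can be tested against known truth
without controlled-access patient data. Per sample it draws an age
group (weights 0.30/0.47/0.23 for A/B/C, matching a large diagnosis
cohort's composition), an age uniform within the group, purity uniform
on 0.5–0.95 (so roughly half the cohort passes the 70% timing filter,
as in real cohorts), alteration statuses from age-dependent
prevalences, signature exposures uniform within configured ranges, and
then realises these as segment profiles (Gaussian per-segment noise, sd
0.05 by default), SNV catalogs (contexts from the generating
signature's spectrum, positions uniform, read counts binomial at 80×
depth around the purity-adjusted expected VAF), and SVs (a hotspot
t(11;17) joined to the ends of co-occurring 11q13.3 and 17q gains,
making the trio non-independent). The default prevalence table is a
stylised rendering of the known landscape — MYCN amplification and
hyperdiploidy concentrated in infants, ATRX and TERT alterations in
older children, 17q gain common throughout.

Choices the data do not dictate, made once and documented here: copy
noise is Gaussian per segment because no generative noise model is
published for absolute copy levels (real studies center real calls);
mutation positions are uniform because positional rate variation is
irrelevant to the callers under test; the pre-gain multiplicity draw is
Bernoulli(1/2) per mutation, the equal-rate assumption of the timing
model; 80× depth is typical of tumor whole genomes sequenced for
somatic analysis; a single global seed drives per-sample substreams so
growing a cohort never perturbs earlier samples.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: subclonal population structure beyond
the single pre/post-gain split, indels and structural-variant read
evidence, germline variation, positional mutation-rate variation
(replication timing, chromatin), wavy GC-driven coverage artefacts, and
purity estimation itself (purity is consumed as truth or as a user
column, never re-derived).

## Numerical and statistical notes

* Grid medians use `stats::median` on segment lookups; NA grid points
  (coverage gaps) are excluded, and loaders fill gaps at the sample
  median so they normally never occur.
* All distance thresholds (5 kb, 15 Mb) and the 0.9 cosine gate are
  inclusive; the focal-amplification fold change and the 0.75
  early-gain threshold are strict, following each rule's wording.
* Fisher's exact test is discrete and therefore conservative: under
  null cohorts of 182 samples with 30% alteration prevalence the
  achieved size at nominal 0.05 is about 0.035–0.04. The calibration
  suite asserts the 0.03–0.07 band.
* The test suite sizes its simulations to run on one CPU in a few
  minutes: 200+ simulated arms for caller sensitivity/specificity, 20
  attribution instances against a 10^6-draw Monte-Carlo oracle, 1000
  null Fisher pairs, and a 60-sample end-to-end cohort. These sizes
  give comfortable statistical margins for the properties asserted
  while staying desk-scale.

## Known limitations

The caller queries fixed terminal windows and will miss interstitial
segmental events that spare the terminus; the acrocentric window length
is a single configurable default rather than per-chromosome values;
sparsification parity with any specific single-sample refitting tool is
not claimed; timing covers only 3-copy regions; and sex chromosomes are
out of scope throughout.
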