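---
title: "Models and methods behind bcrclonality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bcrclonality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrclonality)
options(bcrclonality.quiet = TRUE)
```

This vignette documents the statistical models, conventions and design
choices the package implements, in the spirit of a methods section: what is
computed, under which assumptions, and where a convention had to be fixed
because the field admits more than one.

## Clonotypes, dominance and impact

A *clonotype* is the triple (V gene, J gene, CDR3 amino-acid sequence),
with allele suffixes (`*01`) stripped from the gene calls. Aggregating
UMI-corrected sequence records by this key gives each clone an abundance
`u_i` and a relative frequency `f_i = u_i / Σ u` over the sample's total
UMI count. Defining clones on the amino-acid CDR3 merges synonymous
nucleotide variants (which are retained as `;`-joined variants); a
nucleotide-level definition is available via `call_clones(key = "nt")`
for analyses that need it.

A clone is **dominant** (a highly expanded clone) when `f_i ≥ 0.005`. The
comparison is inclusive — a clone at exactly 0.5% is dominant — and is made
on the exact integer ratio `u_i / Σ u` as represented in double precision,
with no epsilon. The per-sample **impact** is the cumulative frequency of
dominant clones; a sample with no dominant clone has impact 0, and such
samples are kept in clinical analyses by default
(`run_association_suite(include_no_hec = FALSE)` drops them instead, since
it is ambiguous whether a cohort study would include them).

## Diversity, mutation load and CDR3 profiles

Diversity summaries of more than one convention circulate in the repertoire
literature, so the package fixes and documents one set:

* **Simpson's index** is the concentration form `Σ f_i²` (1 = monoclonal,
  1/n = uniform); `variant = "gini_simpson"` gives `1 − Σ f_i²`.
* **Shannon entropy** is `−Σ f_i ln f_i` in nats (`base = 2` for bits),
  with `0 · ln 0 := 0`.
* **Gini index** uses the Lorenz-curve formulation on clone frequencies,
  computed by the sorted O(n log n) identity and verified in the tests
  against the O(n²) pairwise-difference definition. No small-sample
  correction is applied.

**Mutation load** is somatic mismatches versus germline V per aligned V
base pair. A clone's rate is the UMI-weighted mean over its member records
(weighting molecules rather than distinct sequences), and a sample's mean
is again UMI-weighted; clones lacking mutation data are excluded and
counted.

**CDR3 net charge** uses the integer count model at neutral pH,
`#(R, K) − #(D, E)` with histidine ignored — the simplest reproducible
convention. Length and charge distributions are clone-frequency weighted.
V/J usage tables are normalised per sample under either clone weighting
(each clonotype once) or UMI weighting.

## Overlap, turnover and cross-patient sharing

Clone sharing between two samples is exact equality of the clonotype key;
near-match relationships are deliberately left to the Hamming-clustering
layer, so the two notions stay distinguishable. Turnover between baseline
and follow-up classifies each dominant clone as *persisting* (dominant at
both timepoints), *lost* (dominant at baseline only — reported separately
as absent versus present-but-subthreshold, because disappearance of
dominance and disappearance of the clone are different claims), or *new*
(dominant at follow-up only), with a key-level test of whether each new
dominant clone pre-existed at any frequency. These satisfy
`persisting + lost = n_dominant(baseline)` and
`persisting + new = n_dominant(follow-up)` by construction, which the test
suite asserts. Cross-patient sharing counts dominant keys common to patient
pairs; with CDR3 diversity as high as it is, any non-zero off-diagonal
entry warrants inspection.

## CDR3 Hamming clustering and the dynamic threshold

The normalised Hamming distance (mismatches / length) is defined only for
equal-length sequences; unequal lengths are incomparable and never linked.
Clustering is single-linkage: connected components of the graph joining
comparable clones at distance ≤ threshold, the simplest deterministic
reading of "grouping related clones". Two comparability modes exist:
`"cdr3"` (equal length only; the default for cluster analyses, since
relatedness of interest may cross V/J assignment) and `"stratified"`
(identical V gene, J gene and length — standard clonal-grouping practice,
and the mode used when *estimating* the threshold, where within-stratum
distances are the meaningful signal).

The **dynamic threshold** pools each clone's nearest-neighbour distance
within V/J/length strata. In repertoires containing clonally related
expansions this distribution is bimodal: a low mode from hypermutation
variants and a high mode from unrelated sequences. The density is smoothed
with a fixed-bandwidth (0.02) Gaussian kernel on [0, 1]; the threshold is
the density minimum between the outermost modes, ignoring local maxima
below 5% of the peak (numerical ripple). With fewer than 20 usable
distances, or no interior valley (unimodal pools, e.g. all-identical
clones), the configured fallback of 0.15 is returned and flagged. The
valley rule is one of several published bimodality heuristics; it is
deliberately simple, and `select_threshold()` is exposed so an alternative
rule can be swapped in.

## Clinical statistics

The statistical layer mirrors standard practice for small exploratory
cohorts:

* Normality gating uses the **D'Agostino–Pearson omnibus K²** (skewness z
  after D'Agostino 1970, kurtosis z after Anscombe–Glynn 1983,
  `K² = z_s² + z_k² ~ χ²(2)`), implemented in the package and verified
  against an independent reference implementation on frozen fixtures.
  Samples with n < 8 (below the test's validity range) or zero variance
  are classified non-normal. The gate returns mean (SD) for normal data
  and median (IQR) otherwise.
* Group comparisons are two-sided **Mann–Whitney** (exact for small
  tie-free samples via `stats::wilcox.test`, normal approximation with tie
  correction otherwise) or **Kruskal–Wallis** for ≥3 groups.
* Correlations are **Spearman's rho** with average ranks for ties; the 95%
  CI uses the Fisher z transform with variance `1.06/(n − 3)`, a standard
  approximation for rank correlations (the interval always contains the
  point estimate, as tanh is monotone).
* **Responders** are patients with TIS ≥ 40 (inclusive).
* The association panel (baseline impact and dominant count vs CK and MMT;
  week-9-minus-baseline deltas vs TIS and ΔMMT; responder comparisons at
  both timepoints; antibody-class subgroups — 14 tests) reports
  **unadjusted** p-values at α = 0.05, as is conventional for exploratory
  panels; `glance()` reports the number of tests so users can apply their
  own multiplicity correction. Degenerate panel entries (a constant
  metric, an empty group) yield an NA row with a note rather than aborting
  the panel.

Delta conventions: impact and dominant-count deltas are week 9 minus
baseline; MMT delta is follow-up minus baseline. An *improvement* under
treatment therefore appears as a **negative** correlation between the
impact delta and ΔMMT or TIS — "impact decrease tracks clinical gain".

## The synthetic cohort generator

`generate_cohort()` emulates the study design end to end so that every
stage has an input with known ground truth. Defaults describe a 19-patient
cohort; each patient contributes muscle + blood at baseline and blood at
week 9.

* **Clone sizes** follow a discrete power law with survival exponent 1.5
  (`P(S ≥ x) ~ x^{−1.5}`, the Hill-estimable tail exponent), winsorised so
  the largest clone stays below a per-sample clonality cap drawn from
  0.012–0.10 for samples designated to carry dominant clones. Samples are
  scaled to ≥2×10⁴ UMIs before winsorisation so integer caps resolve well
  below the dominance threshold. Five of 19 blood baselines are designated
  HEC-free and capped below 0.5%; designated HEC-positive samples are
  guaranteed at least one (muscle: two) dominant clone.
* **CDR3s** are random in-frame amino-acid strings (`C…W`, lengths
  normal around 15, truncated to 8–28) with consistent random nucleotide
  sequences (3× length); ~10% of clones are split into two records with
  distinct nucleotide variants to exercise aggregation.
* **Sharing**: 10% of blood-baseline clones take their identities from the
  patient's muscle clones, always landing in subthreshold slots — except
  in three designated patients, where one muscle-dominant identity is
  planted into a blood-dominant slot, so dominant-in-both sharing occurs
  exactly where planted.
* **Turnover**: each baseline-dominant blood clone independently stays
  dominant at week 9 with probability 0.05 (planted into a week-9 dominant
  slot and kept above threshold) or is lost (half of lost clones persist
  below threshold, half disappear). The per-clone Bernoulli bookkeeping is
  recorded in the truth ledger, which is what makes exact parameter
  recovery testable. With ~20–40 dominant clones per sample, some patients
  end up with at least one persisting dominant clone even at 95% turnover —
  patient-level persistence is an emergent consequence of per-clone
  turnover, not a separate dial.
* **Mutation load**: per-clone rates are Gamma-distributed around 0.05
  mutations/bp in muscle versus 0.02 in blood, reflecting matured
  tissue-infiltrating B cells; counts are binomial over the aligned length
  (280–300 bp).
* **Clinical couplings** use a Gaussian copula on Blom normal scores of
  the repertoire statistics: CK is log-normal (median ≈ 1199 U/L, a
  realistic scale for active myositis) with latent correlation 0.5 to
  baseline impact; TIS is scaled so roughly 42% of patients cross the
  response cutoff, with latent correlation 0.85 to baseline impact — a
  value chosen once to give a clear responder/non-responder separation on
  impact, consistent with a significant two-group difference at n = 19 —
  and −0.35 to the impact delta; ΔMMT couples to the impact delta at −0.5.
  `generate_null_cohort()` zeroes all four couplings and changes nothing
  else, providing the null model for type-I-error checks.

What the generator does **not** emulate: real V(D)J recombination biology
(CDR3s are uniform random strings, so sequence-composition analyses see no
germline signal), sequencing error, isotypes, and clonal lineage structure
within clones. Passing tests therefore demonstrate that the pipeline's
bookkeeping, statistics and thresholds behave correctly — not that any
biological conclusion generalises to real repertoires.

## Problem sizes and numerical choices

The test suite runs the oracle comparisons at 1,000 random repertoires (up
to 10⁴ clones) for dominant-clone calling, 200 random instances (n ≤ 200)
against a brute-force union-find for clustering, 200 simulated pools for
threshold selection, 300 simulated patients for turnover recovery, and 500
synthetic cohorts each for the type-I-error and sign-recovery studies —
sizes chosen to give stable Monte-Carlo estimates on a desktop machine.
At the default coupling of 0.5 and n = 19, the two-sided Spearman test has
roughly 50–60% power, so coupling recovery is assessed as sign recovery
across cohorts (≈98% expected), with significance rates reported
descriptively; this matches what a single 19-patient study can and cannot
establish.

Ties in impact (samples at 0) are handled by average ranks in Spearman and
the tie-corrected normal approximation in Mann–Whitney. Cluster numbering
is deterministic (by largest member frequency, then lexicographic key), as
is every pipeline output for a fixed seed: reruns are byte-identical.

## Known limitations

* The clonotype definition cannot distinguish convergent recombination
  from true clonal identity across compartments; exact-key sharing is an
  upper bound on clonal overlap at the chosen resolution.
* The dynamic-threshold valley rule assumes a reasonably separated bimodal
  nearest-neighbour distribution; repertoires with little clonal
  relatedness fall back to a fixed 0.15, which is reported but arbitrary.
* The Fisher-z CI for Spearman's rho and the χ² approximation in
  Kruskal–Wallis with very small subgroups are approximations; the null
  calibration of the full panel sits near, but measurably above, the
  nominal 5% (≈6% in simulation), driven by those approximations at
  n = 19.
* Impact is a within-sample relative quantity; comparing it across samples
  of very different sequencing depth inherits the usual compositional
  caveats.
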