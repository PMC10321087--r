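# bcrclonality

Analysis of UMI-corrected B-cell receptor (BcR) heavy-chain repertoires from
paired tissue and blood samples collected before and after treatment, built
for cohorts like treatment-naive myositis patients receiving IVIG: muscle and
peripheral-blood repertoires at baseline, blood again at week 9, and clinical
outcome measures (CK, MMT, TIS) per patient.

The package answers four questions about such cohorts:

1. **How clonal is each repertoire?** Sequence records are aggregated into
   clonotypes (V gene, J gene, CDR3 amino-acid sequence), and a clone is
   called *dominant* (a highly expanded clone, HEC) when its frequency
   `f_i = u_i / Σ u` of the sample's UMI-corrected reads is **≥ 0.5%**. The
   per-sample *impact* is the cumulative frequency of all dominant clones,
   `I = Σ_{f_i ≥ 0.005} f_i`.
2. **Do compartments and timepoints share clones?** Exact clonotype-key
   overlap between muscle and blood, dominant-clone turnover between baseline
   and week 9 (persisting / lost / new, with a key-level de novo test), and a
   cross-patient dominant-clone sharing matrix.
3. **Are week-9 clones related to anything at baseline?** CDR3 amino-acid
   Hamming clustering with a data-driven threshold: nearest-neighbour
   distances are pooled within V/J/length strata, their density smoothed, and
   the threshold placed at the valley between the clonally-related and
   unrelated modes (fallback 0.15).
4. **Does clonality track the clinic?** Per-sample summaries (impact,
   dominant counts, Simpson `Σf²`, Shannon `−Σf ln f`, Gini, mutations per
   aligned V base pair, CDR3 length/charge, V/J usage) joined to clinical
   records and tested nonparametrically: D'Agostino–Pearson normality gating,
   Mann–Whitney / Kruskal–Wallis comparisons, Spearman correlations with
   Fisher-z 95% CIs, responders defined by TIS ≥ 40.

A seeded synthetic-cohort generator (`generate_cohort()`) emulates the whole
study design — power-law clone sizes, a minority of blood samples without
dominant clones, partial muscle↔blood sharing, 95% dominant-clone turnover,
higher mutation load in muscle, V-gene bias, and configurable couplings
between baseline impact and CK / treatment response — and records every
planted truth in a ledger so each stage can be tested against known
parameters.

## Worked example

```r
library(bcrclonality)

co  <- generate_cohort(cohort_config(), seed = 1)   # 19 patients x 3 samples
cl  <- call_clones_all(co$sequences)                # clonotype tables
hec <- call_dominant(cl)                            # dominant clones + impact

dplyr::filter(hec, compartment == "blood", timepoint == "baseline") |>
  dplyr::count(has_hec = n_dominant > 0)
#> # A tibble: 2 x 2
#>   has_hec     n
#>   <lgl>   <int>
#> 1 FALSE       5
#> 2 TRUE       14
```

Fourteen of the 19 blood baselines carry dominant clones; five do not (their
impact is 0). The association panel relates clonality to outcome:

```r
suite <- run_association_suite(hec, co$clinical)
dplyr::filter(tidy(suite), pair == "impact_baseline~ck_baseline") |>
  dplyr::select(pair, n, rho, p_value)
#> # A tibble: 1 x 4
#>   pair                            n   rho p_value
#>   <chr>                       <int> <dbl>   <dbl>
#> 1 impact_baseline~ck_baseline    19 0.497  0.0303
```

A positive Spearman correlation between baseline dominant-clone impact in
blood and serum CK, here `rho = 0.50` at `p = 0.03` on 19 patients. Turnover
between the blood timepoints:

```r
blb <- dplyr::filter(cl, patient_id == "P03", compartment == "blood",
                     timepoint == "baseline")
blw <- dplyr::filter(cl, patient_id == "P03", compartment == "blood",
                     timepoint == "week9")
turnover(blb, blw)
#> <bcr_turnover> patient P03: 26/27 baseline dominant clones lost,
#>   1 persisting, 27 new (27 de novo)
```

`run_pipeline(run_config(seed = 1))` chains every stage and writes all stage
tables plus `run_summary.json` to an output directory; `autoplot()` methods
and `plot_*()` helpers draw the overlap scatters, paired impact lines and
diversity panels.

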