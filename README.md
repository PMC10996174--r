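# edgentropy

Early-warning detection of critical transitions in staged or time-course
gene-expression cohorts, scored on the *edges* of an interaction network.

Expression means often barely move until a disease has already tipped into
irreversible deterioration, which is why differential expression makes a
poor early-warning signal. Dynamic network biomarker theory predicts that
just before the transition a group of molecules begins to fluctuate
collectively. `edgentropy` quantifies that on gene pairs: every network
edge ⟨i, j⟩ in every case sample *k* gets a relative-entropy score built
from univariate Gaussian kernel density estimates,

    H_⟨j,i⟩ = Σ_m p_r(x_jm) · log( p_r(x_jm) / p_c(y_ik) )
    H^k(i,j) = ( H_⟨i,j⟩ + H_⟨j,i⟩ ) / 2

where `P_r` is gene *j*'s probability vector over the reference cohort,
`p_c(y_ik)` the case-cohort probability of gene *i*'s observed value in
sample *k*, and the KDE uses the plug-in bandwidth `h = (4σ⁵/(3N))^(1/5)`
evaluated only at observed points. Per sample, the mean over the top 5% of
edges gives `H^k`; per stage, `H(t)` is the mean over that stage's
samples. An interior stage whose `H^k` values sit significantly above the
mean of its neighbouring stage means (one-sample t-test, two-sided, plus a
direction requirement) is flagged as the critical stage. Edges whose
per-sample top-5% membership exceeds a strict 80% prevalence in the
long- (> 5 years) or short-survival group are called positive or negative
prognostic edge biomarkers.

The package is tidyverse-shaped: data frames in, tibbles out, with
`tidy()`, `glance()` and `autoplot()` methods on fitted objects, plus a
seeded synthetic-cohort generator so the whole pipeline is testable with
no external data, and a command-line interface.

## Worked example

```r
library(edgentropy)

sim <- simulate_cohorts(sim_config(seed = 1))   # planted critical stage 3
fit <- ere_fit(sim)                             # 24 edges x 150 case samples
report <- detect_critical(fit)
report
#> <ere_stage_report>
#>   critical stage: stage3 (alpha = 0.05, reference = neighbors)
#> # A tibble: 5 × 8
#>   stage    n_t   h_t reference_mean statistic    df   p_value critical
#>   <chr>  <int> <dbl>          <dbl>     <dbl> <dbl>     <dbl> <lgl>
#> 1 stage1    30  2.10          NA        NA       NA NA        FALSE
#> 2 stage2    30  2.05           2.43     -3.66    29  0.00100  FALSE
#> 3 stage3    30  2.76           2.07      4.37    29  0.000144 TRUE
#> 4 stage4    30  2.09           2.43     -3.77    29  0.000739 FALSE
#> 5 stage5    30  2.10          NA        NA       NA NA        FALSE
```

The third stage's mean edge entropy `H(t)` (2.76) sits far above the mean
of its neighbours (2.07; t = 4.37 on 29 df, p = 1.4e-4) *and* exceeds it,
so it is flagged; stages 2 and 4 have small p-values in the *wrong*
direction (their means sit below their references — the flanks of the
peak) and are correctly not flagged. Boundary stages are never tested.
`autoplot(report)` draws the `H(t)` series, `autoplot(fit)` the
edge-by-sample heatmap, and `tidy(fit)` the long score table.

Prognostic edge calling on a survival cohort with planted edges:

```r
base <- simulate_cohorts(sim_config(seed = 1, dispersion_factor = 1))
sv   <- simulate_survival(base, seed = 2)       # plants g05--g06 (+), g09--g10 (-)
fit_sv <- ere_fit(sv$expression, sv$metadata, sv$network, case_scope = "all")
dplyr::filter(classify_edges(fit_sv, sv$records), call != "none")
#> # A tibble: 2 × 8
#>   gene_a gene_b edge     call     prevalence_long prevalence_short n_long n_short
#>   <chr>  <chr>  <chr>    <chr>              <dbl>            <dbl>  <int>   <int>
#> 1 g05    g06    g05--g06 positive            0.88            0         75      75
#> 2 g09    g10    g09--g10 negative            0               0.907     75      75
```

The planted positive edge is in the top-5% set of 88% (> 80%, strict) of
long-survival patients and no short-survival patients — a positive edge
biomarker — and symmetrically for the negative edge.
`stratify_by_edge(fit_sv, "g05", "g06")` yields the median-split high/low
groups ready for `survival::survdiff()`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ere.R", package = "edgentropy"))')
Rscript $CLI simulate --out-dir demo --seed 11 --with-survival
Rscript $CLI run --expression demo/expression.tsv --metadata demo/metadata.tsv \
                 --network demo/network.tsv --out-dir demo
Rscript $CLI detect --local-ere demo/local_ere.tsv --out demo/stage_report.tsv
Rscript $CLI biomarkers --local-ere demo/local_ere.tsv \
                 --metadata demo/survival_metadata.tsv --out demo/calls.tsv
```

All artifacts are tab-separated text and byte-identical across runs at a
fixed seed.

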