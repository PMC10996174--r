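---
title: "Edge-based relative entropy: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-based relative entropy: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgentropy)
```

## The problem

Complex diseases often progress through three coarse states: a relatively
healthy before-transition state, a *critical* (pre-transition) state in
which the system is still reversible but sits close to a tipping point, and
an after-transition state of irreversible deterioration. Expression *means*
often barely move until after the transition, which is why differential
expression fails as an early-warning signal. Dynamic network biomarker
(DNB) theory predicts instead that, just before the transition, a specific
group of molecules starts to fluctuate collectively. This package measures
that phenomenon on the *edges* of an interaction network: each gene pair in
each case sample receives a relative-entropy score that is large when the
sample's expression of the paired genes is improbable under the case-cohort
density relative to the reference baseline.

## The score

For gene $g_i$, write $x_{i1},\dots,x_{im}$ for its expression in the $m$
reference samples and $y_{i1},\dots,y_{in}$ for the case samples. A
univariate Gaussian KDE with the plug-in bandwidth

$$h = \left(\frac{4\,\sigma^5}{3N}\right)^{1/5}$$

($\sigma$ the cohort's sample standard deviation, $N$ its size) is fitted
per gene per cohort and evaluated *only at the cohort's own observed
points*; normalizing those densities gives probability vectors $P_r$ (over
the reference points) and $P_c$ (over the case points). Densities are only
trusted where data were observed, which is why no off-sample grid is ever
evaluated.

For an edge $\langle i,j \rangle$ and case sample $k$, the directed score
contrasts gene $j$'s reference vector with the case probability of gene
$i$'s observed value:

$$H_{\langle j,i\rangle} = \sum_{m'} p_r(x_{jm'})
 \log\frac{p_r(x_{jm'})}{p_c(y_{ik})}
 = \sum_{m'} p_r \log p_r \; - \; \log p_c(y_{ik}),$$

and the per-edge, per-sample statistic is the symmetrized mean
$H^k(i,j) = \tfrac12 (H_{\langle i,j\rangle} + H_{\langle j,i\rangle})$.
Note the second argument of the "relative entropy" is a scalar probability,
not a distribution; the identity above shows the score decomposes into a
per-gene constant (the negative entropy of $P_r$) minus the log case
probability, so it is not a Kullback–Leibler divergence in the textbook
sense. We implement it literally in this decomposed form — it is exact, not
an approximation — and the decomposition is what the test suite checks
against.

Per sample, the top fraction (default 5%) of edges by score forms the
signaling set $S$ with $M = \max(1, \lfloor f E\rfloor)$ members, and
$H^k = \frac1M\sum_{\langle i,j\rangle\in S} H^k(i,j)$. Per stage,
$H(t)$ is the mean of $H^k$ over that stage's $N(t)$ samples. An interior
stage is flagged *critical* when a two-sided one-sample t-test of its
$H^k$ values against the mean of the two neighbouring stage means gives
$p < \alpha$ (default 0.05) *and* the stage mean exceeds that reference —
the signal of interest is an increase. Boundary stages are never tested:
the first stage is the natural baseline and the last is after-transition
territory. When several stages pass, the earliest is reported (early
warning is the point); all per-stage p-values are emitted and no
multiplicity correction is applied across stages.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `top_fraction` | 0.05 | fraction of edges in each sample's signaling set; smaller = sharper but noisier (top-1 at 24 edges) |
| `alpha` | 0.05 | per-stage significance level, raw p-values |
| `case_scope` | `"all"` | case cohort used to fit $P_c$ (see below) |
| `sigma_denominator` | `"n-1"` | SD convention in the bandwidth; the population form `"n"` is available |
| `prevalence_threshold` | 0.8 | strict ("over 80%") prevalence for biomarker calls |
| `cut_years` | 5 | survival cut separating long from short survival |

Natural logarithms are used throughout; any other base would rescale every
score by the same constant and change nothing downstream.

## Why the case cohort is pooled by default

A consequential and easily missed fact drove this choice: the normalized
KDE probability vector of a cohort, evaluated at the cohort's own points
with a variance-proportional bandwidth, is **exactly invariant under
location–scale transformations** of that cohort. Shifting every value, or
multiplying every value by a constant, scales the bandwidth and all
densities uniformly and cancels in the normalization. Two corollaries:

* adding a constant to a gene (e.g. a log-scale normalization offset)
  cannot change any score — a property the tests assert; and
* a stage whose module genes merely fluctuate *more* (a pure variance
  inflation of the whole stage cohort) is completely invisible to a
  per-stage fit of $P_c$, because variance is scale.

Fitting $P_c$ once on the pooled case cohort (`case_scope = "all"`)
restores exactly the sensitivity the method is meant to have: samples whose
expression is rare *across the case population* fall in the tails of the
pooled density, get a small $p_c$, and a large score. Stage signals
$H(t)$ remain stage-specific because each stage contributes its own
samples. The per-stage scope is kept as an option for sensitivity analysis;
on data where each stage is a separately normalized batch, it may be
preferable despite the blindness above.

## What the synthetic generator emulates

`simulate_cohorts()` draws every gene i.i.d. Gaussian (mean 8, sd 1 —
log-intensity-like units) for the reference cohort (default 50 samples) and
each of 5 case stages (30 samples each). At the planted critical stage
(the third), each sample is independently *excited* with probability 0.7;
excited samples draw the 4-gene module (`dnb_genes`, ring neighbours, so
the module induces network edges) with sd $\kappa = 4$. The sample-level
mixture is deliberate: exciting *every* stage sample equally would be a
pure scale change of the stage cohort — undetectable per-stage and only
weakly visible pooled — whereas a mixture puts excited samples in the tails
of the pooled case density, which is precisely the DNB picture of a
subpopulation fluctuating between basins near a tipping point. Stages after
the critical one add a mean shift of 3 to the module genes, emulating
after-transition differential expression; by translation invariance this
shift contributes no entropy signal, which is the methodologically honest
choice — the method is supposed to fire *before* the mean moves. With
$\kappa = 1$ the generator is an exact null.

Defaults were chosen once, as conditions a staged cancer cohort plausibly
resembles in miniature (a 16-gene subnetwork, a handful of stages, tens of
samples per stage), and the detection claims in the test suite are made
under exactly these conditions: the planted stage is recovered as *the*
critical stage in well over 90% of seeded runs, and under the null the
flag rate is consistent with $\alpha$ times the number of tested stages.

`simulate_survival()` builds a separate prognostic fixture: case samples
are split into long- (> 5 years) and short-survival (≤ 5 years, death
observed) halves; each long-survival sample, with probability 0.95, gets an
isolated outlier at *both* endpoint genes of the planted positive edge
(magnitude uniform in $(8, 40)\sigma$, random sign — a wide scatter rather
than a common offset, which would just create a second density mode), and
symmetrically for the negative edge in short-survival samples. Two
numerical facts shaped this fixture. First, the planted density deficit
saturates: the plug-in bandwidth grows with the outlier span, so
$-\log p_c$ gains at most $\approx 2$ nats no matter how extreme the
outliers. Second, a *Gaussian* cohort's own extreme samples are nearly as
rare under a small plug-in bandwidth as planted outliers are under an
inflated one, so with Gaussian case noise a sample's top edge is as often
an ordinary tail event as the planted edge. The fixture therefore draws the
case samples' non-planted expression from a compact-support uniform
distribution (±2 sd), which has no deep KDE self-tails, making the planted
edges the only systematic low-density structure. This is a property of the
fixture, not of the method: it isolates the prognostic-calling logic from
sampling-noise membership, which real cohorts will of course contain.

## What passing tests do and do not show

The generator emulates dispersion-driven, network-localized pre-transition
fluctuation with clean Gaussian/uniform noise, exact stage labels, a known
reference cohort and a correct network. It does not emulate batch effects,
stage-label noise, network errors, heavy-tailed biological noise,
correlated baseline co-expression, or censoring-time structure beyond the
5-year rule. Recovery of the planted truth therefore validates the
machinery (scores, aggregation, testing, calling) — not performance on any
real cohort.

## Numerical choices and degenerate inputs

* Probabilities are floored at $10^{-300}$ before logs; floored entries
  are counted and reported on the fit (`n_clipped`).
* A gene with zero variance in any cohort in scope has no KDE profile;
  the gene and its incident edges are dropped with a warning. Stages (or a
  pooled case cohort) with fewer than two samples are rejected.
* Ties at the top-fraction cutoff are broken by canonical (lexicographic)
  edge order, making every top set — and hence every downstream number —
  deterministic.
* A tested stage whose $H^k$ values have zero variance gets $p = 0$ if its
  mean differs from the reference (else $p = 1$), with a warning.
* Duplicate expression values within a cohort are fine (density
  accumulates); only an all-identical cohort is degenerate.
* The bandwidth uses the $N-1$ sample standard deviation by default; the
  convention is configurable because published descriptions of plug-in
  rules are often silent on it, and the difference vanishes as $N$ grows.
* Patient stratification for survival curves splits at the median of the
  edge's scores, ties to the low group; Kaplan–Meier and log-rank
  computations are delegated to the `survival` package.
* Edges above the prevalence threshold in both survival groups are called
  `"none"`: their prognostic direction is ambiguous, and both prevalences
  are reported so the caller can inspect them.

## Problem sizes used by the test suite

Simulation-based checks run the full pipeline at the default configuration
(16 genes, 24 edges, 50 reference + 150 case samples) across 100 seeds for
detection power, 100 seeds for the null flag rate, and 100 seeds for
prognostic-edge recovery; oracle checks sweep cohort sizes 2–200. These
sizes were chosen so that the whole suite documents the method's
behaviour in minutes on a laptop while keeping every claim a measured one.

## Known limitations

* The score is built from two univariate marginals; it never sees the
  joint distribution of an edge's endpoints, so a correlation change with
  unchanged marginals is invisible by construction.
* A reference cohort is required; the method cannot score a lone case
  sample against nothing.
* Location–scale invariance (see above) means uniform per-gene variance
  changes across the whole case cohort carry no signal; only
  subpopulation-level or shape changes do.
* Raw per-stage p-values with an earliest-flag rule favour sensitivity
  over specificity; on long stage series a correction may be warranted.
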