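---
title: "Measuring reliability of risk-of-bias assessments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring reliability of risk-of-bias assessments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robkappa)
```

## The problem

Systematic reviews rate each randomized trial on a set of bias domains —
sequence generation, allocation concealment, blinding of patients /
therapists / outcome assessors, and incomplete outcome data — as *low*,
*unclear*, or *high* risk of bias. These judgements feed directly into
evidence grading, so their reliability matters: if two rater pairs reach
different conclusions about the same trial, downstream decisions differ
too. A typical reliability study has two inexperienced rater pairs (one
per training arm) and one experienced reference pair assess the same
trials; each pair resolves internal disagreements by discussion to a
consensus. Two designs are then of interest:

* **between-group reliability** (primary): agreement of each
  inexperienced pair's *consensus* with the reference pair's consensus;
* **within-group reliability** (secondary): agreement of the two
  *individual* raters inside each inexperienced pair, before consensus.

`robkappa` implements the full analysis — the agreement statistic,
bootstrap inference on group differences, stratified interaction tests —
plus a generative model of such a study so every stage can be validated
against known truth.

## The agreement statistic

For a 3×3 contingency table of counts $f_{ij}$ over $n$ trials, with
marginal totals $r_i$ (rows) and $c_j$ (columns), the chance-corrected
weighted kappa is

$$\kappa_w = \frac{p_{obs} - p_{exp}}{1 - p_{exp}}, \qquad
p_{obs} = \frac{1}{n}\sum_{ij} w_{ij} f_{ij}, \qquad
p_{exp} = \frac{1}{n^2}\sum_{ij} w_{ij} r_i c_j.$$

The default weight scheme treats the ordinal scale low < unclear < high
with *agreement weights*: $w_{ii} = 1$, $w_{ij} = 0.8$ for adjacent
categories, and $w_{ij} = 0$ for low-vs-high. (The printed scheme
1/0.8/0 reads naturally as agreement weights, which is how it is applied
here; disagreement-weight conventions would invert it.) Identity, linear,
quadratic, and custom schemes are available through
`weight_matrix()` for sensitivity analyses; with identity weights
$\kappa_w$ reduces exactly to unweighted Cohen's kappa, which the test
suite verifies against an independent closed-form oracle.

When both raters place every trial in one identical category,
$p_{exp} = 1$ and the statistic is undefined. `robkappa` flags this
**not estimable** ("NE") whenever $1 - p_{exp} < 10^{-12}$; the
tolerance is deliberately tight because the degeneracy arises from exact
arithmetic (all mass in one matched cell), not from rounding. NE
propagates through bootstrap results and report files as the literal
`NE`, never as a forced number.

Estimates are classified into interpretation bands
(≥ 0.93 excellent; 0.81–0.92 very good; 0.61–0.80 good; 0.41–0.60 fair;
0.21–0.40 slight; 0.01–0.20 poor; ≤ 0 none). The bands are contiguous
only at two-decimal resolution, so `classify_kappa()` rounds the
estimate to two decimals before classifying (0.809 → 0.81 → very good);
this makes the classification a total, non-overlapping partition of
$[-1, 1]$.

## Bootstrap inference

All uncertainty statements come from a nonparametric bootstrap with the
**trial as the resampling unit** — rating pairs are resampled intact, so
the dependence between raters is preserved. Intervals are
bias-corrected and accelerated (BCa): with $B$ replicates
$\theta^*$, point estimate $\hat\theta$, and leave-one-trial-out
jackknife values $\theta_i$,

$$z_0 = \Phi^{-1}\!\left[\frac{\#\{\theta^* < \hat\theta\} +
\tfrac12\#\{\theta^* = \hat\theta\}}{B}\right], \qquad
a = \frac{\sum_i (\bar\theta - \theta_i)^3}
         {6\left[\sum_i (\bar\theta - \theta_i)^2\right]^{3/2}},$$

and the interval endpoints are the empirical quantiles of $\theta^*$ at
the adjusted levels $\Phi\!\left(z_0 + \frac{z_0 + z_{\alpha/2}}{1 -
a(z_0 + z_{\alpha/2})}\right)$ (lower) and the mirrored upper form.
Replicates tied with $\hat\theta$ count half in $z_0$, which keeps the
correction finite when many replicates coincide with the estimate; a
fully constant replicate stream returns the degenerate interval
$(\hat\theta, \hat\theta)$ with a flag, and zero jackknife variance sets
$a = 0$ with a flag. When $z_0 = a = 0$ the endpoints coincide exactly
with simple percentile endpoints — an identity the tests exploit as an
oracle.

Design choices the analysis depends on, none of which follow from the
statistic itself:

* **B = 2000 replicates** by default: tail quantiles (and hence inverted
  p-values) are stable at roughly the third decimal, matching the
  precision at which such studies report p-values.
* **Differences in kappa** ($\Delta\kappa = \kappa_A - \kappa_B$,
  always oriented intensive − minimal so positive values favor
  standardized training) use a *paired* bootstrap: one resample of trial
  indices per replicate, applied to both comparisons.
* **Two-sided p-values by interval inversion**: the p-value is the
  smallest $\alpha$ at which the $(1-\alpha)$ BCa interval excludes 0,
  found by bisection on $\alpha \in (1/B, 1)$ to tolerance $1/B$. This
  keeps CI and p-value mutually consistent by construction (the interval
  excludes 0 iff $p < \alpha$, up to bisection tolerance), which the
  suite checks as a property.
* **Stratified interaction tests** (publication before/after the
  CONSORT 2010 statement; fewer than 50 vs at least 50 patients
  randomized per trial arm) resample trials within their own stratum
  level; the interaction statistic
  $\Delta\kappa_{level_1} - \Delta\kappa_{level_2}$ is computed on the
  same replicate for both levels. The trial-size stratifier uses the
  *smallest* arm, the conservative reading of "per trial arm".
* **NE replicates are dropped, not imputed**, with a logged count. If
  more than half the replicates (or all but fewer than 100) are NE, the
  whole result is reported NE rather than forced to a number.

## The synthetic-study generator

Because rater-level data from real reliability studies are rarely
deposited, the generator produces complete studies with known truth:

1. a latent true rating per (trial, domain), drawn from per-domain
   marginals — the default template is the consensus rating distribution
   of a 56-trial study of physical-therapy RCTs
   (`default_marginals()`);
2. each rater reports through a 3×3 row-stochastic confusion matrix
   (`rater_profile()`); the convenience `accuracy_profile(p)` puts
   $p$ on the diagonal and splits the remainder evenly;
3. pair consensus: agreements pass through; a disagreement resolves to
   the latent truth with probability `fidelity`, otherwise uniformly to
   one of the two raters' answers;
4. trial metadata: publication years uniform on 1995–2013 and
   smallest-arm sizes lognormal with median 32 (truncated at 10),
   emulating a cohort with a median of roughly 65 randomized patients
   and an even split around the 50-per-arm stratum boundary.

Default rater accuracies are 0.60 for the minimal-training pair and
0.95 for the intensive-training and reference pairs, with consensus
fidelity 0.6 / 0.9 / 0.9 — values chosen once to reproduce the
qualitative structure of a training-effect study (intensive clearly
better than minimal in every domain) rather than any particular printed
estimate.

The key validation device is the analytic oracle
`expected_kappa()`: for truth marginal $m$ and confusion matrices
$A, B$, the joint reporting distribution is
$P(i,j) = \sum_t m(t) A(t,i) B(t,j)$, and the population kappa follows
from the same $p_{obs}/p_{exp}$ formulas applied to $P$. This closes
the loop between generator and estimator: `tune_accuracy()` inverts the
oracle to hit a target kappa, simulated estimates converge to the oracle
value at large $n$ (checked at $10^6$ draws within ±0.005), and BCa
intervals around simulated estimates can be checked for coverage of a
*known* parameter.

What the generator deliberately does **not** model: correlation of
domains within a trial (ratings are i.i.d. across trials and domains),
rater learning over time, contamination between training groups, and any
text-based features of real trial reports. Passing tests therefore
demonstrate the statistical machinery is correct under a clean
misclassification model — not that real rater behaviour follows that
model.

## Validation sizes and observed behaviour

The test suite validates at these problem sizes (chosen as the smallest
sizes at which each property is informative): oracle equivalence on
1000 random tables at $10^{-12}$; normal-mean BCa coverage at $n = 30$
over 1000 Monte-Carlo repetitions; kappa CI coverage at 200 trials over
200 repetitions with $B = 2000$; parameter recovery (targets
$\kappa = 0.4$ and $0.95$) over 100 generated 56-trial × 6-domain
studies, assessed on the scenario's pooled within-pair kappa (336
rating units).

Two limitations worth knowing. BCa intervals show the well-documented
mild small-sample undercoverage: for the normal mean at $n = 30$
empirical coverage sits near 0.93–0.94 rather than 0.95, and per-domain
intervals from only 56 trials at extreme kappa (≈ 0.95) cover the truth
in roughly 85% of repetitions — pooled over domains the nominal level is
restored. And interaction tests on small strata (a 56-trial study splits
into ~28 trials per level) inherit the same behaviour; their coverage
property is demonstrated at 100 trials per level.

## A worked example

```{r example}
cfg <- scenario_config(seed = 42)
st <- build_scenario(cfg)
res <- run_study(st$ratings, st$meta, n_replicates = 500, seed = 42)
res
```

The report writer (`write_report()`) serialises these results to CSV
(with `NE` literals for not-estimable entries) plus a plain-text
summary, and `read_report()` round-trips the CSV losslessly.
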