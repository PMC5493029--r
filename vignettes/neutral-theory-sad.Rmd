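---
title: "Testing neutral community assembly from species abundance distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing neutral community assembly from species abundance distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutralsad)
```

## The question and the models

Each microbiome sample is treated as one local community: a vector of OTU
read counts `n_1 >= n_2 >= ... >= n_S` with `J = sum(n_i)` individuals.
Neutral theory posits that all individuals are demographically equivalent,
so the probability of observing a given abundance configuration depends
only on a small number of parameters, and the observed SAD can be tested
against that prediction as a null model. Rejection is read as evidence for
deterministic niche structure; the fitted fundamental biodiversity number
θ doubles as a diversity measure that uses the full SAD rather than a
single index.

Two sampling formulas are implemented.

**Ewens** (`ewens_log_likelihood()`): the dispersal-unlimited case
(immigration probability m = 1),

$$\Pr(n_1,\dots,n_S \mid \theta, J) =
\frac{J!\,\theta^S}{\prod_a a^{\phi_a}\,\phi_a!\;\prod_{k=1}^{J}(\theta+k-1)},$$

with $\phi_a$ the number of species of abundance $a$. The species count
$S$ is sufficient for $\theta$: the MLE solves
$S = \sum_{k=0}^{J-1}\theta/(\theta+k) = \theta(\psi(\theta+J)-\psi(\theta))$.
`ewens_theta_mle()` brackets this monotone equation over
$\theta \in [10^{-8}, 10^{8}]$, solves by bisection on the log scale, and
polishes with Newton steps, so the richness identity holds at the returned
root to near machine precision. The boundary cases are flagged rather than
fitted: $S = J$ (all singletons) pushes $\hat\theta \to \infty$ and $S = 1$
pushes $\hat\theta \to 0$; in both the likelihood supremum is 1.

**Etienne** (`etienne_log_likelihood()`): dispersal limitation enters
through the immigration pressure $I = m(J-1)/(1-m)$,

$$P(D \mid \theta, m, J) =
\frac{J!}{\prod_i n_i \prod_j \phi_j!}\,
\frac{\theta^S}{(I)_J}\sum_{A=S}^{J} K(D,A)\,\frac{I^A}{(\theta)_A},$$

where $A$ counts immigrant ancestors and

$$K(D,A) = \sum_{\{a_i\,:\,\sum a_i = A\}} \prod_{i=1}^{S}
\frac{\bar s(n_i,a_i)\,\bar s(a_i,1)}{\bar s(n_i,1)}$$

with $\bar s$ unsigned Stirling numbers of the first kind (so
$\bar s(a,1) = (a-1)!$). As $m \to 1$ the formula converges to Ewens;
`m = 1` exactly is routed to the Ewens code because $I$ diverges there.

## Numerical design

Everything is computed in log space. Factorials and rising factorials of
small arguments go through `lgamma`, but $(I)_J$ and $(\theta)_A$ are
accumulated as explicit sums of logs: with $m$ within $10^{-9}$ of 1, $I$
reaches $10^{11}$ and the difference `lgamma(I+J) - lgamma(I)` loses
enough precision to break the Ewens/Etienne boundary agreement, while the
explicit sum (cost O(J), with J at most a few thousand) does not.

The Stirling triangle (`stirling_table()`) is filled by the standard
recurrence, one vectorised log-add per row, and cached per session.
$K(D,A)$ is never computed by enumerating ancestor assignments: species
$i$ contributes the polynomial with log-coefficients
$\log\bar s(n_i,a) + \log\Gamma(a) - \log\Gamma(n_i)$ for
$a = 1..n_i$, and the $S$ polynomials are multiplied by log-space
convolution (per-output log-sum-exp), O(S·J²) worst case and free of
cancellation since all terms are positive. The test suite verifies the
convolution against full assignment enumeration for communities up to
J = 12 and both formulas against exhaustive normalisation
($\sum_{\text{partitions of }J} P = 1$) for J ≤ 5–6.

`etienne_mle()` maximises over `(log theta, logit m)` with Nelder-Mead
from several starts (the Ewens $\hat\theta$ crossed with m from 0.1 up to
1 − 10⁻⁶), with m clamped to [10⁻⁶, 1 − 10⁻⁹]; the m → 1 boundary
evaluated at the Ewens $\hat\theta$ is always included as a candidate, so
the fitted maximum can never fall below the nested Ewens maximum by more
than the boundary-approximation error (~10⁻⁶ log units).

### A known identifiability limitation

For data that are actually dispersal-unlimited, $(\theta, m)$ lie on a
weakly identified ridge: the likelihood surface regularly has a second
local optimum at small m and large θ that exceeds the m → 1 boundary by
fluctuations of order χ²(1)/2, as expected when one extra parameter is
fitted to a null-model draw. Consequently $\hat m$ itself is an
unreliable quantity on near-neutral data (its point estimate can sit
anywhere on the ridge) even though the maximised log-likelihood — the
input to the likelihood-ratio test — is stable. The package therefore
treats the LRT deviance, not $\hat m$, as the meaningful summary of
dispersal limitation; θ recovery is summarised by the median across
replicates, which the tests show lands within a few percent of truth at
J = 800 while the mean can be distorted by the occasional far-ridge fit.

## The exact neutrality test

`exact_neutrality_test()` follows the simulation-based exact-test recipe:

1. fit the chosen formula to the sample (Ewens by default, matching the
   use case where the two formulas fit indistinguishably and Ewens is the
   simpler null);
2. simulate `n_sim = 100` neutral communities with the same J at the
   fitted parameters;
3. compute each simulated community's log-likelihood at parameters
   refitted to it (so observed and simulated values are exchangeable
   under the null; `refit = FALSE` evaluates at the original parameters
   instead);
4. locate the observed value in the ensemble.

The default p-value is the empirical two-sided quantile
$p = 2\min(r, 1-r)$ with $r = (\#\{\text{sim} \le \text{obs}\} + 1)/(n_{sim}+1)$;
its null distribution is the uniform rank statistic, giving a rejection
probability of 5/101 ≈ 0.0495 at α = 0.05 with 100 simulations. A second
p-value referring $-2(\log L_{obs} - \overline{\log L_{sim}})$ to χ²(1)
when the observed value falls below the ensemble mean (p = 1 otherwise)
is reported alongside for comparability with mean-based variants of the
test; it is not the default because the deviance-from-the-mean is not
χ²(1) distributed under the null and the construction is conservative.

Per-sample p-values are reported raw, without multiple-testing
correction; the cohort-level comparisons consume the binary verdicts, not
the p-values.

## The simulator

`simulate_community()` draws exactly from the sampling formulas by
sequential urn construction rather than approximating stationarity with
forward dynamics. For m = 1 it is the Hubbell/Ewens urn: individual k
founds a new species with probability θ/(θ+k−1), otherwise it copies a
uniformly chosen earlier individual. For m < 1 a two-level urn first
decides whether individual k is an immigrant (probability I/(I+k−1)) or a
local copy, and immigrant a founds a new species with probability
θ/(θ+a−1) or copies an earlier immigrant's species. Both are O(J). The
tests verify exactness directly: partition frequencies at J = 3, θ = 1
match (1/3, 1/2, 1/6) within Monte-Carlo error at 10⁵ draws, and mean
richness at (θ = 16.654, J = 479) matches the closed form (≈ 57).

Seeding is explicit everywhere: every ensemble member and every cohort
sample derives a substream seed deterministically from the master seed,
and generators restore the caller's RNG state on exit, so results are
bitwise reproducible and independent of surrounding code's use of the
RNG.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the pipeline targets: 56
control and 46 disease samples, per-sample J uniform on [300, 900]
(sequencing depth of a few hundred reads per sample), per-sample θ drawn
from a truncated normal with group means 57.13 and 42.89 and sd 8 —
between-subject heterogeneity around the two group diversity levels the
pipeline is meant to distinguish. With these defaults the per-sample
observed richness falls in the 12–266 range expected of such OTU tables
for essentially all samples. A configurable fraction of samples is
generated from classical niche SADs instead (lognormal with σ = 2, or a
geometric series with ratio 0.5 by default), with the species-count
target set to the expected neutral richness at the sample's (θ, J) so
niche and neutral arms match in richness, and totals hit J exactly by
largest-remainder rounding.

What the generator does **not** emulate: sequencing error, chimeras,
compositional noise, OTU-clustering artefacts, or any covariance between
samples. Passing tests on these cohorts show the inference chain is
correct and calibrated on data that satisfy its assumptions; they do not
show that real gut communities satisfy them.

One property of the niche arm deserves emphasis: a geometric series with
ratio 0.5 produces abundances (500, 250, 125, …, 1) at J = 1000 — a
shape essentially identical to the neutral logseries at its own fitted
θ ≈ 1.4. No SAD-shape test can reject such a community, and the exact
test's measured power there is ≈ 0. Power is high (≈ 1 in the test
suite) for niche SADs whose shape does depart from the logseries, e.g. a
near-even geometric series (ratio 0.9) or a moderate lognormal (σ = 1).
Users designing power studies should choose the niche shape accordingly.

## Problem sizes used by the test suite

The suite's statistical checks use: 200 outer replicates (each with 100
inner simulations) for the exact test's type-I error at (θ = 15,
J = 500); 100 replicates for the LRT null-calibration and for power
against niche SADs at J = 1000; 50 replicates for θ recovery at
J ∈ [500, 900] and for the 43-vs-57 two-group contrast on full 102-sample
cohorts; 10⁵ draws for the partition-frequency exactness check. These
sizes give Monte-Carlo standard errors comfortably inside the asserted
bands while keeping the whole suite around a minute on one core.

## Interfaces

`read_otu_tsv()` / `read_mothur_shared()` ingest count tables (counts
must be non-negative integers; relative abundances are rejected because
the sampling formulas are defined on read counts), `make_sample()` drops
zero-count OTUs and canonicalises each sample, `run_cohort()` runs the
full chain, and `write_cohort_report()` emits a per-sample TSV in the
conventional supplementary-table layout — sample, group, J, S, θ, m,
Log(L0), Log(L1), the deviance statistic (labelled `q-value` in that
layout) and the LRT p-value — plus a JSON summary embedding the full
configuration and seed. The package is a library by design; the
acceptance script under `scripts/` and these exported functions are its
entry points.
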