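---
title: "Posterior deviance evidence for rare-variant association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior deviance evidence for rare-variant association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devidence)
```

## The model and the evidence measure

Case-control association analysis for a candidate gene usually reports,
per genetic factor, a p-value from logistic regression. This package
implements an integrated Bayesian/likelihood alternative in which the
evidence object is the *posterior distribution of the deviance*.

Disease status is Bernoulli, $y_i \sim \mathrm{Bernoulli}(\pi_i)$ with
$\mathrm{logit}(\pi_i) = x_i'\beta$. Two nested models are fitted to the
same cohort: a baseline model (model 1) with intercept, age, smoking
status and four ethnicity dummies ($p = 7$), and a factor model
(model 2) that appends one genetic column ($p = 8$). Under a flat prior
on $\beta$ the posterior is proportional to the likelihood, so the
posterior expresses exactly what the data say about the coefficients.
Each posterior draw $\beta_j$ induces a deviance
$D_j = -2\log L(\beta_j)$; across draws this gives a distribution of
model fit rather than a single point. Evidence for the genetic factor is
read off the paired differences between two independent chains,

$$\Delta D_j = D^{(2)}_j - D^{(1)}_j,$$

summarised by the median, the central 95% credible interval, and the
**proportion of positive deviance differences**
$\Pr(\Delta D > 0 \mid \text{data})$. A small proportion means the
factor model fits better over essentially the whole posterior — strong
evidence of association. Because the two chains are independent, the
index pairing is arbitrary; re-pairing by a random permutation changes
the proportion only by Monte-Carlo noise, a property the test suite
checks. The comparator throughout is the standard logistic-regression
p-value for the genetic coefficient (Wald by default, likelihood-ratio
via `pvalue_method = "lrt"`).

Genetic factors are codings of the genotype matrix: the per-variant
minor-allele count (*additive*), the per-variant carrier indicator
(*collapsed*), and the indicator of carrying any variant with minor
allele frequency below 1% (*any-rare*). The bundled `kdr_variants()`
panel has 16 variants (14 rare) in a KDR-like gene region, ten of which
act on a quantitative risk factor Q1, most strongly variants 7 and 13
(per-allele effects 1.08 and 0.94 among nonsmokers).

## Sampling the posterior

`rwm_logit()` draws from the coefficient posterior with a random-walk
Metropolis chain:

* **Prior.** A flat prior is replaced by a uniform box $[-C, C]^p$ with
  half-width `prior_bound = 25` per coefficient. For identified models
  the truncation is numerically irrelevant (widening $C$ to 50 moves
  the deviance CDF by less than 0.005 sup-norm, asserted in the tests);
  under separation — a single rare carrier perfectly predicted — it is
  what keeps the posterior proper. On the log-odds scale $\pm 25$ spans
  odds ratios beyond $10^{10}$, i.e. everything distinguishable from
  infinity at cohort sizes like $N = 697$.
* **Proposal.** Multivariate normal with covariance $(2.38^2/p)\,
  \hat\Sigma$, where $\hat\Sigma$ is the MLE covariance — the standard
  optimal-scaling choice. Coordinates whose MLE standard error exceeds
  $C$ (which happens exactly under separation, where the Wald
  covariance diverges) are decoupled and proposed independently with
  standard deviation $C/2$; otherwise the runaway coordinate dominates
  the proposal, the adapted global scale collapses, and the identified
  coordinates freeze at the MLE.
* **Initialisation** at the MLE when it converges inside the box, else
  at zero. The headline statistic depends on the lower tail of the
  deviance distribution, so starting at the deviance minimum keeps the
  burn-in requirement small.
* **Adaptation.** During burn-in only, a single global scale factor is
  adjusted in batches of 50 toward `target_acceptance` (default 0.25,
  near the high-dimensional random-walk optimum; for one-coefficient
  validation models the univariate optimum 0.44 is requested
  explicitly). The scale is frozen at the end of burn-in, so the
  retained chain is a plain Metropolis chain with the correct invariant
  distribution. Defaults: 10,000 retained draws after 2,000 burn-in
  iterations; desk-scale analyses use 1,000–2,000 draws.
* **Diagnostics.** Each fit carries its acceptance rate, an effective
  sample size for the deviance series, and a drift flag raised when
  mean deviance differs by more than 2 units across chain thirds. A
  chain that accepts nothing during burn-in aborts with an error.

Two sanity anchors connect the posterior to frequentist quantities: the
minimum sampled deviance approaches the MLE deviance from above, and
for identified models the mean posterior deviance exceeds the minimum
by approximately $p$ (the mean of the asymptotic $\chi^2_p$ excess).
Both are asserted in the acceptance tests.

### Validation against independent references

For models with at most two coefficients,
`grid_posterior_reference()` evaluates the likelihood on a dense
lattice (MLE $\pm$ 8 standard errors, clipped to the prior box),
normalises, and yields the posterior deviance distribution by
quadrature — an oracle entirely independent of the sampler. Two closed
forms back it up: an intercept-only model with 3 successes of 10 has,
under a logit-flat prior, a Beta(3, 7) posterior on the success
probability, and posterior mean deviance
$-2\,(3\psi(3) + 7\psi(7) - 10\psi(10))$ with $\psi$ the digamma
function.

Sup-norm (Kolmogorov–Smirnov) comparisons at tolerances of 0.02–0.03
are only meaningful when draws are close to independent: a well-tuned
random-walk chain has an integrated autocorrelation time near 5, which
alone inflates the expected KS distance of 10,000 draws to the size of
the tolerance. Validation checks therefore thin the chain (`thin = 10`,
still 10,000 retained draws), which certifies the invariant
distribution itself; the analysis pipeline runs unthinned, matching the
10,000-draw design of the method.

## The synthetic cohort generator

No individual-level mini-exome data can be redistributed, so the
package generates cohorts with the statistical structure the analysis
assumes (`cohort_config()`, `simulate_cohort()`,
`generate_replicates()`):

* genotypes: independent Hardy–Weinberg draws, count
  $\sim \mathrm{Binomial}(2, \mathrm{MAF})$ per variant. Linkage
  disequilibrium, pedigree structure and per-ethnicity allele
  frequencies are deliberately **not** modelled — the analysis treats
  individuals as unrelated and tests one factor at a time, so these
  features would not exercise any code path under test;
* risk factors: $Q1 = \sum_v \beta_v g_v (1 + 0.5\,s)$ plus unit-sd
  noise, so smoker effects are 50% higher than nonsmoker effects; $Q2$
  is jointly normal with $Q1$ at correlation 0.7; a latent liability
  trait is $0.5 \cdot \mathrm{std(age)} + 0.5 \cdot s$ plus unit-sd
  residual, increasing with age and smoking;
* covariates: age truncated-normal (mean 45, sd 12, range 18–90),
  smoking prevalence 0.3, five equiprobable ethnicity categories;
* disease: $\mathrm{logit}\,\Pr(y=1) = \gamma_0 + 2\,Q1 + 0.3\,Q2 +
  0.5\,L$, with $\gamma_0$ calibrated by bisection so the expected
  prevalence equals `target_prevalence = 0.30` to within $10^{-3}$.

Prevalence, the covariate distributions, the Q1–Q2 correlation and the
liability and disease coefficients have no canonical reference values
for this design, so all of them are explicit, documented assumptions,
chosen once to describe a common disease with a strong rare-variant
component. The Q1
coefficient of 2 gives a carrier of the strongest rare variant a
per-allele disease log-odds shift of about 2.2 — a high-penetrance
rare-variant effect that is detectable but nowhere near saturated at
$N = 697$: with MAF 0.07% the expected carrier count is about one, and
each perfectly-predicted case-carrier can contribute at most
$2\log(1/0.3) \approx 2.4$ likelihood-ratio units, which caps
achievable power regardless of effect size. Passing tests therefore
demonstrate correctness of the machinery on data with this structure;
they do not reproduce power levels attainable only with the original
fixed genotypes (where the replicates share one genotype matrix —
available here via `redraw_genotypes = FALSE`).

Reproducibility uses a counter-based scheme: `derive_seed(master, r)`
maps a master seed and a stream index to a sub-seed through two Lehmer
steps modulo $2^{31}-1$, so replicate $r$ (and chain $i$ within it) can
be regenerated in isolation and in any order.

## The power pipeline

`run_experiment()` simulates replicates, computes the per-factor
evidence table for each, and summarises per factor: the median and
2.5th/97.5th percentiles of both statistics, power at thresholds 0.1,
0.05 and 0.01 (strict `<`, both measures thresholded raw, without
empirical-null calibration — mirroring how the two are compared in
practice), a Wilcoxon rank-sum test of the location shift between the
two statistics, and continuity-corrected chi-square tests of equal
rejection proportions at each threshold. Percentiles use linear
interpolation (R type 7) throughout, so credible intervals and
summaries are bit-reproducible. Failed replicates are excluded with a
reported count, and two runs with the same master seed produce
byte-identical CSV outputs.

Degenerate factors — a rare variant with no carriers in a replicate,
common under Hardy–Weinberg redraws at MAF 0.07% — carry no
information: such rows get p-value 1 and a deviance-difference
comparison of two independent baseline chains (so their positive share
concentrates at 0.5), and are flagged `degenerate` rather than dropped,
keeping power denominators honest.

Within one replicate the baseline chain is sampled once and reused for
all 17 factor comparisons; independence between the two chains of each
comparison is what matters, and reuse keeps one replicate at 18 chains.
The effect-size monotonicity study reuses the same replicate sub-seeds
across effect multipliers (common random numbers), so power differences
between multipliers are not masked by between-replicate noise.

## Numerical choices and edge cases

* Log-likelihoods use $\sum y_i \eta_i - \log(1+e^{\eta_i})$ with a
  piecewise `log1p`/asymptotic form, exact for $|\eta|$ up to and
  beyond 700.
* The MLE is fitted by IRLS (`stats::glm.fit`, tolerance $10^{-12}$,
  at most 100 iterations) with an explicit score-norm convergence
  check; rank-deficient designs are rejected naming the offending
  columns; separation is flagged when $|\hat\beta| > 15$ without score
  convergence or when fitted probabilities pin to 0/1 for all carriers
  of a binary predictor.
* `prop_positive` uses strict $> 0$; exact zeros count as
  non-positive.
* Wilcoxon tests switch to exact enumeration for combined $n \le 20$
  without ties; proportion tests keep the continuity correction, which
  is mildly conservative at very small counts (the tests compare it
  against an exact unconditional enumeration oracle).
* Desk-scale defaults keep the whole test suite to roughly a minute:
  50–200 replicates with 300–2,000 draws per chain, against the full
  200 × 10,000 design available through configuration.

## Known limitations

* Genotype redraws make rare-variant carrier counts vary across
  replicates; power estimates therefore average over ascertainment in
  a way a fixed-genotype design does not.
* The deviance-difference evidence measure is compared at raw
  thresholds; its null rejection rate is an empirical output (around
  0.01 at nominal 0.05 in the bundled calibration) and is *not*
  equalised to the p-value method's — the comparison is deliberately
  of the two statistics as used.
* Gene–smoking interaction models, Bayes-factor comparators and
  multiple-testing corrections across factors are out of scope.
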