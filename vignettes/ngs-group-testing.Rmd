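---
title: "Group association testing from genotype likelihoods under a GLM"
author: "ngsGroupTest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group association testing from genotype likelihoods under a GLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngsGroupTest)
```

# The problem

Low-coverage sequencing studies rarely observe genotypes. What a study
observes are reads, and at 1-4x mean depth a hard genotype call at a site is
often wrong, especially for heterozygotes and rare alleles. The standard
two-stage pipeline — call genotypes, then regress the phenotype on the calls
— discards the calling uncertainty and loses power exactly where sequencing
is cheapest.

`ngsGroupTest` tests the association between a *group* of biallelic variants
and a complex phenotype directly from genotype likelihoods, never calling
genotypes. Two tests are provided:

* **joint significance (JS) test** for a group of `dg` common variants
  (MAF at or above 0.05): a score test of `H0: beta = 0` jointly, chi-square
  with `dg` degrees of freedom;
* **variable collapse (VC) test** for a group of rare variants
  (MAF below 0.05): the marker effects are constrained to a single direction
  `beta = beta0 * W` with a positive weight vector `W`, giving a 1-df score
  test of `H0: beta0 = 0` — the likelihood-uncertainty analogue of the
  weighted burden test.

Both support continuous (linear), binary (logistic) and count (Poisson)
phenotypes through one generalized linear model, with covariates.

# Model

The phenotype density is exponential-family,

$$p(y_i \mid x_i, g_i) = \exp\left\{ \frac{y_i \eta_i - b(\eta_i)}{a(\phi)}
  + c(y_i, \phi) \right\}, \qquad
  \eta_i = \alpha x_i^T + \beta g_i^T,$$

with $(a, b, c)$ chosen per family: gaussian $a(\phi) = \phi$,
$b(\eta) = \eta^2/2$; logistic $a = 1$, $b(\eta) = \log(1 + e^\eta)$;
Poisson $a = 1$, $b(\eta) = e^\eta$. The gaussian family carries the free
dispersion $\phi = \sigma^2$, so its parameter vector is
$(\alpha, \beta, \phi)$; the other two drop $\phi$. `familyTerms()` exposes
$b, b', b''$ and the $a$- and $c$-derivatives that the score machinery
needs.

Genotypes are latent. With reads $D_i$ and a Hardy-Weinberg prior at allele
frequencies $\hat f$, the joint density marginalizes over the genotype
space $\mathcal{G} = \{0,1,2\}^{d_g}$:

$$p_\theta(y_i, D_i \mid x_i) = \sum_{g \in \mathcal{G}}
  f_\theta(y_i \mid x_i, g)\, h(g, D_i), \qquad
  h(g, D_i) = p(D_i \mid g)\, p(g \mid \hat f).$$

Under `H0: beta = 0` the phenotype density leaves the sum, so the
constrained MLE $\tilde\theta = (\tilde\alpha, 0[, \tilde\phi])$ is just
the GLM of `y` on the covariates (`fitNull()`; for gaussian,
$\tilde\phi$ = RSS/N, the MLE, because the score test must be evaluated at
the exact constrained maximum). The score test needs only the score and the
observed information (negative Hessian of the marginal log-likelihood) at
$\tilde\theta$, where both collapse to closed forms in two posterior
moments per individual,

$$E[g \mid D_i] \quad\text{and}\quad E[g^T g \mid D_i],$$

computed by `posteriorMoments()`. The statistic is
$R = s^T o^{-1} s$ with the zero-padded score; `jsTest()` evaluates it
through the Schur complement of the beta block (algebraically identical,
numerically safer) and refers it to chi-square(`dg`). `vcTest()` projects
score and information through `W` by the chain rule and refers the 1-df
statistic to chi-square(1); weights are normalized to sum to `dg`
(identification), so the statistic is invariant to weight rescaling.
`betaWeights()` supplies the customary Beta(1, 25) MAF weighting.

Two derivation details worth recording:

* the exact second-moment matrix over $\mathcal{G}$ would cost $3^{d_g}$
  terms, but the read likelihood and the HWE prior both factorize across
  sites, so the posterior factorizes: off-diagonal entries of
  $E[g^T g \mid D_i]$ are products of per-site means and only the diagonal
  needs per-site second moments. This is an exact reformulation, verified
  in the tests against the brute-force enumeration;
* the collapsed 1-df statistic is written here as $s^T o^{-1} s$; the
  inverse is required for the statistic to be scale-free and chi-square(1)
  (a form without the inverse is not invariant to rescaling the score).

## Observed versus expected information

The information used is the *observed* information — the actual negative
Hessian at $\tilde\theta$ — whose beta block is

$$o_{\beta\beta} = \sum_i \frac{b''(\tilde\alpha x_i^T)}{a}
  E[g^T g \mid D_i] -
  \frac{(y_i - b'(\tilde\alpha x_i^T))^2}{a^2}
  \left( E[g^T g \mid D_i] - E[g^T \mid D_i] E[g \mid D_i] \right).$$

The second term has expectation zero under the model (since
$E[(y-b')^2] = a\,b''$) but is random; the *expected* information would
delete it. This package keeps the observed form, and the choice is
measurable: for the Poisson family the squared residuals are heavy-tailed
(with unit covariate effects, $\lambda = e^{X_1 + X_2}$ spans two orders of
magnitude), and at mean depth 1X — where the posterior genotype variance
multiplying the term is largest — the noise in $o_{\beta\beta}$ inflates
the JS test's finite-sample Type I error above the nominal level (the
acceptance harness measures 0.08-0.09 at N = 300 against a nominal
0.05, decaying slowly with N; logistic and gaussian phenotypes, whose
residuals are bounded or light-tailed, stay within Monte Carlo error of
0.05, as do all families at 10X and the 1-df collapse tests). An
expected-information variant removes the inflation entirely in the same
harness, but it is a different statistic; the observed form is retained as
the definition of the method, and the measurement is reported rather than
hidden. Users testing count phenotypes at very low depth should prefer
larger samples or deeper sequencing.

Finite-sample observed information need not be positive definite. Rather
than failing, the quadratic form uses an eigenvalue-truncated
pseudo-inverse (threshold `1e-10` times the largest eigenvalue), reports
the effective rank in the result object, and keeps the reference degrees
of freedom at `dg` (or 1) — the truncation is a numerical guard, not a
model change.

# Read model and allele frequencies

`siteLikelihood()` converts read counts to genotype likelihoods under the
symmetric error model: a read from genotype `g` reports the alternate
allele with probability $(g/2)(1-e) + (1-g/2)e$, reads independent, with a
single per-base error rate `e` (default 0.005) standing in for per-read
qualities. Likelihood triples are unnormalized and every downstream
computation is invariant to rescaling them; sites with no reads carry the
flat triple and contribute the prior, never dropped. External likelihoods
are accepted as BEAGLE GL text (`readBeagleGL()`/`writeBeagleGL()`) or VCF
with GL (log10) or PL (phred, converted as $10^{-PL/10}$) FORMAT fields
(`readVcfGL()`, biallelic records only).

Three allele-frequency sources feed the HWE prior, and the tests are run
with each in the benchmark (variant 1/2/3 of each test):

1. **known frequencies** (simulation truth or external reference);
2. **two-step**: MAP-call genotypes with an f = 0.5 prior, count alleles,
   re-call once under the resulting frequencies, freeze (`afTwoStep()`;
   the calling prior is MAP under HWE — a maximum-likelihood call is the
   special case of a flat prior, and one refinement round reproduces the
   qualitative behaviour of the two-step estimator without iterating to a
   fixed point);
3. **one-step EM MLE** (`afEM()`): per site, EM on
   $\sum_i \log \sum_g p(D_i \mid g)\,\mathrm{HWE}(g \mid f)$ with
   $f_0 = 0.5$, tolerance `1e-6` on `f`, at most 200 iterations, a
   monotonicity assertion on the log-likelihood at every step, and a
   degenerate-site flag where no individual has coverage.

Genotype-based comparators (`genotypeGroupTest()`, `burdenTest()`) run on
MAP calls under the two-step frequencies, mirroring the two-stage pipeline
they represent. Their test form is the likelihood-ratio chi-square (the
default group-significance test in GLM practice; the gaussian family also
exposes the exact F), with degrees of freedom equal to the rank the
genotype block adds beyond the covariates.

# The simulator

`simulationConfig()` + `simulateDataset()` generate the benchmark design
end to end under one seed:

| parameter | default | meaning |
|---|---|---|
| `mafRange` (common) | U(0.05, 0.5) | per-site MAF spectrum, 5 markers/group |
| `mafRange` (rare) | U(0.005, 0.05) | 10 markers/group |
| `depth` | 1, 2, 4 or 10 | Poisson mean reads per site per individual |
| `errorRate` | 0.005 | symmetric per-base error |
| covariates | X1 ~ Bern(0.5), X2 ~ N(0,1) | effects (0, 1, 1) with intercept 0 |
| `nCausalRange` | 2-5 common, 2-10 rare | causal count drawn per replicate |
| `totalEffect` | 0.2 x magnitude, magnitude in 0-5 | split equally over the causal set |
| `includeEtaNoise` | TRUE for logistic only | extra N(0,1) inside the linear predictor |

The binary generative model includes an N(0, 1) noise term *inside* the
linear predictor. That is unusual (it induces a logistic-normal mixture),
but it is the stated benchmark design and is implemented as such, with a
toggle; for a Bernoulli response it cannot produce overdispersion, so the
null calibration is unaffected. The count model takes no such term. The
gaussian model is `y ~ N(eta, 1)`.

Genotypes are independent Binomial(2, MAF) draws. An optional haplotype
copying mode (`simulateGenotypes(..., ld = )`) couples adjacent sites for
robustness checks and is off by default: the operating characteristics
under study depend on depth, error, MAF spectrum and effect size, not on
fine-scale linkage structure. This is the main respect in which the
simulator is idealized relative to real cohorts; the others are uniform
mean depth across individuals and a single error rate across sites and
read positions. Passing tests therefore demonstrate calibration and
ordering under these design conditions, not robustness to stratification,
depth heterogeneity or error-rate miscalibration.

`runType1()` and `runPower()` drive the replicate grids. Each replicate's
random stream derives from (master seed, cell index, replicate index), so
tables are reproducible and independent of execution order; a method that
errors on more than 1% of replicates aborts its cell rather than silently
biasing the estimate.

# Numerical choices

* logistic `b(eta)` uses the overflow-stable `max(eta, 0) + log1p(exp(-|eta|))`;
* null fits polish the IRLS solution with Newton steps until the
  alpha-score is below `1e-10` (asserted below `1e-8`), since the score
  test assumes the first-order condition exactly;
* likelihood triples from more than 300 reads are computed in log space
  and rescaled by the maximum;
* MAP calling breaks posterior ties toward the smaller genotype
  (deterministic output);
* monomorphic sites — constant dosage with no posterior uncertainty —
  carry no information and are dropped from a group with a warning;
  `dg` and the reference degrees of freedom reflect the retained count;
* a group whose sites are all monomorphic returns statistic 0, p = 1.

# Problem sizes used in the checks

The package's own verification uses: brute-force enumeration oracles up to
`dg = 4` (and numerical score/Hessian oracles at N = 6, `dg = 2`, on an
instance where the observed information is positive definite); reduction
to the classical genotype-based score tests at simulated depth 100;
2000-replicate null grids for the calibration and uniformity checks
(uniformity at N = 1000, where the asymptotic chi-square reference is
accurate); and 400-replicate power grids at magnitude 3 for the
depth-ordering properties. At the benchmark's printed effect scale (total
effect at most 1 split over the causal set) absolute power at N = 300 and
1X is modest, so the depth orderings are asserted as inequalities within
two Monte Carlo standard errors rather than as strict separations.

# Limitations

* Biallelic, autosomal, additive coding only; dominant/recessive/
  heterogeneous effect encodings would enter through the linear predictor
  and are not implemented.
* No variance-component (SKAT-style) test on genotype likelihoods; the VC
  test, like any burden-type statistic, loses power when causal effects
  take both signs.
* Allele frequencies in the prior are treated as known once estimated; no
  uncertainty propagation from $\hat f$.
* Uniform mean depth per dataset; per-individual depth heterogeneity is
  not modelled.
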