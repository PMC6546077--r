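---
title: "Functional mapping of QTL for longitudinal traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional mapping of QTL for longitudinal traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longqtl)
```

## The problem

A quantitative trait measured repeatedly on each individual — stem growth
over years, body mass over weeks, response over doses — is a curve, not a
number. Mapping quantitative trait loci (QTL) one time point at a time
discards the information that the *shape* of the trajectory is heritable
and that measurements on the same individual are correlated. Functional
mapping treats the trajectory as the unit of analysis: each QTL genotype
has its own parametric mean curve, and the within-individual correlation
is modelled by a structured longitudinal covariance.

## Model and assumptions

For individual $i$ with phenotype vector $y_i$ at $m$ time points and QTL
genotype $j \in \{1,\dots,J\}$:

$$f_j(y_i) = (2\pi)^{-m/2}\,|\Sigma|^{-1/2}
  \exp\!\left[-\tfrac12 (y_i - \alpha X_i - g_j)^\top \Sigma^{-1}
  (y_i - \alpha X_i - g_j)\right]$$

* $g_j(t)$ — genotype-specific mean curve (logistic by default).
* $\Sigma(\theta)$ — one covariance shared by all genotypes.
* $\alpha X_i$ — optional covariate effect, a scalar shift applied
  uniformly to all time points (time-varying covariate effects are out of
  scope).

The QTL genotype is unobserved except at typed markers, so the
alternative-hypothesis log-likelihood is a finite mixture,
$\sum_i \log \sum_j p_{ij} f_j(y_i)$, with mixing weights $p_{ij}$ the
conditional genotype probabilities given the flanking markers. The null
model constrains all genotypes to one curve. The scan statistic is
$LR2 = -2(\ell_0 - \ell_1)$ at every grid position (default 1 cM,
anchored so every marker is always evaluated).

Assumptions worth stating plainly: multivariate normality of residuals;
a common $\Sigma$ across genotypes under both hypotheses; no crossover
interference (Haldane map function — required for the flanking-marker
factorisation to be exact); a single QTL per tested interval (no
composite-interval covariate markers).

## Conditional genotype probabilities

All four cross types share one machinery: a two-locus genotype transition
matrix $T(r)$ per interval, with $p(q \mid a, b) \propto T(r_1)[a, q]\,
T(r_2)[q, b]$ for flanking observations $a, b$ and no-interference
recombination fractions $r_1, r_2$. BC and DH carry a single meiotic
product; F2 composes two independent gametes (heterozygote phases equally
likely). Selfed RIL needs care: the Haldane–Waddington expansion
$r^* = 2r/(1+2r)$ is exact for any *pair* of loci, but the RIL genotype
sequence is not a Markov chain, so composing $r^*$ per interval
mis-states three-locus probabilities: for an 8 + 12 cM pair of
intervals the composition $r^*_1(1-r^*_2) + r^*_2(1-r^*_1)$ predicts
$R_{13} = 0.259$, while Haldane–Waddington applied to the summed
distance (which any correct joint law must marginalise to) gives
$0.248$. The package therefore computes the exact three-locus
fixation distribution by absorbing-Markov-chain analysis of the selfing
process (diplotype states, offspring = two independent gametes, solved
for absorption into the eight fixed haplotypes), and conditions on the
flanking observations from that joint law. One-sided conditioning
marginalises the joint and recovers $r^*$ exactly, as it must.
A missing flanking genotype drops its factor
(the individual conditions on the other side only); both missing falls
back to the cross's population prior (BC/DH/RIL: ½,½; F2: ¼,½,¼). At a
typed marker the row is exactly the observed indicator. The test suite
checks every cell of these tables against a physical meiosis simulator
(Poisson crossovers, parity decides recombination) at $10^6$ replicates.

Choices the source framework leaves open, decided here: the map function
is Haldane (Kosambi would contradict the independence factorisation);
"RIL" means RIL by selfing — sib-mated RIL users should be aware the
expansion differs.

## Curves and covariance structures

Both families are registries: built-ins below, user models addable at
runtime (`register_curve()`, `register_covariance()`).

Curves: `logistic` $a/(1+be^{-rt})$ (asymptote $a$ in trait units,
inflection scale $b$ dimensionless, rate $r$ per time unit);
`double_logistic` (sum of two logistics, for biphasic growth);
`legendre` (order-4 polynomial on times rescaled to $[-1,1]$ by their
observed range — the range is stored with the fit for prediction);
`pharmacology` $E_0 + E_{max} t/(E_{50}+t)$. Least-squares fitting uses
Nelder–Mead restarts from jittered initial guesses (5 restarts, fixed
internal seed so fits are deterministic) followed by a BFGS polish;
AIC/BIC use the Gaussian concentrated form
$N\log(\mathrm{rss}/N) + \mathrm{penalty}\cdot k$, which needs no
covariance model at the curve-selection stage.

Covariances: `vc` ($\sigma^2 I$), `cs` (compound symmetry; $\rho$ bounded
away from the singular $-1/(m-1)$ boundary), `ar1` (index-distance
$\sigma^2\rho^{|s-t|}$, appropriate for equally spaced measurements),
`ar1_time` (calendar-time distance, for irregular grids — whether the
source framework uses index or time distance is unstated, so both are
provided), `arma11`, `toeplitz` (banded), `sad1` (first-order
ante-dependence with per-time innovation variances $v_1..v_m$ and lag
coefficients $\phi_2..\phi_m$; $2m-1$ parameters). The original software
advertises thirteen structures without enumerating them; six cover the
families it names, and the registry covers the rest.

Two deliberate parameterisation decisions, both forced by the registry's
positive-definiteness contract (every parameter vector strictly inside
the bounds box must build a PD matrix):

* ARMA(1,1) is parameterised by process parameters $(\sigma^2, \phi,
  \theta)$, which reproduce the surface form $\sigma^2\gamma
  \rho^{|s-t|-1}$ with $\gamma$ derived; free $(\gamma,\rho)$ boxes
  contain indefinite matrices.
* Banded Toeplitz lags are bounded by strict diagonal dominance
  ($|c_k| < 1/(2\,\mathrm{band})$), restricting expressible correlations
  but making the whole box safe.

Covariance ML uses unconstrained reparameterisation (log variances,
scaled-logit correlations). `criterion = "MLE"` picks the largest
log-likelihood regardless of parameter count; it will essentially always
prefer `sad1`'s $2m-1$ parameters, which is why AIC is the default.

## Estimation

The null fit maximises one curve + covariance (+ covariates) by
coordinate ascent; it does not depend on genome position and is computed
once per scan. The alternative fit is EM: E-step posterior memberships
$w_{ij} \propto p_{ij} f_j(y_i)$; M-step is ECM — each genotype's curve
is refit against the $w$-weighted mean trajectory in the $\Sigma$ metric,
covariate coefficients have a closed-form GLS update, and $\theta$ is
refit on the weighted scatter matrix. Every block is warm-started and
each inner optimiser returns the best point visited, so the observed
log-likelihood is non-decreasing; a decrease beyond tolerance raises an
error rather than being clipped, because it indicates an optimiser bug.
Defaults: tolerance $10^{-6}$ on the log-likelihood, 200 iterations,
H1 initialised from the null curve replicated per genotype with a
deterministic ±1% perturbation to break label symmetry. Because the
unperturbed replicated point is itself an H1 parameter vector whose
mixture log-likelihood equals the null log-likelihood, it is always kept
as a candidate: a budget-limited EM run can never return an alternative
fit below the null, so $LR2 \ge 0$ holds by construction rather than by
clipping (and the scan falls back from a stalled warm start to the
null-replication start). $\Sigma$ is
re-estimated under both hypotheses (full MLE); `fm_control(freeze_sigma
= TRUE)` freezes it at the null estimate for speed — the source
publication does not say which convention it uses.

Negative $LR2$ beyond $-10^{-6}$ is an error, not a silent clip.
Missing phenotype cells are marginalised (the MVN density is evaluated
on observed coordinates only), never dropped row-wise.

The scan warm-starts each position from the previous position's fit on
the same chromosome (the mixing weights vary continuously in position),
falling back to null-replication on failure. Chromosomes are independent
units of work, so results are bitwise identical for any worker count.
Failed positions are reported as missing, never interpolated; more than
20% failures aborts the scan.

## Permutation significance and the pre-filter

Permutations reshuffle the assignment of phenotype rows (with their
covariates) to genotype rows — equivalent under the null to permuting
genotypes, but the conditional probabilities can then be computed once.
The null likelihood is invariant to the reshuffle, so the null fit is
reused. The threshold is the type-7 empirical $(1-\alpha)$ quantile of
the per-permutation genome-wide maximum $LR2$; $\alpha = 0.05$ and the
quantile convention are this package's documented defaults (the source
states neither). Per-permutation RNG streams derive from (seed,
permutation index), so results are independent of scheduling.

The cost-saving pre-filter replaces the original genotype-oriented
curve-clustering candidate selection with a cheap documented screen:
positions are ranked by the squared correlation between expected genotype
dosage $\sum_j j\,p_{ij}$ and the phenotype (maximised over time points)
and the top fraction per chromosome is kept, always including each
chromosome's observed peak — so the filter can never hide the observed
signal. Known limitation: the filtered threshold is the quantile of a
maximum over a subset of positions, so it can only be biased downward,
and the bias grows as the keep fraction shrinks and the genome gets
shorter. On a desk-scale genome the test suite verifies agreement within
5% at keep fraction 0.5; aggressive filtering (0.1–0.2) on short genomes
is anti-conservative. On long multi-chromosome genomes — the regime the
filter is meant for — the subset bias shrinks. Choose the keep fraction
accordingly.

## The simulator: what it emulates, what it does not

`simulate_dataset()` is the package's test bed and a first-class module.
It generates marker genotypes as a Markov chain with Haldane
recombination along the map (two independent gamete chains for F2;
expanded $r^*$ for RIL), inserts the QTL as a hidden pseudo-locus at its
map position (returned in a truth sidecar, never written to the genotype
CSV), and draws phenotypes as genotype curve + structured MVN noise +
optional covariate shift. Defaults mirror a forest-tree backcross design:
11 equally spaced measurements, AR(1) residuals with $\sigma^2 = 1,
\rho = 0.6$, asymptote-separated logistic curves, $n = 200$ — a size at
which parameter recovery and localisation are comfortably testable.

It does not emulate: crossover interference, segregation distortion,
genotyping error, phenotype measurement batches, or non-Gaussian
residuals. A green simulation-based test therefore establishes
correctness of the estimator under its own model assumptions, not
robustness to their violation.

Reproducibility: one root seed; per-chromosome substreams for genotypes
and a separate substream for phenotypes. Generation is vectorised across
individuals, so individual-level substreams (useful only under parallel
generation) are not implemented.

## Numerical choices

* Box-constrained inner optimisation via bijection to $\mathbb{R}^k$
  (log / scaled-logit), Nelder–Mead for $\le 6$ parameters, BFGS above.
* Log-sum-exp for all mixture likelihoods.
* Cholesky factorisation for all MVN evaluations; one factorisation
  shared across individuals when data are complete.
* Ties in curve/covariance selection break toward fewer parameters, then
  earlier registration; scan-peak ties break toward the smaller position.
* Degenerate inputs: empty posterior classes keep their current
  parameters for that M-step; zero-variance dosage scores rank last in
  the pre-filter.

## Known limitations

Single-QTL scan only (no composite interval mapping, no epistasis, no
multi-trait models); no support intervals for QTL location; no standard
errors for curve parameters; Kosambi and interference models not offered;
the external poplar replication requires user-supplied data (see
`scripts/replicate_populus.R`) and documented tolerance (10% on the peak
$LR2$), since the original optimiser's internals are not published.
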