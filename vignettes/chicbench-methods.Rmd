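---
title: "Auditing a capture Hi-C interaction caller: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a capture Hi-C interaction caller: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chicbench)
```

## The problem

Capture Hi-C (CHi-C) enriches Hi-C libraries for di-tags anchored at a
designed set of bait fragments — typically promoters — so that
interactions of a few thousand regions of interest can be tested at
restriction-fragment resolution. Calling an interaction means rejecting
a background model in which read counts arise from random polymer
contact ("Brownian collisions") plus technical noise. chicbench packages
a minimal caller built on exactly that background, together with the
diagnostic battery a reviewer would want before trusting any caller's
output: goodness of fit of the count model per distance bin, the shape
of the distance decay, symmetry of the evidence for bait-bait pairs, the
behaviour of score thresholds, and the influence of p-value weighting.
Because real CHi-C libraries of the kind such audits are run on are
controlled-access, the package ships a synthetic-data generator with
known ground truth; every diagnostic runs at desk scale with no
download.

## The background model

For a bait fragment $i$ and another fragment $j$ at genomic distance
$d < 1.5$ Mb, observed counts are modelled as

$$X_{ij} \sim \mathrm{NB}(\mu_{ij},\, r) + \mathrm{Pois}(\lambda), \qquad
\mu_{ij} = s_i\, s_j\, f(d),$$

a Delaporte distribution: the negative binomial captures Brownian
background with a *global* dispersion $r$, the Poisson captures
technical noise, and within 1.5 Mb the Poisson component is small enough
that scoring may use the NB approximation with a per-pool $\lambda$
folded into the tail. The pieces are estimated in a fixed cascade:

* **Distance function** $f(d)$: geometric mean of the *non-zero* counts
  per 20 kb distance bin, fitted on the log-log scale by a cubic
  polynomial, a straight line, and the fixed-slope power law
  $f(d) \propto d^{-1}$ expected for long-range polymer contacts. The
  cubic is the active curve for scoring; all three are reported with
  their RSS and integrated curvature
  $K = \int |y''|\,(1+y'^2)^{-3/2}\,dx$ over
  $[\log 10^4, \log 1.5\times10^6]$, which is zero exactly for a power
  law. Outside the fit range the curves extrapolate linearly on the
  log-log scale.
* **Scale calibration.** Geometric means sit below arithmetic means by a
  dispersion-dependent factor, so the model carries one global
  multiplicative constant (`mean_scale`) matching total expected to
  total observed counts. Without it every p-value would be
  systematically miscalibrated in the same direction.
* **Biases.** The bait-end bias $s_i$ is treated as fixed per bait
  (total observed over total expected, geometric mean normalised to 1);
  the other-end bias is treated as a draw from a random distribution,
  realised as five marginal-count quantile pools each summarised by its
  empirical ratio distribution. This fixed-versus-random asymmetry is
  deliberate: it is the mechanism that makes bait-bait scores depend on
  the direction of computation, and the audit measures exactly that.
* **Dispersion** $r$: profile maximum likelihood with the per-pair means
  held fixed, optimised on $\log r$; under-dispersed input caps at
  $r = 10^6$ with a warning.
* **Technical noise** $\lambda$: estimated from trans-chromosomal pairs
  (which the Brownian term cannot produce) as total trans reads over
  possible trans pairs, within five bait pools stratified by marginal
  read depth.

The per-pair evidence is the upper tail $\log p = \log P(X \ge x)$
computed exactly in log space, and the score is the weighted,
soft-thresholded statistic

$$\mathrm{score}_{ij} = \max\{0,\; -\log p_{ij} + \log w(d)\},$$

where $w(d)$ is a four-parameter bounded logistic prior probability of
interaction in log distance (lower/upper asymptotes in $[0,1]$,
midpoint, non-negative slope — hence monotone non-increasing). The
composition is a design choice: the score statistic's exact closed form
is not part of the published interface of the caller being emulated, and
weighted soft-thresholding reproduces both the "score > 5" semantics and
the interplay with the robust-interaction function $g(\rho)$ used in the
threshold audit.

## The diagnostic battery

**Goodness of fit.** Per distance bin, a discrete Kolmogorov-Smirnov
statistic compares observed counts with the null
$X \sim \mathrm{NB}(s_1 s_2 f(d), r)$, $d$ uniform on the bin, biases
drawn from their estimated empirical distributions. Because the null has
no tractable closed form, the model CDF is the pooled empirical CDF of
an independent simulation pool, and significance is Monte-Carlo:
$p = (1 + \#\{D_\mathrm{sim} \ge D_\mathrm{obs}\})/(1 + n_\mathrm{sim})$
with two independent pools (sample splitting) so that simulated
replicates are never compared against a pool containing themselves. A
bin-wise Bonferroni correction flags rejections. The conventional
settings are 5000 simulations of 5000 pairs; the package exposes both,
and its default desk configuration runs 200 simulations of 500 pairs,
which keeps the estimator floor at $1/201$ — adequate for a screening
table — while an evaluation at the conventional settings is a config
change.

**Score symmetry.** For bait-bait pairs both directions are scored; the
audit reports the Pearson correlation of $\mathrm{score}_{ij}$ against
$\mathrm{score}_{ji}$ over pairs non-zero in at least one direction
(all-zero pairs would inflate the correlation), the five largest squared
deviations, and the proportion of *reversible* interactions — the
Jaccard index of the two directed significant sets. A symmetrized
scoring mode (both roles use fixed biases) is provided as a control: it
makes the two directions identical by construction, demonstrating that
the pooled-bias treatment, not noise, is the source of the asymmetry.

**Thresholds.** Around the conventional score threshold of 5 (strict
inequality) the battery reports: the FNR-style function
$g(\rho)$ — the fraction of pairs with $\log p < \rho$ that fail the
threshold — at $\rho = -10$; the $\rho^*$ solving $g(\rho^*) = 0.05$ by
grid scan plus bisection; the replicate-reproducibility FDR proxy
$1 - J(A_1,\dots,A_K)$; integer thresholds targeting FNR $= 0.2$
(exhaustive scan, ties toward the smaller threshold, favouring
sensitivity); thresholds minimising the FDR proxy under two optimisers;
and the FWER threshold $\log(n/\alpha)$ from the smallest bin's pair
count. The FDR objective is piecewise constant in the threshold, so the
two optimisers genuinely disagree: the bound-constrained quasi-Newton
(`optim`'s L-BFGS-B, finite-difference step 0.5) typically stalls at its
starting point because the staircase is locally flat and its line search
aborts, while Nelder-Mead walks — sometimes to thresholds too large to
be useful. The audit reports both, because demonstrating that the answer
depends on the optimiser *is* the diagnostic; neither value is asserted
as correct.

**Weighting.** The observed prior probability of interaction per bin is
the fraction of tested pairs with $\log p < \rho$ in *all* replicates.
Its lack of monotonicity,
$\mathrm{LOM}(v) = 1 - |v_n - v_1| / \sum_i |v_{i+1} - v_i|$, is 0 for
any monotone sequence, so a large value indicates structure a monotone
logistic cannot represent. The logistic fit's RSS is computed on the
probability scale over bins with observed interactions only — excluded
empty bins deflate the RSS, so their count is reported alongside, making
the artefact visible rather than hidden. The audit refits the weight
curve at $\rho = -10$ and at $\rho^*$, keeps the lower-RSS fit, rescores
everything, and reports the Jaccard concordance of significant calls
plus the changes (custom minus default) in score correlation, percent
reversible, FDR at the threshold, and FNR.

## The synthetic generator

The generator is first-class, tested code, and its defaults define the
study conditions used by the test suite and the acceptance script:

* **Map:** one synthetic chromosome of 1000 contiguous fragments with
  gamma-distributed lengths around 4 kb (HindIII-like digests), 10% of
  fragments designated baits, plus a decoy chromosome of half that size
  whose only role is to furnish trans pairs for $\lambda$ estimation —
  the smallest structure that exercises every estimator.
* **Decay:** $f(d) = e^{c_0}/d$ with $c_0 = \log(5 \times 10^6)$, i.e.
  roughly 500 expected background reads at 10 kb falling to ~3 at
  1.5 Mb. The depth is chosen so that counts are well above zero across
  the whole fit range: the geometric-mean estimator of $f$ is log-scale
  unbiased only in that regime, which is also the regime deep real
  libraries occupy. At substantially lower depth the zero-exclusion
  bias flattens the estimated decay — itself a useful failure mode to
  know about, but not a sensible default condition.
* **Dispersion** $r = 2$; **biases** log-normal with sdlog 0.25 (baits)
  and 0.5 (other ends), geometric mean 1 — enough spread to make the
  bait-bait asymmetry measurable while keeping counts realistic.
* **Technical noise:** five $\lambda$ strata from 0.001 to 0.01 reads
  per possible trans pair, assigned by bait brightness (capture
  efficiency and noise co-vary in real libraries), which is what makes
  the "medians and variances trend upwards" boxplot diagnostic
  meaningful rather than vacuous.
* **Truth:** each cis pair within 1.5 Mb is a true interaction with
  probability given by a logistic prior $(5\times10^{-4},\ 0.03,\ 12,\
  2)$ — a few percent proximally, decaying past $e^{12} \approx 160$ kb
  — with effect multipliers uniform in $[3, 10]$. The upper asymptote
  matches the order of magnitude implied by the field-standard
  macrophage-derived weights; spiking tens of percent of pairs would
  contaminate dispersion estimation so badly that nothing is callable,
  which is a property of unrealistic truth density, not of the caller.
* **Perturbations:** copy-number regions rescale counts by binomial
  thinning (multiplier < 1) or Poisson top-up (multiplier > 1), both
  integer-preserving with mean scaled by the multiplier. A breakpoint
  $(p_1, p_2)$ fuses two loci: pairs flanking both positions are
  resampled at the shortened distance $d - (p_2 - p_1)$ while keeping
  their apparent distance — the minimal mechanism for a translocation's
  distance distortion, with no claim about any particular karyotype.

What the generator does *not* emulate: restriction-site placement from a
real genome, mappability and GC structure in the biases, inter-replicate
batch effects, or read-level artefacts. Passing tests therefore show
that the estimators and diagnostics are correct under the stated model,
not that the model captures everything in real libraries.

## Numerical choices

* All probability computations are in natural-log space; the Delaporte
  upper tail decomposes over the Poisson component and is exact (the
  truncation of the Poisson mixture at mass $10^{-18}$ is bounded by an
  appended tail term).
* The discrete KS statistic is evaluated at integer atoms; the
  pooled-CDF comparison uses a sorted pool and `findInterval`, which is
  exact and avoids materialising step functions over large supports.
* Dispersion: golden-section search on $\log r$ in
  $[\log 10^{-3}, \log 10^6]$, tolerance $10^{-6}$.
* Weight fitting: bounded least squares (L-BFGS-B) from three
  deterministic starts; monotonicity via a sign-constrained slope;
  asymptotes clamped to $[0,1]$.
* $\rho^*$: grid $[-50, -1]$ at step 0.1, then bisection to
  $|g - 0.05| \le 0.005$.
* Ties in threshold scans break toward the smaller threshold
  (sensitivity over specificity), stated in the report.
* Degenerate inputs: zero-count pairs are scored ($\log p = 0$, score 0)
  but excluded from the symmetry correlation; empty distance bins are
  flagged, never imputed as zero; constant sequences have LOM 0 by
  convention with a warning.
* Every stochastic step derives its stream from the config seed and
  restores the caller's RNG state, so pipeline reruns are bit-identical
  and independent of evaluation order.

## Problem sizes

The default desk configuration — 1000 + 500 fragments, 100 baits, two
replicates, ~59,000 tested cis pairs per replicate, KS at 200
simulations of 500 pairs — completes in well under two minutes on one
core. The package's own test battery uses the same generator at sizes
from 400 to 3000 fragments: calibration of the Monte-Carlo KS test runs
200 self-null draws at 500 simulations of 1000 pairs, and parameter
recovery uses ~60,000 pairs, sizes at which the stated tolerances (slope
within 0.05, dispersion within 10%, bias within 20%) hold with
comfortable margins.

## Known limitations

* The caller is a minimal realisation of the stated background model,
  not a re-implementation of any production caller's estimation
  internals; absolute score values are therefore comparable only within
  this package.
* The λ audit at desk scale is granular: with ~1 expected trans read
  per bait, per-pool variances are noisy and the joint
  median-and-variance trend flag can legitimately fail even though the
  generating λ is monotone across strata — the per-pool medians are the
  more stable half of that diagnostic.
* The replicate-Jaccard FDR proxy assumes true interactions replicate
  perfectly; with two replicates of independent noise it is biased
  upward, which is visible in the default report and consistent with
  the proxy's behaviour on real replicate pairs.
* Bait-bait pairs are comparatively rare at desk scale, so the symmetry
  correlation carries wide sampling error from run to run.
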