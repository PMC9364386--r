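---
title: "Sex-unbiased between-array normalization by autosomal rank interpolation"
author: "interpXY package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-unbiased between-array normalization by autosomal rank interpolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interpXY)
```

## The problem

Infinium methylation arrays report, per CpG probe and sample, a methylated
(M) and an unmethylated (U) fluorescence intensity; the methylation level is
summarized as the beta value

$$\beta = \frac{M}{M + U + 100},$$

with the conventional offset of 100 stabilizing low-intensity probes and
keeping $\beta \in [0, 1)$. Between-array normalization is usually
quantile-based: every sample's intensity distribution is forced onto a
common reference (the per-rank mean), separately per channel and per
Infinium design type (type I and II probes have different intensity
distributions; a dasen-style pipeline first shifts type I intensities so
their low-intensity density mode matches type II's, then
quantile-normalizes each type).

Sex chromosomes break this. Under X inactivation, female X-linked CpGs
average an unmethylated active X and a largely methylated inactive X, so
their betas cluster at intermediate values; the male's single active X is
largely unmethylated, so male X betas skew low, at roughly half the total
intensity of female X (one copy instead of two). Y probes carry signal only
in males; in females they read background. When all probes enter one
quantile pool, these sex-specific insertions displace the ranks of
autosomal probes *differently in females and males*: probes below the
female X cluster are pushed down in females and up in males. The result is
a small but systematic artificial sex effect on thousands of autosomal
CpGs — significant sex-associated positions (saDMPs) that appear almost
exclusively "higher in males", and an inflated sex-explained fraction of
variance on autosomes.

## The two-step strategy

`adjustedNormalize()` avoids the leak:

1. **Autosomes alone.** The base normalizer (`dasenNormalize()`, a
   quantile-only variant, or any plug-in satisfying the per-stratum
   matrix-in/matrix-out contract) runs on autosomal probes only. Its type
   I/II alignment offsets are also estimated from autosomal probes, so no
   sex-probe value can influence any autosomal output (this is tested as a
   strict invariant: replacing sex-probe intensities with arbitrary values
   changes no autosomal corrected value).
2. **Sex probes by interpolation.** Within each stratum — channel (M, U)
   $\times$ design type (I, II) — and per sample, each sex-chromosome
   probe's raw intensity is placed at a fractional rank in the autosomal
   raw-intensity distribution (piecewise-linear interpolation between
   bracketing values; ties take average ranks), and that rank is read off
   the sorted corrected autosomal values. A sex probe whose raw value
   coincides with an autosomal probe's receives exactly that probe's
   corrected value; values outside the autosomal range clamp to the extreme
   ranks, so corrected sex intensities always lie inside the corrected
   autosomal range.

Betas are then recomputed from the corrected intensities. Sample sex is
never consulted, so the method needs no prior sex annotation and treats
karyotype anomalies evenly.

Interpolation runs on intensities, not betas: the beta transform is
nonlinear, and rank interpolation in intensity space composes with it
exactly. A beta-space plug-in route exists for matrices lacking channel
data but is non-canonical.

## Parameters that matter

* `offset` (default 100, intensity units): the beta denominator offset.
* `minAutosomal` (default 1000 probes): refuse interpolation when a
  stratum containing sex probes has a sparser autosomal grid; lower it
  deliberately for toy data.
* `minTypeProbes` (default 50): minimum probes per design type for the
  KDE-based mode alignment; below this the density estimate is unstable.
* `useChipRow` (default TRUE): when the sample sheet carries a chip row,
  per-sample alignment offsets are replaced by their least-squares fit
  against row position, smoothing estimation noise with the physical
  covariate it varies along.

Numerical conventions: quantile references are per-rank means over rows
complete in all samples; within a column, missing values are skipped and
fractional ranks rescale to the reference length; tied values share the
mean of the reference values their ranks span. The type I/II mode is the
first local maximum of a Gaussian-kernel, Silverman-bandwidth, 512-point
KDE exceeding 1% of the peak density, with parabolic refinement of the
peak position (the fixed grid otherwise quantizes the mode to the grid
step, which is coarse because the intensity range is dominated by the long
upper tail). Out-of-range interpolation queries clamp rather than
extrapolate, keeping corrected values inside the observed corrected range.

## Evaluation toolkit

**Gold standard (`singleSexGoldStandard()`).** In a single-sex group there
is no between-sex pattern difference, so normalizing sex chromosomes as
ordinary autosomes is legitimate and provides reference corrected betas.
The adjusted normalizer's interpolated betas are scored against them by

$$\mathrm{RMSE} = \sqrt{\tfrac{1}{m}\sum_{i=1}^m (\beta_i - \hat\beta_i)^2},$$

per sample, over X- and Y-linked probes, in four categories (sex
$\times$ chromosome). Female-Y RMSE is reported for completeness only:
females carry no Y, and those probes read background.

**Sex-explained fraction of variance.** With divisor-$n$ variances
($V_{total} = \frac{1}{n}\frac{1}{m}\sum_i\sum_j (\beta_{ij} -
\bar\beta_j)^2$, probe means within the relevant group),

$$F_{sex} = 1 - \frac{n_f V_{total,f} + n_m V_{total,m}}
{(n_f + n_m)\, V_{total}}$$

is exactly the between-sex fraction of the total sum of squares, hence in
$[0, 1]$; the test suite checks this against a brute-force ANOVA
decomposition to $10^{-12}$. A good normalizer lowers $V_{total}$
(technical variance) while preserving or raising $F_{sex}$ when a real sex
effect exists — and a sex-*biased* normalizer betrays itself by raising
$F_{sex}$ on autosomes where no true effect exists.

**Sex EWAS (`sexEWAS()`).** Per probe, the two-group linear-model F test
(1 and $n-2$ degrees of freedom, equal-variance form — the standard
linear-regression F test for a binary covariate) with Bonferroni
correction at $\alpha = 0.05$ and no further covariates. Zero-variance
probes are skipped. `compareSaDMPs()` decomposes two saDMP sets into
shared/specific counts by direction.

## What the simulator emulates — and what it does not

`simulateDataset()` inverts the beta formula: per probe a base beta is
drawn from its group's distribution, per sample it is jittered on the
logit scale (sd 0.1, keeping betas in (0,1)), a total intensity
$T$ is drawn log-normal (median 5000, sdlog 0.5), and the channels are
$M = \beta T f_M + b$, $U = (1-\beta) T f_U + b$ with per-sample
per-channel log-normal technical factors (sdlog 0.15), an additive
background $b = 300$ (non-specific hybridization anchors the
low-intensity mode), additive Gaussian noise (sd 50, floored at 0) and a
+500 type I intensity shift.

Group structure: autosomal betas come from a three-component Beta mixture
(weights 0.45/0.10/0.45, means 0.08/0.50/0.88) shared across sexes;
female X betas are intermediate (Beta with mean 0.45, concentration 20);
male X and male Y betas come from a low-dominated mixture (weights
0.8/0.2, means 0.08/0.80) with total intensity halved (one copy); female
Y cells read 5% of the autosomal intensity scale. Default probe counts
(50k autosomal, 1.2k X, 120 Y) keep the array's few-percent sex-probe
share at desk scale; optional planted autosomal effects add $\pm\Delta
\beta/2$ by sex at a chosen number of probes.

Not emulated: control probes, out-of-band signal and dye bias (needed only
for functional-normalization pipelines), probe-level SNP artifacts,
cell-type composition, and spatial chip effects beyond a random chip row.
Passing tests on this generator therefore demonstrate the *mechanism* —
rank displacement by sex-specific insertions and its repair — not parity
with any particular real cohort.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated data:
interpolation accuracy on a 50k-autosome single-sex design (12 males; 4
females added in the acceptance run), with the density trend checked at
5k/50k/200k; the bias audit on 20k autosomes + 480 X + 48 Y (the array's
sex-probe share) with 150 females and 150 males over five seeds, sized by
a power analysis of the measured artifact magnitude (beta shifts of
0.002–0.007 against within-sex noise of ~0.01 under a Bonferroni
threshold); EWAS calibration on 10k Gaussian probes with n = 100. At
these sizes the mixed ("dasen on everything") normalizer reproducibly
yields hundreds to thousands of Bonferroni-significant autosomal saDMPs
with no true effect planted, essentially all higher in males, while the
adjusted normalizer yields approximately none — the qualitative signature
reported for large real cohorts.

## Design choices where the design was open

* **Mode alignment before interpolation is autosome-only.** Estimating
  type I/II offsets on all probes would be slightly more stable but lets
  sex probes perturb autosomal output; the strict invariance was chosen.
* **Clamping, not extrapolation,** outside the autosomal raw range:
  corrected sex values stay in the observed corrected range at the cost of
  flattening extreme tails (flagged per probe via the clamp indicators).
* **"Weighted average of nearest neighbours" = linear interpolation.** For
  two bracketing neighbours the two phrasings coincide; the explicit
  rank-interpolation algorithm is implemented.
* **Two design-type levels (I/II).** Sub-channel splits (IGrn/IRed) belong
  to functional-normalization pipelines, which attach through the plug-in
  seam instead.
* **Divisor n everywhere** in variance computations, so the $F_{sex}$
  identity is exact; per-CpG boxplot variances use the same convention.
* **Bonferroni, not FDR,** for saDMP calls, and an equal-variance F test;
  both match common EWAS practice for this audit and keep the null
  calibration testable.

## Known limitations

* The gold-standard RMSE floor is set by the reference run's own
  type-alignment offsets (estimated with sex probes present) differing
  minutely from the candidate's autosome-only offsets; with a background
  anchor in the intensity model this floor decreases with probe density,
  but it never reaches zero.
* Interpolated Y-probe betas in females are background readouts; they are
  normalized consistently but carry no biology.
* `chipRow` is the only chip-geometry covariate; full positional models
  are out of scope.
* The plug-in seam passes per-stratum matrices; base normalizers needing
  control probes or sample covariates must close over them.

## A worked run

```{r example, eval = FALSE}
sim <- simulateDataset(simConfig(nAuto = 20000, nX = 480, nY = 48,
                                 nFemale = 150, nMale = 150, seed = 1))
adj <- adjustedNormalize(sim$data, "dasen")
mix <- dasenNormalize(sim$data, "all")
varianceReport(adj)
compareSaDMPs(sexEWAS(mix, scope = "autosomes"),
              sexEWAS(adj, scope = "autosomes"))
```

The README shows the numbers such a run prints; `scripts/acceptance.R`
recomputes them from scratch for any seed.
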