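---
title: "Methods: thresholding and RISH harmonization of multi-site structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thresholding and RISH harmonization of multi-site structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in `rishnet`, the assumptions
behind them, the synthetic data generator that stands in for multi-site
patient cohorts, and the numerical and design choices that a maintainer
would otherwise have to reverse-engineer from the code.

## The analysis pipeline

The package analyses case–control structural connectomes from several
acquisition sites. Per subject the inputs are a symmetric streamline-count
matrix and an FA-weighted matrix over a fixed parcellation (90 nodes by
default). The pipeline is:

1. **Binarize** counts (an edge exists if at least one streamline connects
   the node pair) and average binary matrices within a group into a
   *connection-probability matrix*; average FA over the subjects that
   possess each edge into a *group FA matrix*.
2. **Consistency** between sites $a,b$ is the edgewise relative difference
   $100\% \times |a - b| / ((a+b)/2)$, summarised by its mean over the union
   support ($a + b > 0$). Values live in $[0, 200]$; 200 marks an edge seen
   at one site only.
3. **Threshold** each site's probability matrix to a fixed density $d$:
   keep the $K = \lfloor d \, n(n-1)/2 \rfloor$ highest-probability edges.
4. **Harmonize** the diffusion signal across scanners with RISH features
   (below), then recompute FA-weighted matrices.
5. **Edgewise statistics**: per edge, residualize FA on age and sex over the
   usable subjects, compute the pooled two-sample $t$ (controls − patients)
   and Cohen's $d$, permute group labels for empirical $p$-values, apply
   Benjamini–Hochberg across edges.
6. **Score** staged detections ($d > 0.8$; ∩ mask; ∩ $q < 0.05$) against a
   reference edge set: $\mathrm{precision} = TP/(TP+FP)$, and the count of
   FDR survivors as the sensitivity indicator.

## RISH harmonization

The diffusion-weighted signal on the sphere is expanded in the real,
even-order spherical-harmonic basis up to $l_{\max} = 6$ (28 coefficients;
antipodal symmetry makes odd orders vanish). Fitting is ordinary least
squares on the $b \ne 0$ measurements after dividing by the voxel's mean
$b = 0$ signal; the basis is orthonormal with the Condon–Shortley phase, the
convention of common dMRI tooling. The order-$l$ power
$E_l = \sum_m c_{lm}^2$ is invariant to rotations of the sampling frame
(property-tested to $10^{-3}$ relative under random rotations), which is
what makes it a pure scanner-effect readout: it ignores fibre orientation.

Scale maps between a site and a reference are estimated from matched
controls (15 per site by default; 15–20 controls suffice to capture
group-level scanner properties rather than individual anatomy):

$$ s_l(v) = \sqrt{ \overline{E_l^{\mathrm{ref}}}(v) \; / \;
                   \overline{E_l^{\mathrm{site}}}(v) } $$

with the arithmetic mean over control subjects, and the guard $s_l = 1$
where the site's mean power is zero (no order-$l$ energy to rescale).
Harmonization multiplies each voxel's order-$l$ coefficients by $s_l$ and
resynthesizes the signal; $b=0$ measurements pass through unchanged. Because
the maps are group-level and monotone, within-site rank orders of subject
features are preserved — harmonization removes the site effect, not
between-subject variation. Self-harmonization is the identity.

Two deliberate simplifications relative to a full neuroimaging deployment:
the package works on a common voxel grid that plays the role of the
template space (spatial registration is out of scope), and only single-shell
schemes are supported (each site one nonzero $b$-value, as in typical
clinical SVD protocols). Whether $b=0$ normalization precedes the SH fit is
not a settled convention; here it does, and the stored $b_0$ restores
physical units on resynthesis.

## Tensor FA

FA enters as the edge weight, so the package includes a plain log-linear
least-squares tensor fit: regress $\log S$ on the six tensor components and
an intercept, take eigenvalues (a vectorised closed-form symmetric
$3\times3$ solver, verified against `eigen()`), and
$\mathrm{FA} = \sqrt{3/2}\,\|\lambda - \bar\lambda\| / \|\lambda\|$, clamped
to $[0,1]$. Robust tensor estimators and Rician bias correction are out of
scope; noise is treated as Gaussian throughout.

## The synthetic generator

The generator emulates the study design of a multicentre SVD analysis at
desk scale, with ground truth known by construction:

* **Network truth.** 90 nodes; 600 core edges with per-edge detection
  probability drawn from $U(0.60, 0.95)$ — the shared architecture every
  site should recover; 60 *affected* edges sampled among core edges with
  probability $\ge 0.8$ (the planted disease effect should live in the
  high-probability network that thresholding retains, mirroring how a
  reference standard is itself defined after thresholding); spurious edges
  at a Poisson rate of 40 per subject, resampled uniformly over non-core
  pairs for every subject — this is what makes them low-probability at group
  level and inconsistent across sites, the signature of cumulative
  tractography error. The spurious rate is a free parameter (no published
  count exists to match); 40 per subject makes roughly a third of node
  pairs appear somewhere in a pooled 160-subject cohort while keeping
  per-site group probabilities of spurious edges an order of magnitude
  below core probabilities.
* **Edge FA through the signal model.** Each present edge gets a target FA
  (core baseline $U(0.30, 0.60)$, between-subject SD 0.03, minus
  $\texttt{burden} \times \texttt{disease\_delta}$ for affected edges in
  patients), realised as an axially symmetric tensor with random
  orientation and mean diffusivity $0.7\times10^{-3}\,\mathrm{mm^2/s}$
  (eigenvalues $\lambda_\parallel = \mathrm{MD}(1+2\delta)$,
  $\lambda_\perp = \mathrm{MD}(1-\delta)$ with
  $\delta = \mathrm{FA}/\sqrt{3-2\,\mathrm{FA}^2}$, exact by construction).
  The noise-free signal is projected onto the SH basis, order-$l$
  coefficients are multiplied by $\sqrt{\text{scale}_l}$ — the site's
  scanner effect — the signal is resynthesized, Gaussian noise of SD 0.02
  (fraction of $b_0$) is added, and FA is re-fit. Harmonization therefore
  has to undo the scanner effect in signal space to restore FA; nothing is
  drawn directly.
* **Sites.** Four sporadic-disease sites of 20 controls + 20 patients
  (pooling to 80 per group) with distinct per-order scalings (e.g. an
  $E_2$-suppressing scanner lowers FA, an $E_2$-raising one inflates it),
  plus a high-burden reference site (20 controls, 25 patients, disease
  effect ×1.5) that plays the monogenic-SVD role: its
  thresholding+FDR survivors define the reference edge set.
  `disease_delta = 0.040` was calibrated once against the generator's own
  realised FA dispersion (subject SD 0.03 plus noise-induced tensor-fit
  variability) so that the planted pooled effect lands near Cohen's
  $d = 1$, the regime the recovery property is specified in; it has not
  been revisited since.
* **Covariates.** Age normal (mean 70, SD 8) truncated to 50–90 years; sex
  alternating. They exist so that the adjustment machinery runs on real
  inputs; no demographic realism is claimed.
* **Phantoms.** For scale-map estimation, voxel phantoms share ground-truth
  SH coefficients across sites (mean DW level $U(0.4, 0.7)$ with per-order
  amplitudes decaying 0.12/0.05/0.02 for $l = 2/4/6$), per-subject
  multiplicative jitter (log-normal, SD 0.05) seeded site-independently,
  site scaling, and site-seeded noise. With no scanner effect and no noise,
  two sites' phantoms are byte-identical.

What the generator does **not** emulate: raw k-space/EPI artefacts, motion,
lesions, real tractography geometry, Rician noise, registration error, or
the demographics of any real cohort. Passing tests therefore demonstrate
that the pipeline's logic is correct and self-consistent under its stated
model — not that harmonization removes every scanner effect found in real
multicentre data.

## Statistics: choices that were genuinely open

* **Per-edge case exclusion.** Subjects lacking an edge are excluded from
  that edge's test rather than entered as FA = 0; absence is missingness,
  not low anisotropy. The same rule governs the group FA matrix (mean over
  possessing subjects). Consequently low-probability edges are tested on
  very few subjects — which is exactly why they generate unstable large
  effect sizes, and why thresholding improves precision.
* **Adjustment before permutation.** Age and sex are regressed out over the
  pooled usable subjects per edge; residuals are held fixed and group labels
  permuted (the Freedman–Lane simplification). Covariates that are constant
  among an edge's usable subjects are dropped from that edge's design.
* **Permutation p and FDR.** Two-sided
  $p = (1 + \#\{|t_\pi| \ge |t_{obs}|\})/(n_\pi + 1)$, so $p \ge
  1/(n_\pi+1)$; Benjamini–Hochberg across tested edges. An exhaustive mode
  enumerates all $\binom{n}{n_1}$ assignments (identity included) and is
  verified against brute-force enumeration. The default is 50,000
  permutations; all shipped analyses and tests use 1,000, which keeps the
  full experiment under a minute while leaving the $p$-value floor
  ($\approx 10^{-3}$) small enough for BH to operate at the shipped edge
  counts.
* **Signed effect gate.** Detection requires signed $d > 0.8$ (FA reduced in
  patients); an absolute-value gate is available as a flag. Whether the
  original convention was signed is not documented anywhere we could
  verify; the signed form matches the directional hypothesis.
* **Union-support summaries.** The consistency mean runs over edges nonzero
  at either site. The alternative (intersection) would ignore exactly the
  one-sided spurious edges the statistic is meant to expose.
* **Floor rounding of K.** $K = \lfloor \cdot \rfloor$ so realised density
  never exceeds the target and all sites get identical $K$; ties at the
  cutoff break lexicographically by node pair, making masks deterministic.
* **Scale maps on the phantom grid.** In the synthetic experiment the maps
  are estimated on the phantom voxel grid and collapsed to their per-order
  voxelwise mean before application to per-edge signals: the generator's
  scanner effects are global per order, so the maps are spatially flat up to
  noise and the mean is their natural summary on the edge "grid". With
  spatially varying scanner effects this collapse would be wrong; that
  regime is outside the generator's model.

## Problem sizes and runtime

The shipped configuration (4 + 1 sites, 205 subjects, 90 nodes, 300 phantom
voxels, 1,000 permutations, seven permutation analyses) runs the complete
experiment in well under a minute on one CPU; the test suite and the
acceptance script each stay within a few minutes. These sizes were chosen so
that every property — binomial detection frequencies, null calibration,
recovery of planted edges — has enough samples to be sharp while the whole
suite remains quick to iterate on.

## Known limitations

* Gaussian (not Rician) noise slightly understates FA bias at low SNR.
* The $l_{\max}=6$ truncation of a pure tensor signal is not exact, so
  generated FA differs from its target by a small deterministic amount;
  group contrasts are unaffected.
* Per-site analyses at 20 + 20 subjects have little power after FDR — by
  design, since the motivating argument is that pooling after harmonization
  is what buys sensitivity.
* Precision against the reference edge set inherits the reference's own
  sampling noise; precision against the planted truth is also reported in
  every experiment for that reason.
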