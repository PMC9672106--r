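---
title: "Brightness-based subunit counting: models, assumptions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brightness-based subunit counting: models, assumptions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toccsl)
```

## The problem

Membrane transporters and receptors often work as oligomers, and the
oligomeric state at the plasma membrane of a living cell is hard to see:
at physiological surface densities, diffraction-limited microscopy cannot
tell one labeled protein from a cluster of several. The TOCCSL trick
("thinning out clusters while conserving stoichiometry of labeling")
solves the crowding problem by photobleaching an aperture-confined region
of the membrane and letting intact, unbleached oligomers diffuse back in.
For a short window, the bleached region contains well-separated single
oligomers whose integrated brightness reports how many active
fluorophores they carry.

This package implements the full analysis chain for such experiments —
photon conversion, spot detection and Gaussian fitting, brightness-PDF
mixture decomposition, FRAP kinetics, and a subunit-exchange model —
together with a simulator that generates every input with known ground
truth.

## The brightness mixture model

Let $\rho_1(B)$ be the probability density of the measured brightness of
a single active fluorophore. Because the brightness of a spot carrying
$n$ independent fluorophores is the sum of $n$ single-fluorophore
brightnesses, the $n$-mer density is the $n$-fold autoconvolution
$\rho_n = \rho_1 * \cdots * \rho_1$. The observed single-spot brightness
density is modeled as the constrained linear combination

$$\rho(B) = \sum_{n=1}^{n_{max}} \alpha_n\, \rho_n(B),
\qquad \alpha_n \ge 0,\ \ \sum_n \alpha_n = 1,$$

and the mixture weights $\alpha_n$ are the oligomer fractions of
*visible* spots. The average oligomeric state is defined in this package
as the weighted mean $\langle n\rangle = \sum_n n\,\alpha_n$ (the source
literature uses the phrase without printing a formula; this definition is
declared here and used consistently).

Numerical choices:

* $\rho_1$ is a Gaussian kernel density estimate with Silverman's
  rule-of-thumb bandwidth, tabulated on a 1,024-point uniform grid from
  0 to $n_{max} \times 1.2\times$ the largest calibration sample, then
  renormalized to unit trapezoidal integral (KDE mass leaking below zero
  is discarded).
* Autoconvolution is computed by FFT on that grid and cross-checked in
  the test suite against a brute-force double-summation oracle to
  1e-10.
* The fit maximizes the sample log-likelihood
  $\sum_i \log \sum_n \alpha_n \rho_n(B_i)$ with the simplex enforced by
  a softmax reparameterization (BFGS with analytic gradient, two starts).
  Maximum likelihood was chosen over least squares on a histogram/KDE
  curve because it removes binning and bandwidth sensitivity from the
  estimate; the histogram least-squares estimator is kept in the package
  (`fit_mixture_lsq()`) as an independent cross-check and the two must
  agree within 0.05 on every $\alpha_n$ at 5,000 samples.
* $n_{max}$ defaults to 3: dimers are the largest species reported for
  this transporter family at the cell membrane, and one spare order lets
  the fit express higher oligomers if the data contain them. With
  $n_{max} = 1$ the fit returns $\alpha = (1)$ exactly.
* Samples outside the grid support are clipped to the support edge and
  counted (`n_clipped`); a sample with zero density under every
  component is an error, not a silent drop.
* Bootstrap SDs follow the published protocol exactly: random 50%
  subsamples without replacement, 100 repetitions, SD per $\alpha_n$.

## Monomer calibration must share the measurement noise

$\rho_1$ comes from a calibration measurement in which repeated partial
photobleaching leaves at most one active fluorophore per oligomer. A
subtle but important point, reproduced by this package's pipeline: the
calibration brightness values must be *measured through the same imaging
and fitting path* as the mixture data. Measured brightness carries shot
noise, read noise, and fit noise on top of the intrinsic fluorophore
variability; shot noise is additive-in-variance under convolution (a
dimer has twice the photons), but the per-measurement constant
(read-noise/fit) term is not. If $\rho_1$ were taken noise-free, the
autoconvolved $\rho_2$ would be broader than real measured dimers and the
weights would be biased. In simulate mode the pipeline therefore images
its calibration sample by default (`monomer_calibration$imaged`).

## The synthetic world

The simulator states one fixed world, used by every test:

* Composition 60% monomer / 40% dimer — the wildtype plasma-membrane
  composition of the transporter under study, used as simulation truth.
* Single-fluorophore brightness: lognormal with median 100 photons and
  geometric SD 1.4. The literature reports the estimation *procedure*
  but not the underlying law or photon yield; lognormal is the standard
  positively-skewed, strictly-positive choice for single-fluorophore
  brightness, and 100 photons/1.4 give realistic single-molecule SNR on
  the modeled camera. These are config defaults, not asserted literature
  values.
* `active_prob` defaults to 1 (every label fluorescent). Dark/immature
  GFP is available as an optional stressor but is not part of the
  baseline world, which reports apparent (visible-spot) fractions.
* Camera: offset 100 counts, inverse gain 4 photons/count, read noise
  0.5 counts RMS, 0.16 um pixels (100x objective on a cooled slow-scan
  CCD). The read-noise default was chosen so that a monomer's
  matched-filter response clears the detection threshold — a
  prerequisite of the technique itself; at 3x this read noise, single
  fluorophores drop below the 5-sigma threshold and the recovered
  fractions acquire a strong monomer-loss bias (measured during
  development, and documented as a limitation below).
* Spot rendering: integrated isotropic 2D Gaussian (PSF sigma 1.2 px),
  per-pixel Poisson shot noise, Gaussian read noise, rounding and
  clipping to 16 bit. With `noise = FALSE` the exact expectation image
  is returned un-rounded so closed-form totals can be asserted.
* TOCCSL timing defaults follow the published protocol (2,000 ms bleach,
  5,000 ms recovery, 5 ms exposures). Bleaching is applied as a single
  aperture mask at the bleach midpoint; diffusion during the 2 s bleach
  window is ignored for simplicity, so aperture-edge effects are not
  emulated.
* Bleaching is *spot-wise* (all fluorophores of one oligomer co-diffuse,
  hence co-bleach), while exchange re-pairing is *fluorophore-wise*:
  after $r$ rounds with per-round survival $s$, an exchanging $n$-mer
  carries Binomial($n$, $s^r$) active fluorophores. This is exactly the
  dichotomy that separates the stable-dimer scenario (unchanged
  composition, fewer spots) from the exchanging scenario (rising
  apparent-monomer fraction).
* Prebleach fields are Poisson in number (density x area) with uniform
  positions; default density 0.5 spots/um^2 for prebleach fields and
  0.06 spots/um^2 for postbleach-like sparse frames, matching the
  single-molecule regime the method needs.

What the generator does **not** emulate: triplet blinking, EMCCD excess
noise, TIRF evanescent-field weighting of intracellular signal, drift,
or uneven illumination. A green test therefore establishes correctness
of the analysis chain on an idealized but noise-faithful experiment, not
robustness to every instrumental artifact.

## FRAP and exchange statistics

Recovery traces follow the one-phase association model
$I(t)/I_0 = mf\,(1 - e^{-Kt})$ with mobile fraction $mf$ and rate
constant $K$. The fit is plain nonlinear least squares (`nls`, port
algorithm, $mf \in [0, 1.5]$, $K > 0$), initialized from the tail mean
and the half-recovery time; the 95% CI comes from the parameter
covariance. A constant trace is reported as $mf = \max(0,\bar I)$ with
$K$ undefined rather than an error. Acquisition-photobleaching
correction is not applied (not part of the modeled protocol), and no
diffusion coefficient is derived.

Repeated-run series are compared with the Friedman test (cells as
blocks) followed by Dunn's posthoc of each later run against run 1 on
within-cell rank means, with Bonferroni-style correction over the number
of comparisons. Density-vs-oligomeric-state association uses Spearman
correlation; condition comparisons use the two-tailed Mann-Whitney test.
No multiplicity correction is applied outside the posthoc, matching
standard practice for these designs. The exchange model predicts
apparent fractions given the active-molecule fraction $q$; it
deliberately introduces no kinetic rate constant and does not invert for
an exchange rate, because only snapshot data are modeled.

## Degenerate inputs and tie-breaks

* Zero-variance ("delta") brightness laws are supported throughout and
  used for exact bookkeeping tests.
* Detection keeps strict local maxima (plateau ties broken by scan
  order); an all-constant image yields no candidates because the robust
  threshold (median + k x 1.4826 MAD, k = 5) is exceeded strictly.
* Candidate pairs closer than 4 x PSF sigma are both discarded: two
  oligomers that close cannot be attributed separate brightnesses.
* If two mixture components have essentially identical support the
  optimizer may split weight between them; the fitted vector is reported
  as-is, without pruning.

## Known limitations

* **Sub-diffraction merging.** Two molecules closer than ~2 PSF sigma
  produce a single intensity maximum and are indistinguishable from one
  oligomer by any detector. The proximity rule rejects *resolvable*
  close pairs; merged blobs enter the brightness table as single spots.
  A second-moment anisotropy rejection was evaluated and rejected: at
  single-fluorophore photon counts the shape statistic of noisy monomers
  overlaps that of merged pairs, so it mostly discards true monomers.
  TOCCSL's sparsity keeps accidental merging rare.
* **Detection selection bias.** Near the detection threshold, dim
  monomers are found less efficiently than dimers; at the default SNR
  this depresses the recovered monomer fraction by a few percentage
  points in the full image pipeline (the sample-level fit is unbiased).
  The effect is visible in the end-to-end test tolerance (0.05 vs 0.03
  at the sample level) and would equally affect a real instrument at
  marginal SNR.
* **Partial bleaching of dimers** during repeated runs slightly inflates
  apparent exchange; no correction is applied, as in the modeled
  protocol.
* The apparent fractions are not corrected for incomplete fluorophore
  maturation; they describe visible spots.

## What the tests establish

Every stage is validated against an independent oracle: closed-form
moments for the generators, forward-rendered images for detection and
fitting, brute-force convolution and enumeration oracles for the mixture
and exchange models, and a histogram least-squares cross-fit for the
likelihood estimator. The acceptance-level checks recover the wildtype
composition (60/40 within 3 points at 5,000 spots), the wildtype mobile
fraction (89% within the printed 2-point interval over ten noisy
traces), and the stable-vs-exchanging dichotomy. Quantities that depend
on wet-lab data (the real-cell density correlation, drug-induced
changes) are covered only by property-based analogues: null-calibration
of the correlation and power checks of the condition comparison on
synthetic groups.
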