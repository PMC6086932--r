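---
title: "Nanoscale analysis of endocytic sites: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanoscale analysis of endocytic sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endonano)
```

## The scientific problem

Clathrin-mediated endocytosis in budding yeast is driven by several dozen
proteins that assemble at the plasma membrane, bend it against turgor
pressure, and pinch off a vesicle. Single-molecule localization microscopy
(SMLM) of fixed cells, with the focal plane at the cell bottom, yields 2D
projections of individual endocytic sites: each tagged protein appears as a
cloud of localizations whose lateral organization — filled patch, ring with
a central hole, or projected dome — reflects its role in the machinery.
Because fixation freezes each site at a random moment of its lifetime,
thousands of snapshots sample the whole process, and a diffraction-limited
marker channel (whose intensity grows over the site's lifetime) orders the
snapshots in pseudo-time.

`endonano` implements this analysis chain end to end: simulation of raw
data with known ground truth, emitter localization, localization
post-processing, segmentation, geometric model fitting and averaging,
pseudo-time staging, side-view temporal reconstruction, and the closed-form
force/rate laws used to reason about actin-driven membrane invagination.

## The geometric site model

A site's rendered image is fitted with an annular density blurred by the
localization precision:

$$ f(X,Y) = A\left[\operatorname{erf}\!\frac{r_\mathrm{out}-R}{\sqrt2\,\sigma}
           - \operatorname{erf}\!\frac{r_\mathrm{out}-dr-R}{\sqrt2\,\sigma}\right],
   \qquad R = \sqrt{(X-x_0)^2+(Y-y_0)^2}, $$

with fixed $\sigma = 15$ nm representing the expected localization spread.
Rings have $dr < r_\mathrm{out}$ (a central hole), patches have
$dr \ge r_\mathrm{out}$. The four shape parameters
$\{x_0, y_0, r_\mathrm{out}, dr\}$ are found by least squares on a 3 nm
rendering; the amplitude $A$ enters the residual linearly and is profiled
out exactly at every optimizer step, which reduces the search to four
dimensions.

Numerical choices:

* **Optimizer.** Bounded Nelder–Mead with perturbed restarts (default 3),
  tie-broken by residual sum of squares. The erf model is mildly
  non-convex (ring/patch boundary, center vs. rim trade-offs) but has no
  useful analytic gradient once rendering noise is present; a
  derivative-free simplex with restarts is robust and, on ideal model
  images, reproduces parameters to better than $10^{-2}$ nm over a grid of
  ring and patch geometries (verified in the acceptance suite).
* **Bounds.** $r_\mathrm{out} \in [5, 300]$ nm, $dr \in [5, 600]$ nm;
  initialization from the localization centroid and RMS radius.
* **Rendering for fitting.** Sites are rendered as near-histograms (6 nm
  floor kernel), *not* with per-record precision kernels. The blur
  observed in such an image is the true localization scatter, which the
  model's fixed $\sigma$ already represents; rendering each record with its
  precision would count the localization error twice and biases
  $r_\mathrm{out}$ upward by roughly 8 nm at 15 nm precision. Display
  renderings (`render_image`) do use $\max(\text{precision}, 6\,\text{nm})$
  kernels, as usual for SMLM visualization.
* **Patch identifiability.** For $dr \gg r_\mathrm{out} + 3\sigma$ the
  inner erf term saturates and $dr$ is no longer identifiable — any
  sufficiently large $dr$ gives the same filled disk. Parameter-recovery
  claims are therefore made on geometries where the inner edge is inside
  the field.

Exclusion rules after fitting: sites with fewer than 30 localizations are
always excluded (`few_locs`); under the `"general"` policy, fitted
$r_\mathrm{out} < 30$ nm is also excluded (`small_radius`). Proteins that
genuinely form small structures (coat and scission components) use the
`"coat_scission"` policy, which applies only the count rule — otherwise the
size cut would bias their radius distributions.

Averaging (`align_and_average`) translates every site by its fitted center,
sums the renderings, and averages radial profiles (5 nm bins,
annulus-area-normalized). The summary reports mean/SD/SEM of
$r_\mathrm{out}$, the ring fraction (hard cut $dr < r_\mathrm{out}$; the
boundary $dr = r_\mathrm{out}$ counts as patch), and the half-width at half
maximum of the average profile (linear interpolation on the first crossing
below half maximum). Shape classification: *dome* if mean
$r_\mathrm{out} > 80$ nm **and** central density exceeds 80% of the profile
maximum (a large structure whose center is nearly filled is read as the
projection of a hemispherical network); otherwise *ring* or *patch* by the
average $dr$ vs. $r_\mathrm{out}$.

## Localization: detection and Poisson MLE

Peaks are detected per frame by B3-spline smoothing, à-trous wavelet
background subtraction (level 3 by default), thresholding at
`threshold_factor` × the robust noise SD (1.4826 × MAD of the filtered
image — the "dynamic threshold" is deliberately parameter-light), and
non-maximum suppression. Candidates must be local maxima of both the
filtered and the smoothed image; this rejects the ringing side lobes that
background subtraction creates around bright spots.

Each candidate ROI (13 px default) is fitted with a pixel-integrated 2D
Gaussian plus constant background under a Poisson likelihood, by damped
Fisher scoring (expected information, Levenberg damping), at most 50
iterations, convergence when every parameter moves less than $10^{-3}$ of
its unit. The PSF width is fitted by default (the 175 nm width filter
needs it); a fixed-width mode exists. Localization precision is the square
root of the CRLB diagonal. The acceptance suite verifies that the
empirical scatter of fitted positions is within 15% of the numerically
computed information bound at 1000 photons over background 10.

## Post-processing

* **Grouping** (75 nm radius, 1-frame gap): greedy per-frame
  nearest-neighbour chaining; merged records take the photon-weighted mean
  position, summed photons, first frame, and inverse-variance recombined
  precision $(\sum \sigma_i^{-2})^{-1/2}$. The paper-style rule does not
  say whether precision is recombined or inherited; inverse-variance
  recombination is the statistically consistent choice for averaged
  positions.
* **Filtering**: precision ≤ 30 nm and fitted PSF SD ≤ 175 nm, boundary
  values kept.
* **Drift correction**: ten time windows, all pairwise window shifts by
  FFT cross-correlation with 3-point quadratic sub-pixel interpolation,
  least-squares solution of the redundant shift system with window 1 as
  gauge, cubic-spline interpolation to per-frame drift. Movies shorter
  than 5000 frames, or with estimated maximal drift under 10 nm, are
  returned unchanged with a skip flag.
* **Channel registration**: normalized-DLT homography from bead-like
  control points (≥ 5, non-collinear), with field-wide accuracy better
  than 10 nm at 3 nm point noise verified in the acceptance suite.

## Staging by marker intensity

The marker image is the maximum projection of the 7 z-slices around focus,
background-subtracted with a level-3 wavelet filter. Site intensity is the
amplitude of the first of three Gaussians: one fixed at the mapped site
center and two free ones constrained ≥ 350 nm away (from the center and
from each other) that absorb overlap from proximal sites. Because the
wavelet subtraction is linear, the fitted templates are themselves
background-filtered the same way; the template also uses the stack's
defocus model (pixel-integrated, max-projected), so noiseless recovery is
exact rather than biased by the filter.

One subtlety of max projection deserves note: the pixelwise maximum over
noisy slices is inflated (Jensen's inequality — about $+0.8$ noise SD at
the spot center, i.e. several percent of the amplitude at moderate SNR).
The estimator therefore computes the expected inflation analytically from
the fitted spot model under a normal approximation to the Poisson slice
noise, scales it by an empirical dispersion estimate (so noiseless input
is untouched), subtracts it, and refits the amplitudes. This brings the
amplitude bias at SNR 20 from ≈ +3% down to ≈ +1–1.5%.

Binning: sites brighter than 1.5 × the 80th percentile are excluded
(overlapping signal of > 2 sites); of the rest, intensity < 0.1 × the
post-exclusion 80th percentile forms the "no marker" bin, and the
remainder is split into three contiguous equal-count bins (low/medium/high,
remainders to the lower bins). Quantiles use the type-7 (linear
interpolation) convention — the source procedure does not fix one, so one
is fixed here and recorded. The "no" threshold uses the post-exclusion
percentile (flagged in the output); with every intensity zero the whole
cohort is "no". Staging is scale-invariant by construction.

## The synthetic-data generator

The generator emulates, with known parameters, exactly the features the
pipeline consumes:

* **Structures**: rings/patches sampled uniformly (by area) on the annulus
  $[\max(0, r_\mathrm{out}-dr), r_\mathrm{out}]$ — the $\sigma \to 0$
  limit of the erf model; domes sampled uniformly on a hemisphere and
  projected orthographically.
* **Blinking**: geometric blink counts (support ≥ 1, mean `mean_blinks`,
  default 3) in runs of consecutive frames with occasional 1-frame gaps
  (probability 0.2). The fluorophore's true photophysics is not published;
  a memoryless one-parameter law is the minimal choice consistent with the
  grouping rules.
* **Precision**: per-blink truncated Gaussian (mean 15 nm, SD 5 nm, floor
  1 nm) — typical spreads for photoconvertible-protein SMLM at the
  camera settings the pipeline targets.
* **Frames**: pixel-integrated PSFs (σ 130 nm on 100 nm pixels), constant
  background, per-pixel Poisson noise.
* **Marker stacks**: Gaussian spots whose width grows and amplitude falls
  with defocus (depth scale 400 nm), 50 nm z-steps, linear superposition,
  optional Poisson noise.

What it does **not** emulate: EM-gain excess noise, pixel-dependent sCMOS
noise, 3D PSF shapes, fixation artifacts, and structured (non-uniform)
background. A green test therefore establishes correctness of the
algorithms on data matching the stated noise model, not robustness to
every instrumental artifact.

Coordinates are nm, origin at the field corner, and pixel $(i,j)$ covers
the half-open square $[i p, (i+1)p)$ — one fixed convention used
everywhere.

## Actin force and rate laws

The closed-form laws are implemented as unit-tagged functions:
Brownian-ratchet polymerization $k_+ = k_\mathrm{on} A_1 e^{-f\delta/k_BT}$
with $\delta = 2.8$ nm; stall force
$f_0 = k_BT \ln(A_1/A_1^*)/\delta$, $A_1^* = k_\mathrm{off}/k_\mathrm{on}$;
Kramers crosslinker unbinding $k_u = k_\mathrm{off}^0 e^{f/f_u}$
($k_\mathrm{off}^0 = 0.025\,\mathrm{s}^{-1}$, $f_u = 10$ pN); and the
piecewise invagination resistance (0 for $L\le0$; $f_0 + k_\Pi L$ on
$(0, L_0)$; 0 beyond the snap-through depth $L_0 = 60$ nm, with
$f_0 = 200$ pN and the peak pinned at 1000 pN).

Two documented inconsistencies in the printed parameter set are resolved
as follows. First, $k_\mathrm{on}$ printed as "400 s⁻¹" only yields a rate
when multiplied by a concentration; it is treated as
per-µM-per-second. Second, with the printed numbers the stall-force
formula gives ≈ 13.7 pN, not the ~9 pN quoted alongside it; the package
exposes the formula and its consequences (the tests pin 13.7 and the
algebraic identity $k_+(f_0) = k_-$), not the quoted value. $k_BT$
defaults to 4.114 pN·nm (25 °C, the temperature is not stated) and is
configurable.

## Known limitations

* Grouping is greedy per frame; at very high per-frame emitter densities
  (several active emitters within 75 nm simultaneously) distinct molecules
  are merged, as with any gap-tolerant chaining rule.
* The fitted $dr$ of noisy rings is biased upward by a few nm (rim
  thickness convolves with sampling noise); $r_\mathrm{out}$ is much
  better behaved (sub-nm bias at 300 localizations). Averaged summaries
  inherit this asymmetry.
* Dome classification uses the stated two-threshold rule only; no attempt
  is made to fit a 3D model to the projection.
* Side-view rotation angles are taken as supplied (they are determined
  manually upstream); only alignment, ordering and windowed averaging are
  automated.
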