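# endonano

Nanoscale geometric analysis of endocytic sites from single-molecule
localization microscopy (SMLM) data.

## What this is for

In budding yeast, clathrin-mediated endocytosis is carried out by a
self-assembling machine of dozens of proteins. Imaged from below in fixed
cells, each endocytic site appears in SMLM as a 2D cloud of localizations
whose lateral shape — a filled **patch**, a **ring** with a central hole,
or a projected **dome** — encodes how that protein is organized on the
membrane. `endonano` provides the full analysis chain for such data, for
microscopists and modelers who want reproducible, testable site-level
geometry:

1. **Simulation** (`structure_spec`, `emit_localizations`,
   `render_frames`, `gen_gfp_stack`) — every input the pipeline consumes,
   generated from known ground truth so all downstream stages can be
   validated by parameter recovery.
2. **Localization** (`detect_peaks`, `fit_mle_gaussian`,
   `localize_frames`) — wavelet background subtraction, non-maximum
   suppression, and pixel-integrated Gaussian fitting by Poisson MLE with
   CRLB precision estimates.
3. **Post-processing** (`group_localizations`, `filter_localizations`,
   `render_image`, `drift_correct`, `estimate_channel_transform`) —
   blink grouping (75 nm, 1-frame gap), quality filtering (precision
   ≤ 30 nm, PSF σ ≤ 175 nm), Gaussian rendering, redundant
   cross-correlation drift correction, projective channel registration.
4. **Segmentation** (`segment_cells`, `cell_bottom_region`,
   `segment_sites`) — cells by large-blur peak detection; analysis
   restricted to the shrunk convex hull of the cell bottom; sites by
   thresholded peaks with a size cap for juxtaposed double sites.
5. **Geometry** (`fit_site`, `radial_profile`, `align_and_average`,
   `classify_shape`, `rank_sum_test`) — the core erf ring/patch model

   ```
   f(X,Y) = A [ erf((r_out − R)/(√2 σ)) − erf((r_out − dr − R)/(√2 σ)) ],
   R(X,Y) = √((X−x0)² + (Y−y0)²),  σ = 15 nm fixed
   ```

   fitted by least squares on a 3 nm rendering with A profiled out;
   rings have `dr < r_out`, patches `dr ≥ r_out`; site averaging, radial
   density profiles, and dome/ring/patch classification.
6. **Staging** (`gfp_site_intensity`, `stage_sites`,
   `sideview_reconstruct`) — pseudo-time ordering of snapshots by
   diffraction-limited marker intensity (triple-Gaussian fit with ≥350 nm
   neighbour constraints; no/low/med/high bins by percentile rules) and
   running-window side-view averages.
7. **Actin laws** (`polymerization_rate`, `stall_force`,
   `crosslinker_unbinding_rate`, `invagination_resistance`) — closed-form
   Brownian-ratchet, Kramers unbinding, and piecewise membrane-resistance
   laws with unit tagging.

## Worked example

Simulate a ring-shaped site, localize it from raw frames, and recover its
geometry:

```r
library(endonano)
set.seed(1)

spec <- structure_spec("ring", center = c(1600, 1600),
                       r_out = 70, dr = 30, n_molecules = 300)
man  <- ground_truth_manifest(list(spec), n_frames = 1200)
em   <- emission_model(mean_blinks = 1.3, precision_mean = 15,
                       precision_sd = 0, photons_mean = 2000)
tab  <- emit_localizations(man, em)

cam   <- list(pixelsize_nm = 100, width_px = 32, height_px = 32,
              background = 10)
stack <- render_frames(tab, cam)
loc   <- localize_frames(stack, pixelsize_nm = 100)
loc   <- filter_localizations(group_localizations(loc))

fit <- fit_site(loc)
round(c(r_out = fit$model$r_out, dr = fit$model$dr,
        x0 = fit$model$x0, y0 = fit$model$y0), 1)
#>  r_out     dr     x0     y0
#>   69.0   42.9 1597.3 1599.6
```

The fitted outer radius (69.0 nm) recovers the simulated 70 nm ring from
raw camera frames; the fitted center lands within ~3 nm of ground truth.
The rim thickness `dr` runs several nm wide for a single noisy site — a
known, documented bias of the erf model at finite localization counts
(see the methods vignette, `vignettes/endocytic-site-analysis.Rmd`);
averaging over hundreds of sites, as the pipeline does, brings the median
`r_out` bias under 1 nm.

A command-line interface mirrors the library
(`inst/cli/endonano simulate|localize|postprocess|segment|fit-sites|stage|actin-laws`).

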