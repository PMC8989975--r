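---
title: "Models and methods behind fusulm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fusulm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(fusulm)
```

# What this package computes

`fusulm` implements the computational chain used to image hemodynamics in
small, deep neural structures — the motivating case is the trigeminal
ganglion of the rat — with ultrafast ultrasound:

1. **SVD clutter filtering** of beamformed ultrafast frame blocks and
   **Power Doppler** formation (functional ultrasound, fUS);
2. **GLM activation mapping** of the Power Doppler series against a
   stimulus regressor built from a four half-cosine hemodynamic response
   function (HRF), with Bonferroni-corrected Z-score maps, ROI extraction
   and percent blood-volume (dBV) quantification;
3. **linear mixed models** for evoked-response statistics across nested
   rats/acquisitions/stimulations, on signed-square-root-transformed dBV
   differences;
4. **ultrasound localization microscopy** (ULM): microbubble detection,
   optimal-assignment track linking, velocimetry and super-resolved
   density/velocity maps.

Because raw in vivo recordings are not required anywhere, the package ships
a first-class synthetic-data generator that emulates both acquisition types
with known ground truth; every stage is validated against that truth or
against independent closed-form oracles.

# Data model and conventions

Frames are `(n_z, n_x, n_t)` arrays: `z` is depth in mm, positive downward;
`x` is lateral position in mm; axis order matches the probe geometry.
Frames are complex-valued IQ data by default (the clutter filter and Power
Doppler are defined on complex ultrafast data); a real-valued mode exists
for simple tests. All dB parameters are amplitude ratios,
`20*log10(a1/a2)`.

The acquisition presets mirror the published sequences:

* `config_fus()` — ten plane waves from −10° to 10° at 5.5 kHz PRF,
  beamformed into blocks of 200 compound frames at 500 Hz. Note the
  compound framerate is *below* `PRF/n_angles` = 550 Hz: the hardware idles
  between blocks, so the package validates `framerate <= prf/n_angles`
  rather than strict equality.
* `config_ulm()` — five angles (−5…5°) at 5 kHz PRF, blocks of 400 frames
  at 1000 Hz (here `5000/5 = 1000` exactly), 750 blocks = 300 s, 12 mm
  depth.

# The synthetic functional acquisition

`simulate_functional_stack()` composes three additive parts, each drawn
from its own seeded random stream (so components generated separately sum
exactly to the composite):

**Tissue clutter** is a sum of `tissue_rank` separable space–time
components: smooth random spatial fields times oscillations spanning the
quasi-DC to cardiac-harmonic band (0.02–25 Hz), with amplitudes decaying
`tissue_decay_db` (default 6 dB) per rank — the smoothly decaying singular
spectrum of in vivo clutter. The oscillating components complete at least
one cycle per 0.4-s block so the clutter subspace keeps full numerical rank
inside each block. Tissue sits `tissue_to_blood_db` (default 40 dB, a
choice — the ratio is not published) above blood.

**Blood** is, per pixel, a complex Gaussian process with a Gaussian Doppler
spectrum, synthesised in the frequency domain per block. This is the
many-scatterer limit: an ensemble of unresolved red-cell scatterers with
mean axial velocity and an in-cell velocity dispersion has exactly these
second-order statistics. Defaults `doppler_hz = 250`, `spread_hz = 130`
follow from the imaged physiology: at a 15-MHz transmit
(wavelength ~103 µm) vessel speeds of 9–20 mm/s give Doppler shifts
2v/λ ≈ 175–390 Hz, aliased across the ±250 Hz band of the 500-Hz compound
framerate, and transit-time broadening through a ~100-µm resolution cell
adds ~50–100 Hz per vessel; a broad Gaussian centred near the band edge is
the simplest spectrum with those properties. The expected blood power at
pixel `p` is `baseline_map[p] * (1 + amplitude * r(t))` inside the
activation mask and `baseline_map[p]` outside, where `r(t)` is the
stimulation indicator convolved with the HRF and peak-normalised.

**Noise** is white complex Gaussian at `noise_db` (default −20 dB) relative
to the blood amplitude.

The ground truth returned with each simulation records the activation mask,
the amplitude, the response `r` at the Power Doppler frame times, the
baseline/stimulation classification of each frame, and the *expected*
`dBV_STIM`: because `r(t)` ramps with the HRF and never averages to 1 over
a stimulation window, a 10% power amplitude corresponds to an expected
`dBV_STIM` of roughly 6–7% under the corneal design — recovery is judged
against this expectation, not against the raw amplitude.

`simulate_functional_pd()` generates, filters and integrates one block at a
time with identical per-block random streams, so long acquisitions
(hundreds of blocks) never hold the ultrafast stack in memory.

# SVD clutter filtering and Power Doppler

Each contiguous block of `block_size` frames is reshaped to its Casorati
matrix (space × time) and the `n_remove` largest singular components are
projected out (60 for the functional preset, 10 for ULM; "first" singular
vectors = largest singular values, descending order). The projection is
computed from the eigendecomposition of the temporal covariance
`C^H C` — algebraically identical to truncating the SVD, but much faster
when `n_space >> n_t`. Complex data use the conjugate transpose; real data
degrade to the ordinary transpose.

Two properties deserve emphasis:

* **Idempotence is a property of the projector, not of re-estimation.**
  Projecting twice onto the same complement (`basis =` argument) is exact
  to machine precision. Re-*estimating* the subspace on filtered data
  necessarily removes the next-largest components instead — an intrinsic
  property of truncation filters, not an implementation artifact.
* **Broadband blood loses a fixed energy fraction.** Truncating 60 of 200
  temporal dimensions removes an O(30%) share of any broadband signal along
  with the clutter. This attenuation is common to all SVD clutter filters;
  it cancels in every relative quantity downstream (dBV is scale-invariant)
  and is accounted for by comparing filtered composites against the
  *identically truncated* blood-only component when validating clutter
  rejection.

Power Doppler integrates the energy of the filtered frames
(`sum_t |s|^2`, no normalisation by frame count, as the sequence
description states), giving one image per block — every 400 ms for the
functional preset. Trailing frames that do not fill a block are dropped
with a warning.

# Activation mapping

**HRF.** The canonical four half-cosine kernel has an optional initial dip
to `-c1` over `d1`, a rise to the unit peak over `d2`, a fall to `-c2` over
`d3` and an undershoot recovery over `d4`. Defaults
(`d = 0, 1, 2, 2` s, `c1 = 0`, `c2 = 0.3`) describe the fast rodent
blood-volume response; the published parameter values were obtained by
nonlinear fitting to measured responses and are not printed, so the
defaults are deliberate, exposed choices, and `fit_hrf_params()` performs
the same bounded nonlinear least-squares adjustment against a measured dBV
trace (L-BFGS-B, two starts). Duration pairs trade off against each other
under long stimulation blocks — the classic block-design identifiability
caveat — so a flat trace is flagged non-identifiable rather than fitted.

**Design and GLM.** The regressor is the causal convolution of the binary
indicator with the kernel on the paradigm's fine grid, sampled at the Power
Doppler block centres and peak-normalised; the design adds an intercept.
Per pixel, ordinary least squares gives `t = beta/SE`, a one-sided p
(activation = blood-volume increase; two-sided by flag), and
`Z = qnorm(1 - p)`. Significance is Bonferroni over all pixels in the frame
(no brain mask) at family-wise 0.05. Zero-residual pixels report Z capped
at 8.2 (p ~ 1e-16). No drift regressors, prewhitening, smoothing or
cluster-extent inference: the processing chain being modelled uses none.

**ROI and dBV.** The ipsilateral ROI is the 8-connected component of the
significance mask containing the maximal Z (ties broken in column-major
raster order); the contralateral ROI is its mirror image about a vertical
midline, pixel count preserved. The ROI-averaged series `s(t)` is expressed
as `dbv(t) = 100 (s - b)/b` with `b` the mean of `s` over frames whose
whole span has a strictly zero stimulation indicator — consequently the
baseline mean of `dbv` is exactly zero by construction, and `dbv` is
invariant to rescaling the series. Frames are classified "stimulation" if
they overlap any stimulation window; whether the baseline should also
exclude post-stimulus HRF-tail frames is unspecified in the source chain,
so the raw indicator rule is used as written.

The paradigm presets encode the published stimulation designs (corneal:
6 × 10 s / 20-s gaps / 30-s rests, 220 s total; von Frey: 4 × 5 s / 55-s
gaps / 60-s rests, 305 s; whisker trains: 6 × 20 s; capsaicin: one 180-s
application after a 60-s baseline, flagged *phasic* and unsuitable for
block-design GLM). The whisker preset's 30-s lead-in/out is a choice (the
published description omits it); the within-train 4-Hz deflections are
encoded as a filled block.

# Mixed-model statistics

Evoked-response summaries are compared with the two intercept-only nested
forms: `Y_ik = delta + R_i + W_ik` (one stimulation per acquisition) and
`Y_ijk = delta + R_i + A_ij + W_ijk` (acquisition within rat), fitted by
REML. `Y` is a dBV difference (e.g. ipsi − contra `dbv_stim`) transformed
by the signed square root `sign(x) sqrt(|x|)`. The literal reading of the
published transform text would map negative values to positive ones,
destroying the ordering the transform is meant to stabilise; the
sign-preserving form is used, with the literal form available for
comparison (`literal = TRUE`).

The fixed effect is tested with `F = (delta_hat/SE)^2` on 1 and, by
default, `n - 1` denominator df — the residual-df default of the
mixed-model environment the analysis chain comes from, and the choice under
which the one-observation-per-rat collapse reproduces the squared
one-sample t exactly; Satterthwaite df are available by flag. Random
effects are tested by REML likelihood ratio against the plain chi-squared
(1 df) reference — conservative, since the null variance sits on the
boundary; the 0.5/0.5 mixture is available by flag. Degenerate groupings
are flagged, never silently dropped: one observation per rat collapses to
an intercept-only linear model, and a two-level design with one acquisition
per rat is refitted as one-level with a warning. Residual normality uses
Shapiro–Wilk on the conditional residuals.

# Ultrasound localization microscopy

**Simulation.** Bubbles enter each vessel as a Poisson process thinned by a
hard-core exclusion (`min_spacing_mm`, default 0.4 mm): microbubbles travel
single file in a microvessel and cannot overlap, and pure Poisson arrivals
would occasionally spawn sub-PSF pairs that no localization algorithm can
separate. Each bubble advances `flow_speed/framerate` per frame along its
polyline, jittered across the lumen, and is rendered as a Gaussian blob
(`psf_sigma_mm`, default 45 µm ≈ the diffraction-limited PSF at 15 MHz)
with a fixed random phase and an amplitude in [0.5, 1.5]. Tissue uses the
same clutter model with defaults (rank 10, 3 dB/rank decay) that keep every
clutter component above the bubble signal — the regime the fixed
10-component cutoff is calibrated for.

**Detection.** Candidates are strict local maxima of the magnitude image
over a 3×3 window at or above `min_intensity`; exact plateau ties (a bubble
on a pixel boundary) keep the first tied pixel in raster order. Sub-pixel
refinement defaults to the three-point log-parabola vertex per axis, which
is *exact* for a Gaussian PSF and deterministic. The weighted centroid is
available (`refine = "centroid"`) but not the default: over a finite window
it shrinks sub-pixel offsets by tens of percent, and since inter-frame
displacements are themselves sub-pixel (10–20 µm against a 100-µm grid) the
shrinkage propagates directly into velocity estimates. When detections lie
within a few PSF widths, each one's estimated coherent Gaussian is
subtracted from its neighbours' stencils and the refinement repeated
(`deconflict = TRUE`) — the usual high-density localization remedy.

**Linking.** Between consecutive frames, detections are paired by an
optimal (Hungarian) assignment minimising total Euclidean distance, with no
link beyond `max_link_mm` and a non-link cost of `max_link_mm` per
unmatched detection — so the optimum links as many pairs as the gate
allows, then minimises distance. The solver is a Jonker–Volgenant
shortest-augmenting-path implementation validated against brute-force
enumeration. A missed detection terminates the track (`max_gap = 0`, as in
the classical tracker being modelled; gap closing is available). Tracks
shorter than `min_length = 4` points are discarded. Segment velocities are
`(delta position) x framerate`, attributed to the segment's starting point;
maps at the 6.5-µm reconstruction pitch count localizations (density),
average segment speeds per pixel (speed, signed `vz` separately for
up/down rendering) and average vectors on a coarser grid.

**A genuine limitation.** Projecting out *any* 10-dimensional temporal
subspace leaves each bubble's own projection behind as path-shaped sidelobe
residue (≈ −15 dB). On clutter-filtered movies this residue jitters
individual localizations by a few µm — comparable to the inter-frame
displacement — so *per-segment* speeds on filtered data carry tens of
percent of noise, while track-level and map-level averages remain accurate.
Tracking accuracy itself is therefore validated on clutter- and noise-free
dilute movies (where the per-segment speed error is at machine precision),
and the full filtered pipeline is validated on what it can honestly
deliver: vessel geometry in the density map and the ordering of the
across-vessel speed gradient.

# Problem sizes and numerical choices

The validation suite exercises the published acquisition geometry at
reduced spatial extent, chosen so the full suite runs in minutes: the
activation fixture uses a 64 × 64 grid (6.4 × 6.4 mm at the native 100-µm
pitch) with the full 220-s corneal paradigm — 550 blocks of 200 complex
frames, filtered with `n_remove = 60`; GLM calibration uses 100 null
simulations at the same grid and length; ULM recovery uses 20 blocks of
400 frames with three vessels at 10/15/20 mm/s in the dilute regime; mixed
-model recovery uses 500 replicates of 20 rats × 5 stimulations and 1000
null replicates for test calibration. Tolerances: energy partition and
projector idempotence at 1e-8/1e-10 relative; balanced REML against the
ANOVA closed form at 1e-6; dBV recovery within ±2 percentage points of the
ground-truth expectation; ≥80% activation-mask overlap; ≥95% of
ground-truth ULM segments recovered with <5% speed error.

Other numerical choices: per-block SVD uses the `C^H C`
eigendecomposition; eigenvalues are clamped at zero before square roots;
GLM p-values come from the t distribution on `n - 2` df; `qnorm` of
p-values below ~1e-16 is capped at Z = 8.2; ROI tie-breaks and detection
plateau ties are resolved in column-major raster order for determinism;
all random streams derive from a single seed through per-stage hashes, so
every component and block is independently reproducible.

# Worked example

```{r example, eval = FALSE}
# a short functional acquisition with a known 10% response
cfg <- config_fus(n_blocks = 550, depth_mm = 6.4, width_mm = 6.4)
paradigm <- paradigm_preset("corneal_mech", dt = 0.1)
mask <- matrix(FALSE, cfg$n_z, cfg$n_x); mask[28:34, 20:26] <- TRUE

sim <- simulate_functional_pd(cfg, activation_mask = mask, amplitude = 0.10,
                              paradigm = paradigm, seed = 7)
X   <- build_design(paradigm, hrf_params(), 550, 0.4)
map <- glm_fit(sim$pd, X)
roi <- extract_roi(map)
dbv <- delta_bv(sim$pd, roi, paradigm)
glance(dbv)
autoplot(map); autoplot(dbv)
```

# Known limitations

* No beamforming: the package starts from beamformed, compounded frames
  (angles and PRF are carried as metadata only).
* No motion correction, spatial smoothing or cluster-extent inference in
  the GLM; no 3-D reconstruction or atlas registration.
* The simulator reproduces the statistical structure the analyses assume —
  low-rank clutter, Gaussian Doppler blood, Gaussian-PSF point scatterers —
  not acoustic propagation or speckle physics. Passing tests therefore
  demonstrate correctness of the analysis chain under its own model
  assumptions, not performance on arbitrary in vivo data.
* Per-segment ULM velocities on clutter-filtered data are jitter-limited
  (see above); map- and track-level speeds are the robust quantities.
* Vessel-diameter estimation from track density profiles is deliberately
  not provided: the published diameters come from a measurement procedure
  that is not described, so any implementation would be unvalidatable.
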