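---
title: "Methods: engulfment volumetry, adaptation-ratio classification, and estimation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: engulfment volumetry, adaptation-ratio classification, and estimation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engulfr)
```

## What the package measures

During early postnatal development, myelinated low-threshold (A-fiber)
touch afferents withdraw their terminals from the superficial dorsal horn,
and microglia participate by phagocytosing fiber material. The package
implements three quantitative readouts of this biology:

1. **Engulfment volumetry.** In a 3-channel confocal z-stack (microglia,
   Iba1; microglial lysosomes, CD68; fiber reporter), each channel is
   binarized and three nested volumes are measured per field of view:
   microglial volume, microglial lysosome volume (CD68 ∩ Iba1), and
   engulfed fiber volume (fiber ∩ CD68 ∩ Iba1). Volumes are foreground
   voxel counts times the physical voxel volume in µm³.
2. **Synaptic puncta density.** A synaptic-stain channel is binarized,
   26-connected 3-D components are labeled, an optional minimum-size filter
   applied, and object count plus total volume reported.
3. **Spike-train classification.** Dorsal-horn wide-dynamic-range neurons
   are split into *adapting* (putative excitatory) and *nonadapting*
   (putative inhibitory) groups from their response to a threshold von
   Frey stimulus, via the adaptation ratio
   `R = spikes(0.5–1 s) / spikes(0–0.5 s)`.

Group comparisons use estimation statistics: unpaired mean differences
with 95% bias-corrected-and-accelerated (BCa) bootstrap intervals (5000
resamples), two-sided permutation p-values, and Welch's *t* as a
conventional companion.

## Imaging model and parameter choices

- **Thresholding.** Default is Otsu's method per channel (exhaustive
  maximisation of between-class variance over 256 bins), with a fixed
  per-channel override; the method and value are always recorded in the
  output for provenance. On phantom data of known amplitude we use the
  fixed half-amplitude threshold — the half-maximum volume criterion —
  because Otsu is unreliable when foreground occupies a tiny fraction of
  the volume (the engulfed-fiber channel), a known failure mode of
  between-class-variance thresholding on sparse images.
- **Connectivity.** 26-neighbourhood in 3-D, matching common 3D object
  counters: diagonally bridged voxels belong to one object.
- **Windows and coordinates.** Half-open intervals everywhere. ROI
  micrometre coordinates map to 0-based half-open voxel intervals with the
  origin floored and the far edge ceiled, so the crop always covers the
  requested field (e.g. a 245 µm × 65 µm lamina field at 0.5 µm/voxel is
  exactly 490 × 130 voxels).
- **Anisotropy.** Handled by volume weighting only (count ×
  dz·dy·dx); binary masks are never resampled to isotropic grids, which
  would interpolate object boundaries.
- **Quality control.** Animals contributing fewer than 6 analyzed sections
  are flagged (not dropped), following the sampling rule the assay was
  designed around; recording depths outside 200–550 µm are likewise
  flagged.

## The phantom generator: what it emulates, what it does not

`gen_engulfment_phantom()` builds the nested-compartment structure the
engulfment measurement assumes: spherical microglia (radius scaled to the
field, 16% of the smallest physical extent), one concentric lysosome
sphere per cell whose volume is `lysosome_fraction` of the cell volume,
and fiber fragments as short cylinders. Engulfed fragments are compact
cylinders placed wholly inside a lysosome with a safety margin; free
fragments are thin cylinders (0.5 µm radius) placed clear of all
microglia. Ground truth is voxel-exact and always refers to the pre-blur,
pre-noise masks, so `engulfed ≤ lysosome ≤ microglia` holds identically.

Degradation is an isotropic Gaussian blur specified in µm (applied
per-axis in voxel units, edge-renormalised) followed by additive Gaussian
noise clipped at zero. The defaults (blur σ = 0.2 µm, noise SD = 10 on a
foreground amplitude of 200, i.e. 5%) are stated choices, not measured
acquisition statistics — no noise model for the source microscopes is
published, so reports must carry the spec used.

Two sizing choices matter and are deliberate:

- **Engulfed-fragment size.** Fragment radius is 0.64 of the lysosome
  radius (≈1.2 µm at the default geometry), about four times the largest
  supported blur σ (0.3 µm). Real engulfed fiber pieces (∼1–2 µm) are
  comfortably resolvable at the 63×/NA 1.4 resolution of the source
  imaging; the phantom keeps that regime. Objects near the blur scale
  would be systematically under-measured by any fixed-threshold
  volumetry (the half-max surface of a curved object retreats by ≈ σ²/2r),
  and that bias is a physics statement, not an implementation defect.
- **Known residual bias.** Even in the resolvable regime, half-max
  volumetry of the blurred phantom under-measures engulfed volume by
  ∼10–13% (curvature plus corner rounding at the cylinder rims). The
  recovery requirement (≤15% relative error at blur 0.3 µm, 10% noise) is
  met, but with a real margin, and the bias direction (undershoot) is
  stable. A green recovery test therefore establishes correct plumbing
  and a bounded, documented measurement bias — not unbiased volumetry of
  arbitrarily small objects.

The puncta phantom places spheres with at least one background voxel
between any two objects, so component counting must be exact; blur and
noise can be layered on top. Neither phantom attempts realistic microglial
morphology, optical PSFs beyond a Gaussian, or tissue background texture.

## Spike simulation and classification

Simulated cells respond to the threshold filament with an
inhomogeneous-Poisson rate: `r(t) = peak · exp(−t/τ)` for adapting cells,
constant `peak` for nonadapting cells (thinning against the peak rate);
spontaneous activity is a homogeneous background over the whole recording
(default 1 Hz — low spontaneous rates are typical of the recorded
population; cells with high spontaneous rates were not recorded in the
source protocol). The stimulus protocol is emulated as an ascending
filament series: three 2-s trials per sub-threshold filament at a constant
2 Hz response, then `n_trials` trials of the threshold filament (index 4
by default), 10 s apart.

Analysis decisions, declared where the source description is silent:

- The vF threshold is the first filament whose mean first-second evoked
  rate reaches 10 Hz (inclusive).
- R is computed from counts **pooled** across the threshold-filament
  trials (sum/sum), not a mean of per-trial ratios; pooling is robust to
  single trials with an empty first half. A pooled first-half count of
  zero leaves R undefined and the cell is excluded with a logged warning.
- A spike exactly at onset + 0.5 s belongs to the second half-window
  (half-open windows).
- When no filament reaches 10 Hz — which genuinely happens for rapidly
  adapting cells whose burst is over well before 1 s, e.g. a 40 Hz peak
  with τ = 0.1 s averages only ∼4–5 Hz over the first second — the
  classifier falls back to the strongest filament applied (in an ascending
  protocol, the stimulus the experimenter stopped at), flags the cell, and
  reports its threshold as missing. Excluding such cells would bias the
  cohort toward nonadapting cells.
- Classification uses either the exact 1-D 2-means boundary fitted to the
  cohort (globally optimal sorted-split search; boundary = midpoint of the
  two centroids) or a fixed configured boundary (0.33 is the published
  convention). The boundary is inclusive on the upper side: R at the
  boundary is nonadapting. The mode used is recorded, since the published
  boundary was fitted on a cohort including earlier experiments that are
  not available here.

The nonadapting:adapting split is tested against the expected 1:2
inhibitory:excitatory ratio with an exact two-sided binomial test under
the minimum-likelihood rule (likelihood ties compared with a 10⁻⁷
relative tolerance, the convention of standard exact-test
implementations).

## Estimation statistics: numerical conventions

- **BCa interval.** Groups are resampled independently; the bias
  correction z₀ uses the fraction of bootstrap statistics *strictly below*
  the observed difference (a declared tie rule — ties move z₀ at discrete
  data); acceleration comes from a jackknife over the pooled leave-one-out
  differences. If z₀ is infinite (all bootstrap statistics on one side) or
  the jackknife variance is zero, the interval falls back to the plain
  percentile interval and the output records it.
- **Permutation test.** Two-sided on |mean difference|, Monte-Carlo with
  the add-one convention p = (b+1)/(N+1), so p is never exactly zero; an
  exhaustive mode enumerates all splits and returns the exact fraction.
  Whether the original web service used a one- or two-sided convention is
  not documented; two-sided is assumed and flagged in output metadata.
- **Determinism.** Every resampling routine takes an explicit seed; the
  pipeline derives per-stage seeds from one global seed so a single number
  reproduces a run. Comparisons whose permuted difference ties the
  observed one count as extreme (with a 10⁻¹² absolute guard against
  floating-point noise).

The 95% BCa coverage of the true mean difference, checked over 500
synthetic normal cohorts at n = 20/group, is required to fall in 92–98% —
the Monte-Carlo band around nominal coverage at that replicate count.

## Orchestration

`run_pipeline()` chains `simulate → engulfment → puncta → ephys → stats`
from a single JSON config (JSON rather than YAML: no YAML parser in the
supported dependency set). Volumes travel as multi-page float32 TIFF with
a JSON sidecar carrying voxel size, channel names and (for phantoms)
ground truth; a volume without voxel metadata is rejected outright. The
TIFF layer is a minimal baseline reader/writer validated against an
independent implementation in the test suite. Stage tables are CSV with a
schema-version header comment and stable column order (byte-identical
across reruns at a fixed config); the manifest records the config
snapshot, per-stage row counts and every QC warning raised anywhere in
the run.

## Known limitations

- Volumetry of objects at or below the blur scale is biased low by
  construction; the package measures, it does not deconvolve.
- The phantoms do not model uneven staining, autofluorescence, or
  section-to-section registration; batch QC rules (≥6 sections/animal)
  are bookkeeping, not a substitute for stain-quality review.
- The exhaustive permutation mode is feasible only for small groups
  (`choose(na+nb, na)` splits).
- Receptive-field areas are reported in mm² on the template; normalising
  to percent of plantar surface is left to configuration because the
  source unit convention is not stated.
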