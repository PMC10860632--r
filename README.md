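# engulfr

Quantitative tools for studying microglial engulfment of A-fiber (touch
afferent) terminals in the spinal dorsal horn, and its functional
consequences — for developmental neuroimmunologists and spinal
somatosensory physiologists who need the whole measurement chain to be
reproducible and testable offline.

The package covers three readouts and the statistics used to compare
them between groups:

- **Engulfment volumetry.** Given a 3-channel confocal z-stack (Iba1
  microglia, CD68 lysosomes, a fiber reporter), each channel is binarized
  and three nested volumes are measured per field of view:

  - microglial volume = |Iba1|
  - microglial lysosome volume = |CD68 ∩ Iba1|
  - engulfed fiber volume = |fiber ∩ CD68 ∩ Iba1|

  with |·| the foreground voxel count × voxel volume (µm³). The nesting
  `engulfed ≤ lysosome ≤ microglia` holds by construction.
- **Synaptic puncta.** 26-connected 3-D component counting and volume of
  a binarized synaptic stain, with an optional minimum-size filter.
- **Neuron classification.** Dorsal-horn wide-dynamic-range cells are
  labeled *adapting* or *nonadapting* from the adaptation ratio of their
  threshold von Frey response,

  `R = spikes(0.5–1 s) / spikes(0–0.5 s)`,

  split either by exact 1-D 2-means (globally optimal sorted-split
  search) or at a fixed boundary (0.33, inclusive upward). The
  nonadapting:adapting count is tested against the expected 1:2
  inhibitory:excitatory ratio with an exact two-sided binomial test
  (minimum-likelihood rule).
- **Estimation statistics.** Unpaired mean differences with 95% BCa
  bootstrap intervals (5000 resamples), two-sided permutation p-values
  ((b+1)/(N+1) convention), and Welch's *t*.

Seeded synthetic-data generators produce every input with ground truth
attached — engulfment phantoms (nested spheres and cylinders, voxel-exact
truth), non-touching puncta fields, inhomogeneous-Poisson spike trains,
and two-group cohorts — so the full pipeline runs and is tested without
any imaging data.

## Worked example

```r
library(engulfr)

## 1. a phantom field of view with known ground truth, degraded by
##    0.2 um blur + 5% noise, quantified with per-channel Otsu
ph  <- gen_engulfment_phantom(engulfment_phantom_spec(seed = 1))
res <- quantify_engulfment(ph$volume)
res[, c("microglia_um3", "lysosome_um3", "engulfed_um3")]
#>   microglia_um3 lysosome_um3 engulfed_um3
#> 1        411.14        83.16        29.78
unlist(ph$truth)
#> true_microglia_um3  true_lysosome_um3  true_engulfed_um3
#>             410.96              82.66              29.26
```

The measured engulfed fiber volume (29.78 µm³) recovers the voxel-exact
truth (29.26 µm³) to within ~2% at this degradation level.

```r
## 2. classify a simulated cohort of 6 adapting + 3 nonadapting cells
recs <- c(lapply(1:6, function(s) gen_spike_recording(
            spike_sim_spec("adapting", seed = s))),
          lapply(7:9, function(s) gen_spike_recording(
            spike_sim_spec("nonadapting", seed = s))))
cl <- suppressWarnings(classify_cohort(recs))
cl
#> <adaptive_classification> 9 cells (0 excluded), boundary kmeans = 0.575
#>   adapting: 6, nonadapting: 3
round(cl$cells$r, 3)
#> [1] 0.133 0.045 0.000 0.263 0.474 0.048 1.183 0.855 0.928

## the published cohorts: 8/30 and 5/28 nonadapting cells vs p0 = 1/3
ratio_binomial_test(8, 30)   # 0.56
ratio_binomial_test(5, 28)   # 0.11
```

All six simulated adapting cells (low R) and three nonadapting cells
(R near 1) are recovered by the fitted boundary.

```r
## 3. estimation statistics on a synthetic two-group cohort
co <- gen_cohort(cohort_spec(n_per_group = 20, group_means = c(0, 1),
                             seed = 4))
effect_size(co$a, co$b, seed = 4, name = "cKO vs control")
#> mean_diff = 0.93, 95% BCa CI [0.399, 1.417], perm_p = 0.0022
```

The interval covers the generating difference of 1.0, and the
permutation p reflects a clear two-group separation at n = 20/group.

## Pipeline and CLI

A JSON config drives staged, seed-deterministic runs:

```sh
Rscript -e 'engulfr::engulfr_cli()' all --seed 1 --outdir out
```

(`simulate | engulfment | puncta | ephys | stats | all`; flags
`--config`, `--seed`, `--outdir`, `--log-level`.) Stage outputs are
schema-stamped CSVs plus a manifest JSON recording the config snapshot
and every QC warning (e.g. animals with fewer than 6 analyzed sections).

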