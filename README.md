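# dicimap

Automated identification of a component of interest — typically the
language resting-state network — from individual-subject spatial ICA of
resting-state fMRI, for presurgical mapping workflows.

Spatial ICA happily decomposes a resting-state run into 20–60 components,
but somebody still has to say which component *is* the language network,
and at which model order. `dicimap` answers that with the discriminability
index from signal-detection theory. Each component map is standardized,
binarized at `z > 1.96` (with an adaptive fallback down to `z > 0.8` for
low-SNR data), and compared with a binary network template through

```
HR  = |C ∩ T| / |T|                hit rate
FAR = |C ∩ (B \ T)| / |B \ T|      false-alarm rate
d'  = Φ⁻¹(HR) − Φ⁻¹(FAR)
```

where `C` is the binarized component, `T` the template and `B` the brain
mask. The maximum-d′ component per model order becomes that order's
candidate; the candidate with the largest d′ across all orders is the final
component of interest. Unlike the traditional goodness-of-fit score
(in-template minus out-of-template mean z), d′ works on binarized maps and
is immune to the extreme voxel values ICA maps often contain.

The package covers the full chain:

* **Template construction** — seed-based functional connectivity (default
  seed: Broca's area, MNI `[-57, 15, 24]`), Fisher z, one-sample t-test,
  Benjamini–Hochberg FDR (`q = 0.001`), 20-voxel cluster-extent filter.
* **Preprocessing** — initial-frame discard, linear detrending, 0.01–0.08 Hz
  zero-phase band-pass, Gaussian smoothing (FWHM 8 mm), 2 mm / 2° motion
  screening.
* **Multi-order spatial ICA** — symmetric FastICA (logcosh) after PCA
  whitening, deterministic per-order seeding, skewness sign convention.
* **d′ scoring and selection** — adaptive threshold descent, per-order and
  cross-order argmax, expert-review escalation, GOF comparator.
* **Stimulation-site validation** — site-by-site classification against the
  binary map with exact and 1-cm-extended sensitivity.
* **Phantom simulator** — ground-truth-annotated synthetic 4D data
  (ellipsoidal brain, band-limited orthogonal sources, AR(1) noise, an
  intentionally imperfect template), so everything above is testable
  without scanner data.

See `vignette("dici-methods")` for the model, its assumptions and all
numerical conventions.

## Worked example

Simulate a subject with a known two-cluster language network among
distractor sources, identify the component of interest over model orders
5/8/11, and compare with the ground truth:

```r
library(dicimap)

ph  <- make_language_phantom(rng_seed = 7)
sel <- identify_coi(ph$volume, ph$brain, ph$template,
                    orders = c(5, 8, 11), rng_seed = 7)
sel
#> <selection_result> best component 2 at order 5 (d' = 3.399, HR = 0.649, FAR = 0.001, threshold 1.96)

sel$per_order_candidate
#>   order component_index threshold_z  hit_rate false_alarm_rate     dici      gof
#> 1     5               2        1.96 0.6493506      0.001282325 3.399175 5.454421
#> 2     8               2        1.96 0.6493506      0.001282325 3.399175 5.454943
#> 3    11               2        1.96 0.6493506      0.001282325 3.399175 5.455469

coi <- selected_component_map(sel)
mask_dice(coi$mask, ph$source_masks$language)
#> [1] 1
```

Reading the table: at every model order the best candidate covers 65% of
the (deliberately imperfect, Dice 0.75 vs truth) template while marking
only 0.1% of non-template brain voxels, giving d′ ≈ 3.4; thresholded, the
winning component reproduces the true source mask exactly (Dice 1.0). The
binarization threshold never had to descend below its 1.96 start, so no
expert review is flagged.

A thin command-line wrapper over the same functions lives at
`inst/cli/dicimap.R` (`simulate`, `preprocess`, `template`, `ica`,
`identify`, `validate` subcommands driven by a YAML config; exit codes in
`?PIPELINE_EXIT_CODES`).

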