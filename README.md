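# dielcross

Crosstalk between drought response and diurnal rhythm in transcriptome
time courses.

Many genes that respond to water deficit in rice leaves are also
diurnally rhythmic, and the overlap between the two gene sets — which
genes, what share, and at which time of day their expression peaks — is
itself the quantity of interest. `dielcross` implements the full
analysis as tested, reusable R functions:

* **Fold-change construction** — log2 normalization of linear
  intensities and per-replicate stress-versus-MOCK log2 fold changes,
  with stress samples paired to controls within series by replicate
  index.
* **Drought classification** — an internally implemented, deterministic
  K-means (Lloyd + exhaustive small-instance seeding / k-means++
  restarts) over fold-change profiles; clusters whose mean drought
  log2FC exceeds ±1 label their members up- or down-regulated.
* **Diurnal calling** — median-centered clustering of 2-hourly,
  2-day, multi-stage time courses; rhythmicity scored with a fixed-24-h
  cosinor R² (default threshold 0.3 on cluster centroids); peak phase
  assigned to one of four clock windows (midday 08–16, lateday 18–20,
  midnight 22–02, predawn 04–06) by window-mean argmax.
* **Crosstalk summary** — per-direction diurnal percentages and phase
  proportions: e.g. 403 of 712 up-regulated genes diurnal = 56.6%.
* **Enrichment** — fold enrichment k/(nK/N) and upper-tail
  hypergeometric P, with the ≥2-fold & P ≤ 0.05 filter.
* **Interaction networks** — pathway-centered graphs with
  interolog-confidence edge weights, Pearson-correlation edge scores
  (flagged above 0.5), transcription-factor regulon overlays, and
  SIF/GraphML export.
* **qPCR utility** — comparative-Ct (2^−ΔΔCt) relative quantification
  with Welch's unequal-variance t test and inclusive significance
  stars.
* **Synthetic data** — generators for stress series, diurnal courses,
  annotations and interaction tables with planted ground truth, used by
  the test suite to demonstrate parameter recovery end to end.

## Worked example

Simulate a stress compendium and a diurnal course with shared ground
truth, classify both ways, and summarize the crosstalk:

```r
library(dielcross)

cfg <- sim_config(n_genes = 500, seed = 42)

stress <- generate_stress_series(cfg)
fcp    <- fold_change(log2_normalize(stress$matrix), stress$metadata)
labels <- classify_drought(fcp, k = 10, seed = 42)
response_counts(labels)
#>   n_up n_down n_none
#>    101     86    313

diurnal <- generate_diurnal_course(cfg)
calls   <- call_diurnal(log2_normalize(diurnal$matrix),
                        diurnal$metadata, k = 7, seed = 42)
crosstalk_summary(labels, calls)
#> up   : 55/101 diurnal (54.5%)
#>        phase %: predawn 38.18, midday 21.82, lateday 25.45, midnight 14.55
#> down : 51/86 diurnal (59.3%)
#>        phase %: predawn 33.33, midday 21.57, lateday 21.57, midnight 23.53
#> total diurnal crosstalk genes: 106
```

Of the 101 genes the K-means classifier labels drought-up, 55 are also
called diurnally rhythmic (54.5%), peaking mostly before dawn — the
same style of readout as for the 712/761-gene sets the method was built
for. `run_pipeline()` chains all stages (simulate → fold change →
classify → diurnal → crosstalk → enrich → network) from one YAML/list
config and writes every intermediate table plus a checksummed manifest.

## Documentation

The methods vignette (`vignettes/crosstalk-methods.Rmd`) describes the
models, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, numerical choices, and known
limitations.
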