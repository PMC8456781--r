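# filotip

Quantification of filopodial protein localization, dynamics and integrin
activity from fluorescence microscopy.

Filopodia are finger-like, actin-rich protrusions that cells extend to probe
their environment. The myosin motor MYO10 concentrates at filopodia tips, and
the balance of active versus inactive β1 integrin along each protrusion
determines how filopodia adhere. Studying this system requires a chain of
small, exacting quantifications, and `filotip` implements all of them as one
tested R package:

* **Profile mapping** — tip-to-base line-intensity profiles (bilinear sampling
  at 1 px arc spacing), reduced to 40 median bins
  (sample *i* of *n* → bin ⌊i·40/n⌋), averaged into per-protein localization
  maps; per-filopodium **enrichment ratio** (mean of tip bins 1–6 over shaft
  bins 7–40) and **tip positivity** (tip-bin average ≥ 5000 on the normalized
  0–65535 scale), plus length extraction.
* **Screen spot counting** — ImageJ-style prominence ("noise tolerance")
  find-maxima with F-actin cell masking to exclude intracellular spots.
* **Lifetime tracking** — Laplacian-of-Gaussian detection
  (σ = diameter/(2√2), 0.8 µm default) with subpixel refinement, and exact
  minimum-distance frame-to-frame assignment gated at 1 µm with no gap
  closing; lifetimes are (frames − 1) × interval with boundary censoring.
* **Immunogold distances** — kernel density curves (area = 1, nm scale, never
  length-normalized) and a pooled-resampling **bootstrap Kolmogorov–Smirnov
  test**.
* **MST binding** — the single-site ligand-depletion (quadratic) model

  ```
  AL = ((A0 + L0 + Kd) − sqrt((A0 + L0 + Kd)² − 4·A0·L0)) / 2
  signal(L0) = F_free + (F_bound − F_free) · AL / A0
  ```

  with `fit_kd()` estimating (Kd, F_free, F_bound) by grid-seeded
  Levenberg–Marquardt; returns a classed model object with the usual
  `print`/`coef`/`predict`/`plot` methods.
* **Flow & qPCR** — integrin activity indices AI = (F − F_EDTA)/F_PB1 and
  IA = (F_9EG7 − F_2ndAb)/(F_P5D2 − F_2ndAb); 2^−ΔΔCt relative expression.
* **Resampling statistics** — randomization (permutation) test with exact
  enumeration option, bootstrap effect sizes, Tukey boxplot summaries.
* **Synthetic data** — `make_scene()`, `make_gold_particles()`,
  `make_titration()`, `make_flow_population()`, `make_timelapse()` generate
  every input with stored ground truth, so the whole pipeline is verifiable
  offline.

## Worked example

Render a ground-truth scene, score β1-integrin localization, and fit a binding
affinity:

```r
library(filotip)

sc <- make_scene(scene_config(n_filopodia = 30, seed = 1))

binned <- list()
for (ch in c("active-b1", "inactive-b1")) {
  for (i in seq_along(sc$polylines)) {
    binned[[length(binned) + 1]] <- bin_profile(extract_profile(
      sc$images[[ch]], sc$polylines[[i]], sc$config$pixel_size,
      filopodium_id = i, channel = ch))
  }
}
act <- binned[sapply(binned, function(b) b$channel == "active-b1")]
ina <- binned[sapply(binned, function(b) b$channel == "inactive-b1")]

percent_positive(act)
#> [1] 60
mean(sc$ground_truth_positive[, "active-b1"])   # generator truth
#> [1] 0.6

median(sapply(act, enrichment_ratio))
#> [1] 4.31
median(sapply(ina, enrichment_ratio))
#> [1] 0.01
randomization_test(sapply(act, enrichment_ratio),
                   sapply(ina, enrichment_ratio), seed = 1)$p
#> [1] 0.000999001

fit_kd(make_titration(Kd = 4.7e-6, F_free = 800, F_bound = 900, noise_sd = 0))
#> Ligand-depletion binding fit
#>   Kd      = 4.7e-06 M (4.7 uM)
#>   F_free  = 800
#>   F_bound = 900
#>   n = 16 points, SSE = 1.292e-26, converged: TRUE
```

60% of filopodia score tip-positive for active β1, exactly the fraction the
generator seeded; the tip-enriched species shows a median enrichment ratio of
4.3 versus ~0 for the shaft-restricted species (its tip bins are empty), and
the permutation test calls the difference significant at the smallest p the
resample count allows. The noiseless titration returns the generating Kd
exactly.

A config-driven pipeline (`run_pipeline()`) wires simulate → profiles → map →
per-filopodium CSVs with a run manifest; `inst/cli/filotip.R` exposes the same
workflows as shell subcommands (`simulate`, `map`, `screen`, `track`, `sem`,
`mst`, `flow`, `stats`).

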