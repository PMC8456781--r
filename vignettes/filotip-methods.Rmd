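---
title: "Quantifying filopodial protein localization, dynamics and integrin activity with filotip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying filopodial protein localization, dynamics and integrin activity with filotip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filotip)
```

## Scope

Filopodia are thin, actin-rich protrusions that cells use to probe their
surroundings; the myosin motor MYO10 accumulates at their tips, and the
activation state of β1 integrins along the protrusion controls how filopodia
anchor to matrix. `filotip` implements the complete quantitative workflow used
to study this system: tip-to-base intensity-profile mapping, tip-enrichment and
tip-positivity scoring, spot counting for silencing screens, spot tracking for
lifetime measurement, immunogold distance-distribution comparison, a
ligand-depletion binding model for microscale thermophoresis (MST), flow
cytometric activity indices, qPCR relative expression, and the resampling
statistics used to compare conditions. A synthetic-data generator produces
every input with known ground truth, so each stage can be verified end to end
without any external dataset.

## Intensity-profile mapping

The mapping workflow assumes tip-to-base line profiles, one pixel wide, drawn
from the filopodium tip to its base (the intersection with the lamellipodium).
`extract_profile()` samples a polyline at one-pixel arc spacing with bilinear
interpolation; sample 0 is the tip vertex.

To make filopodia of different lengths comparable, `bin_profile()` reduces
each profile to **40 bins**: sample $i$ of $n$ (0-based) is assigned to bin
$\lfloor i \cdot 40 / n \rfloor$ and each bin takes the **median** of its
samples. The floor-assignment rule is the deterministic equal-width rule that
a factor construction over sample indices produces; profiles shorter than 40
samples are first nearest-neighbour upsampled to 40 samples and flagged
(`upsampled = TRUE`) rather than rejected, because short filopodia are real
and should stay in the analysis. `build_map()` averages binned profiles per
channel into the localization map (one 40-value row per protein).

Two per-filopodium statistics are derived from the binned profile:

* **Enrichment ratio** — mean intensity of tip bins 1–6 divided by the mean of
  shaft bins 7–40 (`enrichment_ratio()`); values above 1 mean tip enrichment.
* **Tip positivity** — a filopodium is positive for a protein at its tip when
  the tip-bin average is **at least 5000** on the 0–65535 scale
  (`classify_tip_positive()`); the boundary value itself is positive. The
  threshold is meaningful only after `normalize_image()`, which linearly
  rescales each image so the brightest structure inside the cell mask maps to
  65535 and the modal background value maps to 0, mirroring an automatic
  brightness/contrast adjustment anchored on the brightest cellular structure.
  Normalization therefore precedes profile extraction in `run_pipeline()`;
  whether the original workflow normalized before or after export is not
  documented, so this package declares the order rather than inferring it.

Filopodium length is read directly off the profile: the arc length of the
traced polyline times the pixel size (`filopodium_length()`).

## Spot counting for silencing screens

`count_myo10_spots()` reproduces "Find Maxima"-style counting: a local
maximum counts as a spot when one cannot reach any higher pixel from it
without first descending by at least the *prominence* (noise tolerance). The
implementation floods, from each candidate maximum in decreasing value order,
the region of 8-connected pixels above `value − prominence`; candidates whose
region touches a higher pixel or an already-accepted maximum merge away. No
numeric tolerance is documented for the original screen, so prominence is a
required parameter (fixture default 2000 ADU). Intracellular spots are
excluded by masking the cell with the F-actin channel: Otsu threshold by
default (overridable), hole filling, largest connected component. Optional
background flattening uses grayscale morphological opening with a disc
(radius default 50 px), the standard approximation of rolling-ball background
estimation. An empty cell mask is an error, deliberately distinct from a
zero count.

## Spot tracking and lifetimes

`detect_spots()` is a Laplacian-of-Gaussian detector at
$\sigma = d/(2\sqrt{2})$ for spot diameter $d$ (default 0.8 µm), with local
maxima above a quality threshold and optional quadratic subpixel refinement.
The quality scale is arbitrary (it scales with spot brightness), so the
threshold is a free parameter calibrated on the synthetic fixtures. The
published tracker settings give spot diameter and link distances in "mm";
these are read as µm here, the only physically sensible unit at filopodial
scale.

`link_tracks()` joins consecutive frames by the minimum-total-distance
one-to-one assignment restricted to displacements ≤ 1 µm (maximum link count
takes priority over total distance, the behaviour of a simple LAP tracker
with gap closing disabled). The assignment is solved exactly as a
maximum-weight bipartite matching. Lifetime is $(k-1)\times$ frame interval
for a track spanning $k$ frames (5 s default interval); tracks touching the
first or last movie frame are censored and excluded from summaries, since
their true lifetime is only bounded from below. Two genuinely ambiguous
events — a spot dying in the same place and frame-neighbourhood where another
is born — cannot be separated by any position-only tracker; the tests allow
for this explicitly.

## Immunogold distance distributions

Gold-particle distances to the filopodium tip are compared as probability
densities (`density_curve()`, Gaussian kernel; bandwidth "auto" is Silverman's
rule, since no kernel settings are documented). Distances are **never**
normalized by filopodium length; curves live on the nm scale of the inputs.
Statistical comparison uses `bootstrap_ks()`: the observed statistic is
$D = \sup_t |F_x(t) - F_y(t)|$, and the null is built by resampling both
samples, at their original sizes, with replacement from the pooled data —
1000 resamples by default, with the add-one corrected p-value
$(1 + \#\{D^* \ge D\})/(n_{boot}+1)$, which can never be exactly zero.
Pooled (rather than within-sample) resampling was chosen because it directly
simulates the null of a common distribution and handles ties without any
asymptotic approximation; the original bootstrap construction is not
documented.

## MST binding model

Binding of a fluorescent partner A (fixed total concentration $A_0$, 20 nM in
the assays this reproduces) to a titrated ligand L follows the single-site
ligand-depletion model: the complex concentration is the quadratic root

$$AL = \tfrac{1}{2}\left((A_0 + L_0 + K_d) - \sqrt{(A_0 + L_0 + K_d)^2 - 4 A_0 L_0}\right),$$

computed in the cancellation-free form $2A_0L_0 / (S + \sqrt{S^2 - 4A_0L_0})$
(`complex_concentration()`). The measured signal is affine in the bound
fraction, $y = F_{free} + (F_{bound} - F_{free})\,AL/A_0$, so the fit consumes
raw ratios or normalized fluorescence (`delta_fnorm()`, the post/pre IR-laser
ratio) equally. `fit_kd()` fits all three parameters $(K_d, F_{free},
F_{bound})$ — amplitudes are left free because nothing documents them as
fixed — with $K_d$ on a log scale bounded to $[10^{-12}, 1]$ M. "auto"
initialization scores a 49-point log-spaced $K_d$ grid (amplitudes solved by
linear least squares at each candidate) and refines the best seed by
Levenberg–Marquardt. Replicate experiments are pooled by concatenating
points, matching how the original affinities were derived from three pooled
experiments; a per-concentration-averaging mode is intentionally not the
default. A flat titration (amplitude below three times the residual noise) is
a distinct "no binding" error rather than a garbage estimate. The fit is an
S3 model object (`kd_fit`) with `print`, `summary`, `coef`, `predict`,
`fitted`, `residuals` and `plot` methods, plus a case-resampling bootstrap CI
(`bootstrap_kd_ci()`).

## Flow cytometry, qPCR and resampling statistics

Two integrin activity indices operate on per-cell summaries of gated
populations (gating itself is upstream; `rectangular_gate()` exists only for
synthetic data): `activity_index_fn()` computes
$AI = (F - F_{EDTA})/F_{PB1}$ — fibronectin-fragment binding corrected by the
EDTA-treated signal (EDTA chelates the cations integrins require) and
normalized to total α5 integrin — and `activity_index_9eg7()` computes
$IA = (F_{9EG7} - F_{2ndAb})/(F_{P5D2} - F_{2ndAb})$, active over total β1
with secondary-only background subtracted. Both are invariant to a common
instrument gain. `relative_expression_ddct()` is the standard $2^{-\Delta\Delta
C_T}$ fold change against a reference gene and control condition.

`randomization_test()` permutes group labels preserving group sizes; the
default statistic is the difference of means (a median option is kept), the
p-value is two-sided with the add-one correction, and `exact = TRUE`
enumerates all $\binom{n}{n_a}$ assignments, which the Monte-Carlo p converges
to. `effect_size()` reports the difference of means with a percentile
bootstrap CI from independent within-group resampling. `tukey_summary()`
summarizes with type-7 (linear-interpolation) quartiles and 1.5 IQR whiskers —
the quantile rule of the boxplots produced by the plotting tools this
workflow standardizes on.

## The synthetic-data generator

`make_scene()` renders a circular cell body with straight filopodia radiating
from its rim (hand-drawn profiles are polylines in principle, and the data
model keeps polyline support, but straight segments suffice to exercise every
downstream computation). Each channel follows a `channel_law()`:
`tip_exponential` (amplitude × $e^{-d/\lambda}$ from the tip — tip-enriched
proteins such as MYO10 or active β1), `uniform`, `shaft_uniform`
(tip-excluded), or `body_only`. Each filopodium carries a channel's signal
with probability `tip_positive_fraction`, and the flag is stored as ground
truth, so positivity recovery is testable as a binomial experiment. The
render rule is closed-form per pixel (tent-shaped one-pixel anti-aliasing
across the segment, contributions combined by maximum), which lets a direct
per-pixel oracle verify the renderer exactly. Noise is
Poisson(signal/scale)·scale plus Gaussian read noise, rounded and clipped to
0–65535; no camera model is documented for the quantified images, so these
two knobs are declared defaults (scale 4, read SD 60 ADU), as are the scene
defaults chosen to resemble structured-illumination data of a U2-OS-like
cell: 0.08 µm pixels, cell radius 8 µm, 30 filopodia of 2–8 µm, four channels
(MYO10, F-actin, active-β1 at fraction 0.5, inactive-β1). Everything is a pure
function of (config, seed).

The other generators follow the same ground-truth-closure principle:
`make_gold_particles()` (uniform or tip-concentrated truncated-exponential
distances), `make_titration()` (geometric dilution under the depletion model
plus Gaussian noise), `make_flow_population()` (log-normal stain
intensities), and `make_timelapse()` (exponential lifetimes rounded up to ≥1
frame, uniform start frames, bounded random-walk motion; boundary-touching
tracks marked censored).

What the generator does *not* emulate — curved and crossing filopodia, PSF
blur and SIM reconstruction artifacts, photobleaching, spot merging/splitting,
autofluorescence — bounds what green tests mean: they demonstrate the
*computations* are correct on data obeying the stated models, not that the
models capture every property of real micrographs.

## Numerical choices and degenerate inputs

* Coordinates are 0-based pixel centres; distances in µm derive from
  `pixel_size`. All intensities live on the 16-bit 0–65535 scale.
* `normalize_image()` refuses constant images (undefined scale) and empty
  masks; `enrichment_ratio()` refuses a zero shaft mean; the spot counter
  distinguishes "no cell" from "no spots"; `fit_kd()` distinguishes "no
  binding" from a fit.
* The binding quadratic uses the cancellation-free root; recovered noiseless
  $K_d$ values are exact to optimizer tolerance (≪1 %) across
  $10^{-8}$–$10^{-4}$ M.
* Assignment ties in linking (equal total distance) are broken by the
  matching implementation; tests compare cardinality and total distance, the
  quantities the tracker optimizes.
* Monte-Carlo p-values use the add-one correction and explicit seeds; every
  stochastic function takes a `seed` argument and restores the caller's RNG
  state.

## Problem sizes used in the test suite

The suite verifies stochastic claims at desk scale: 500 null simulations for
the calibration of the randomization test and of the bootstrap KS test
(199 resamples each), 400 filopodia across 8 rendered scenes for positivity
recovery, 200 noisy replicates for Kd bias, $10^5$ draws for distributional
means, and exhaustive enumeration for assignment (≤4 spots per frame) and
permutation (≤10 observations) oracles. These sizes give 3-standard-error
resolution on every rate being checked.

## Limitations

Filopodium tracing is out of scope: profiles come from annotations or the
generator, matching the manual tip-to-base drawing the mapping procedure is
defined on. The LoG quality threshold has no absolute calibration. The
bootstrap KS construction and the Find-Maxima tolerance are declared choices
where the original settings are undocumented; both are parameters, not
constants. FCS parsing, compensation and gating GUIs are not reimplemented —
per-cell tables are the interface.
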