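---
title: "Quantifying nuclear oxidative-damage immunofluorescence and foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear oxidative-damage immunofluorescence and foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucfoci)
```

## The measurement problem

Oxidative DNA damage markers such as 8-OHdG (8-hydroxy-2′-deoxyguanosine)
are routinely visualized by immunofluorescence: cells are counterstained
with DAPI (blue channel, nuclear DNA) and stained with an antibody against
the damage marker (green channel). Two readouts matter:

1. **Compartmentalized intensity** — how much marker signal sits in the
   nucleus versus the cytosol, summarized as per-compartment means, the
   nuclear-to-cytosolic ratio N/C, and intensities relative to an untreated
   control whose mean is defined as 100%.
2. **Nuclear foci** — punctate accumulations of the marker inside nuclei,
   counted as local intensity maxima and normalized by the nuclear area in
   pixels (foci density), which makes counts comparable across images taken
   with the same objective and no electronic post-magnification.

`nucfoci` reimplements this evaluation as a tested pipeline. Every pixel is
classified by two manually chosen, per-series thresholds:

* **nucleus** — DAPI intensity strictly above the DAPI threshold (after
  hole-filling and a minimum-area filter on the connected components);
* **cytosol** — not nucleus, but green intensity strictly above the
  background threshold ("not nucleus, but brighter than the background");
* **background** — everything else.

Pixels exactly at a threshold count as background: the threshold is the
limit that truncates signal, so the limit itself is excluded. Thresholds
are fixed once on a reference image of a stained series and propagated
verbatim to the rest of the series (`propagate_threshold()`); the package
logs an Otsu suggestion but never applies it silently, and `audit_export()`
writes the mask and foci overlays a user needs for the manual suitability
check.

## Foci as noise-tolerance maxima

Foci are detected on the green plane restricted to the nuclear mask with a
prominence ("noise tolerance") rule: a candidate local maximum at intensity
$I$ is rejected if and only if a strictly higher pixel can be reached from
it along an 8-connected path on which every pixel keeps intensity
$> I - \mathrm{tol}$. Equivalently, a peak survives only if it is separated
from every higher peak by a descent of at least the noise tolerance.
Details that the rule alone does not fix, and how this package fixes them:

* **Plateaus.** Connected regions of equal intensity are one candidate,
  represented by the plateau pixel nearest the plateau centroid (ties by
  row-major scan order).
* **Flat regions.** A candidate must have at least one strictly lower
  in-mask neighbour. A globally constant plane therefore has no maxima, and
  a perfectly flat nucleus contains no foci, while a genuine summit plateau
  yields exactly one.
* **Equal twin peaks.** Two equal-height peaks have no *strictly higher*
  pixel to merge into, so both are kept regardless of the tolerance. This
  follows from the path rule as stated; interactive tools sometimes merge
  within-tolerance equal maxima instead. On scenes of isolated bright
  puncta over smooth nuclei the two behaviours coincide.
* **Mask semantics.** Pixels outside the nuclear mask are bottomless
  (−∞): merge paths cannot leave the nucleus, so two nuclei merged into a
  single label cannot share a focus across a background gap. The
  alternative — detecting on the full plane and filtering by mask — differs
  exactly when a merge path exits the nucleus, and is not what a
  mask-applied detection does.

The implementation is a C++ plateau-flood; an independent pure-R exhaustive
search (`brute_force_maxima_oracle()`) implements the identical rule and
the test suite requires exact set equality on hundreds of random planes.

The noise tolerance is a per-series setting like the thresholds. As a
starting point `suggest_noise_tolerance()` proposes twice the robust
standard deviation (MAD) of the intranuclear green signal of the reference
image: about two noise standard deviations must be descended between two
peaks before they count as separate foci.

## Normality-gated statistics

Group comparisons follow a fixed selection procedure. Each group is run
through a four-test normality battery — D'Agostino–Pearson, Anderson–
Darling, Shapiro–Wilk and Kolmogorov–Smirnov — and counts as Gaussian only
if **all four** retain normality at the battery alpha (0.05 by default;
`rule = "majority"`/`"any"` are available because no combination rule is
canonical). The K–S member is the Lilliefors variant: a plain K–S test
against a fully specified normal is invalid when mean and sd are estimated
from the sample. Then:

| groups | all Gaussian | any non-Gaussian |
|---|---|---|
| 2 | one-tailed Student's *t* (no correction) | one-tailed Mann–Whitney U |
| ≥ 3 | one-way ANOVA + Holm–Šídák comparisons | Kruskal–Wallis (+ Dunn, Holm-adjusted — an extension, the source procedure names no follow-up) |

When a control group is designated the one-tailed direction is
*treated > control* (the damage-induction hypotheses are one-directional
increases); without a control the package warns and tests two-sided.
Significance is graded with inclusive thresholds:
`*` p ≤ 0.05, `**` p ≤ 0.01, `***` p ≤ 0.001, `****` p ≤ 0.0001, `ns`
otherwise. ANOVA follow-ups compare each non-control group against the
control with the pooled ANOVA mean-square error and Holm–Šídák adjustment.

Three of the four normality tests have no implementation in the installed
toolchain and are implemented from the standard formulas; they were
verified against independent reference implementations during development,
and the test suite pins their p-values on frozen samples.

The analysis unit is a real choice the source procedure leaves open:
roughly a thousand cells per condition are pooled, but whether replicates
are cells or images is unstated. The pipeline emits **both** per-image and
per-nucleus tables and compares either (`unit = "per_nucleus"` is the
default; N/C ratios are always compared per image because cytosol is not
assigned to individual cells). Per-nucleus pooling treats cells as
independent and ignores image-level clustering — users who consider images
the experimental unit should set `unit = "per_image"`.

## The synthetic stated world

Real deposited images do not exist for this workflow, so every stage is
exercised on generated scenes with known ground truth
(`generate_scene()`). The generator emulates a confocal field of adherent
cells; its defaults, fixed once as a realistic 8-bit acquisition and not
revisited:

| parameter | default | meaning |
|---|---|---|
| scene | 256 × 256 px, 8-bit | one field of view |
| nuclei | 8, semi-axes 9–14 px, non-overlapping ellipses | adherent-cell density |
| DAPI level | 180 | nuclear blue signal over a 0 background |
| green levels | 60 / 30 / 5 | nucleus / cytosol halo (6 px) / background |
| foci | Poisson(3) per nucleus, amplitude 90, σ = 1.5 px | PSF-limited puncta |
| noise | Gaussian, sd 4, both channels | read noise; clipped to [0, 255] |

Foci centers are sampled uniformly inside the inner 85% of each ellipse
with a 4 px minimum separation: maxima counting can only resolve separated
puncta, so the generator plants what the instrument could resolve. The
reference thresholds for this world are DAPI 90 and background 15 — the
midpoints a user would pick between the modes on a reference image.

The generator's "true N/C ratio" is measured on the noise-free green plane
over the true masks, foci included — the 60/30 level ratio alone
understates what the scene actually contains (with the default foci load
the rendered ratio is ≈ 2.2–2.3).

`generate_experiment()` produces a two-group experiment; the menadione-like
preset multiplies the nuclear green level by 1.5 and the foci load by 3 in
the "treated" group, mirroring the direction (not any printed magnitude —
none exists) of an oxidative challenge; multipliers of 1 give an
exchangeable null experiment used for calibration checks.

What a green test on this world does **not** establish: robustness to
uneven illumination, out-of-focus light, touching/overlapping nuclei,
nucleoli, autofluorescence, or non-elliptical nuclei. Nuclei are never
split (no watershed); foci density per total nuclear area is robust to
merged nuclei, per-nucleus counts are not.

## Numerical and degenerate-input choices

* Intensities are carried on the native integer scale; 16-bit input is
  processed natively, never rescaled to 8-bit.
* Empty compartments yield `NA` means; N/C is `NA` when the cytosolic area
  is zero; foci density is `NA` when no nuclear pixels exist. `NA` is never
  silently replaced by 0.
* Connected components use 8-connectivity (the common default of the
  interactive tool this replaces); hole filling floods the complement with
  4-connectivity from the border. Both hole filling (default on) and the
  minimum nucleus area (default 50 px) are exposed as options rather than
  hard-coded, since interactive workflows differ on both.
* Maxima ordering is deterministic: descending intensity, ties by scan
  order. Reruns of the pipeline on identical inputs are byte-identical.
* Shapiro–Wilk is undefined above n = 5000 in base R; larger samples are
  thinned deterministically (every k-th value) before testing.
* Zero-variance samples are declared non-Gaussian with a warning; samples
  with n < 8 cannot run the full battery and are conservatively declared
  non-Gaussian (n < 4 is an error).

## A minimal session

```{r example, eval = FALSE}
ex <- generate_experiment(scene_params(), n_images_per_group = 20, seed = 1)
cfg <- run_config(ex$manifest, threshold_config(90, 15))
res <- run_pipeline(cfg, images = lapply(ex$scenes, `[[`, "image"))
res$comparisons$foci_density$comparisons
```

For batch use from a shell, `inst/cli/nucfoci.R` wraps the same functions
as `simulate`, `run`, `stats` and `audit` subcommands; configuration is
per-series, thresholds are never defaulted silently, and the run summary
records thresholds, tolerance, the four normality p-values per group and
the chosen tests, keeping the manual threshold-suitability step auditable.
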