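---
title: "Decomposing fly body pigmentation into component traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing fly body pigmentation into component traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigmentr)
```

## The measurement problem

Dorsal pigmentation of a fly mixes two kinds of information: the *colors*
of the cuticle, and the *spatial arrangement* of a darker pattern element —
the trident on the thorax, the posterior bands on each abdominal segment —
on a lighter background.  A single "darkness score" conflates them: a fly
can darken by tinting its background, by darkening its pattern elements, or
by widening them, and those routes respond differently to genotype, sex,
and developmental temperature.  pigmentr therefore decomposes an
antero-posterior color profile of each body part into five traits measured
on the same transect:

| Trait | Meaning | Units / range |
|-------|---------|---------------|
| `odk` | overall darkness: mean of `dmax - Dbk` over positions | `[0, dmax]` |
| `pat` | fraction of positions on the darker pattern element | `[0, 1]` |
| `ran` | RGB distance between median colors of the 20 darkest and 20 lightest pixels | `>= 0` |
| `cbk` | angle of the background color line to the gray diagonal | degrees, `[0, 90]` |
| `cpa` | same for the pattern-element pixels | degrees, `[0, 90]` |

`Dbk` is the distance of a pixel's RGB coordinates (channels scaled to
`[0, 1]` regardless of image bit depth) to black.

## The transect

Each measurement starts from two landmark endpoints in continuous, 0-based
pixel coordinates.  The segment is sampled at unit arc-length spacing
(`floor(|b - a|) + 1` positions); at every position the mean of five
bilinearly interpolated samples on the unit perpendicular (offsets −2…2) is
taken.  This perpendicular averaging is the pipeline's only spatial
denoising; it reduces i.i.d. pixel noise variance about five-fold and makes
the profile robust to one-pixel landmark wiggle.  Membranous tissue between
abdominal segments can be excluded with half-open `[start, end)` position
intervals: masking flags positions rather than deleting them, so the
envelope estimation (below) treats each unmasked run as an independent
segment and no information flows across a gap.

Transects drawn over debris cannot be measured meaningfully.  The screen in
`flag_debris()` looks for a *short* run (3–10 positions by default) of
darkness values more than 6 robust standard deviations from the segment
median.  The run-length upper bound is what separates debris specks from
legitimate pattern elements, which are wide: a 30%-coverage band also sits
many MADs from the median (the MAD is computed over the whole segment and
has a 50% breakdown point), so a rule without the upper bound would reject
every strongly banded fly.  The screen is conservative, always logged, and
can be disabled via `run_config(debris_enabled = FALSE)`.

## Darkness normalization

Darkness is `dmax - Dbk`.  Two conventions are supported because the
natural normalization depends on the distance used: with plain Euclidean
distance the maximum attainable `Dbk` on the unit cube is `sqrt(3)`
(the default, `darkness_params()`), while the squared-Euclidean maximum is
3 (`darkness_params("squared_euclidean")`).  A Euclidean metric with
`dmax = 3` is also accepted; it offsets every darkness value by
`3 - sqrt(3)` and changes no ordering, no envelope, and no label — only the
scale on which `odk` is reported.  Results produced under different
conventions should not be pooled, which is why the convention is part of
`run_config()` and serialized with every output.

## Envelope estimation and the pattern/background split

The darkness profile of a banded body part oscillates between two smooth
"envelopes": the lower one tracks the background, the upper one the pattern
elements.  Both are estimated with SNIP (statistics-sensitive non-linear
iterative peak clipping): for window sizes `p = 1 … m`, each value is
replaced by `min(y_i, (y_{i-p} + y_{i+p})/2)`, simultaneously within a
pass.  The baseline of the values is the lower envelope; the negated
baseline of the negated values is the upper one.  Positions strictly above
the midpoint ("median line") of the two envelopes are labeled *pattern*,
the rest *background*; ties go to background, so a perfectly flat profile
has `pat = 0` rather than an arbitrary split.

Numerical choices that required care:

* **Window schedule.** The maximum window defaults to
  `floor(segment_length / 4)` — large enough to clip a pattern element up
  to about half the segment long into the baseline, small enough that the
  envelope still follows slow illumination trends.  It is configurable
  (`snip_window`) because transects with unusually wide bands need a
  window exceeding half the widest band.
* **Boundary policy.** Out-of-range neighbors are supplied by the odd
  (point-symmetric) extension of the *input* sequence through its boundary
  value, floored at that boundary value.  The linear extrapolation keeps
  flat and linear profiles exact fixed points of the clipping (clamping
  the index instead would erode a ramp's upper end); taking it from the
  input rather than the evolving baseline lets the upper envelope's "drag"
  from a band propagate all the way to the segment ends (otherwise
  positions near the ends keep an envelope glued to the noise and are
  mislabeled); and the floor prevents a band that sits close to a boundary
  from being mirrored into a phantom valley that would drag the baseline
  spuriously low.
* **No pre-smoothing.** The perpendicular averaging at extraction is the
  only denoising before SNIP; an optional moving-average pre-filter was
  considered and rejected because it widens band edges, biasing `pat`.

## Color clusters, trimming, and angles

The envelope labels define the two pixel clusters used everywhere
downstream; we deliberately use one segmentation for both the pattern
fraction and the colors, rather than re-clustering the RGB values
separately, so that `pat`, `cpa`, and `cbk` describe the same pixels.  The
95% rule is interpreted as an outlier trim within each cluster: each class
keeps the `ceiling(0.95 n)` pixels nearest its RGB centroid, discarding
band-edge and stray pixels (ties broken by position index for
determinism).  The trim fraction is configurable (`keep_fraction`).

Each cluster's color is summarized by the angle between its best-fit color
line and the gray (black–white) diagonal — a measure of how far the cuticle
color deviates from neutral gray, insensitive to brightness.  The line is
the total-least-squares fit: through the centroid, along the first
principal axis of the centered cloud.  Two degenerate situations fall back
to the direction from black to the centroid, with a flag recorded in the
trait table:

* zero total variance (all pixels identical), and
* *no dominant axis*: when the leading eigenvalue carries less than 60% of
  the total variance, the cloud is a noise ball and the principal
  direction is sampling noise, not color structure.  The black-to-centroid
  ray is the stable estimator there, and for cuticle pixels it is exactly
  the brightness axis along which a homogeneous region varies.  Clouds
  with genuine 1-D structure (brightness gradients, exactly collinear
  constructions) stay on the TLS path, which recovers their direction to
  numerical precision.

An empty cluster (for example, no pattern detected on a uniform transect)
yields a *missing* angle, never zero — a zero would silently pull group
means toward gray.

`ran` complements the angles with a magnitude: the RGB distance between
the componentwise median colors of the 20 darkest and 20 lightest pixels
(darkness rank, ties broken by position).  It needs at least 40 unmasked
positions; shorter transects either error or, with `allow_short_ran`, fall
back to `k = floor(n/2)` with a warning.  Because it is built from ranked
extremes, `ran` carries a small positive selection bias under pixel noise
(about `2.6 sd` of the per-position darkness noise for typical class
sizes); at the default noise of the synthetic generator (sd 0.02) this
bias is ≈ 0.05 RGB units, and it vanishes on noise-free input.

## What the synthetic generator emulates — and what it does not

`generate_transect()` builds a 1-D transect from a recorded truth: a
lighter background cuticle color, a darker pattern color on half-open band
intervals (hard edges by default, logistic edges of configurable width as
an option), additive i.i.d. Gaussian channel noise clipped to the unit
cube (sd 0.02 by default, the upper end of what the perpendicular-averaged
profiles of a well-exposed 8-bit camera show), and an optional linear
additive illumination gradient.  `generate_fly_image()` renders the same
structure as a 2-D body — thorax with a central trident band, abdomen with
three segment bands — on a dish-colored canvas, adds pixel noise (sd 0.01
by default, before the five-pixel averaging), snaps intensities to the
8-bit grid so a written PNG re-reads bit-identically, and emits the
landmark endpoints and truth JSON that make the measured transect cross
known ground truth.  `generate_population()` layers a strain × sex ×
temperature design on top: flies developed at the colder temperature get a
darker pattern color (−0.12 per channel by default), males slightly darker
than females (−0.04), with per-fly Gaussian color jitter (sd 0.02)
standing in for genetic and micro-environmental variation.

Passing recovery tests on these constructions shows that the *estimators*
are correct and stable under stationary noise; it does not certify
performance on real images.  The generator does not emulate specular
highlights (the imaging protocol avoids them by submerging specimens),
3-D body curvature shading, bristle shadows, focus gradients, or spatially
correlated sensor noise.  In particular, an additive illumination gradient
moves both clusters' colors along the gray axis: with a strong gradient the
color-line fits align with gray and the angles shrink toward zero — on
real data, controlled illumination and white balance at acquisition are
doing work that no downstream estimator can undo.

## Statistical summaries

`group_summary()` gives per-group trait means, SDs (n−1), and missing
counts; missing angles are excluded rather than imputed.
`correlation_matrix()` computes all unique Pearson pairs among the five
traits within each group, with two-sided p-values and Holm adjustment
across the group's family of cells (pairwise-complete observations, per-
cell n reported; cells with fewer than three complete pairs are left
missing and excluded from the family).  To reproduce matrices that mix
body parts, `widen_body_parts()` turns the fly × body-part table into one
row per fly with `odk_thorax`, `odk_abdomen`, … columns, and all unique
off-diagonal cells of that wider matrix form one Holm family.  Model-based
inference (mixed models, multivariate regression, post hoc contrasts) is
intentionally out of scope: the package emits tidy TSV trait tables that
drop directly into any modeling environment.

## Problem sizes and determinism

The validation suite runs entirely on synthetic data built at test time:
1-D recovery uses 100 seeded replicates of 200-position transects,
image-based recovery 50 seeded replicates of a 170 × 320 rendered fly, and
the null-correlation simulation 500 seeded replicates of a 20-row,
10-cell family — sizes at which every property is stable yet the whole
suite completes in well under a minute.  The measurement pipeline itself
contains no randomness: identical images, landmarks, and configuration
yield byte-identical trait tables, and every output file carries a JSON
sidecar with the serialized `run_config()` and package version.

## Known limitations

* Landmarks are taken as given; anatomical landmark detection is out of
  scope, as is automatic segmentation of the body outline.
* The envelope split assumes pattern elements are *darker* than the
  background; inverted (light-on-dark) patterns would need the labels
  swapped.
* `pat` inherits a one-to-two-position uncertainty per band edge from
  sampling and interpolation; on short transects with many bands this is
  the dominant error term.
* The debris screen cannot detect debris that is wide, or debris lying on
  a pattern element whose own contrast already dominates the MAD; visual
  QC of rejected-and-accepted lists remains advisable.
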