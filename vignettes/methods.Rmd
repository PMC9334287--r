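---
title: "Methods: radiographic flatfoot angles from bone masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiographic flatfoot angles from bone masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footangles)
```

## The measurement problem

Pes planus (flatfoot) is assessed on standing lateral radiographs through
two angles. The Meary angle is the angle between the long axes of the
talus and the first metatarsus; a collapsed medial arch tilts the talus
plantarward relative to the metatarsus. The calcaneal pitch is the angle
between the inferior border of the calcaneus and the weightbearing
surface. The clinical cutoffs implemented here are Meary < −4° and pitch
< 18°, both strict (a foot measured exactly at the boundary is classified
non-PP, because the clinical rules are phrased as "less than").

Neither angle has a unique accepted construction: readers differ in where
they draw each bone axis. This package fixes one fully specified,
reproducible construction that operates on per-bone label masks, so that a
segmentation model plus this geometry yields a deterministic measurement,
and a measurer can still override any suggested landmark.

## Coordinate conventions

All geometry uses raster coordinates: the origin at the top-left pixel,
x increasing rightward, y increasing **downward**, in pixel units. The
canonical orientation has the toes pointing toward +x; left-foot masks are
mirrored on entry and results mapped back. Declination of a line is the
signed angle from the horizontal, positive when the line descends (tilts
plantarward) going anteriorly. Under these conventions the Meary angle is

\[ \mathrm{MA} = \delta(\text{metatarsal axis}) - \delta(\text{talar axis}), \]

which makes arch collapse negative, consistent with the < −4° cutoff. The
published verbal definition of the sign ("positive when the metatarsal
axis is plantarly tilted less than the talar axis") contradicts that
cutoff under standard arch-collapse anatomy; this implementation treats
the cutoff as normative and exposes `sign_flip = TRUE` for the opposite
reading. Pitch is reported as the unsigned acute angle in [0°, 90°); a
calcaneal border dipping below its own support (non-physiologic) still
yields the acute magnitude, with a warning.

## Landmark constructions

**Talar axis.** The principal axis of the talus mask (dominant eigenvector
of the pixel-coordinate covariance, anchored at the centroid, sign-fixed
to dx > 0, ties broken toward +x) orients the bone. Chords are taken
perpendicular to it at fixed fractions of the projected extent: 0.35
(talar body) and 0.78 (talar neck). These defaults are a design choice —
the clinical description names only "body" and "neck" — selected so the
body chord is the longer of the two, as in the clinical drawing; both are
configurable. Each chord midpoint averages the most extreme boundary
pixels on either margin within a band whose width is 1.8% of the bone
extent (about 2 px at default resolution): averaging about one pixel per
column damps the half-pixel jitter of single extreme pixels, which
otherwise dominates the short body–neck baseline. The talar axis joins
the two midpoints.

**Metatarsal axis.** A 101-station width profile is measured perpendicular
to the principal axis over stations at fractions 0.05–0.95 of the
projected extent. The diaphyseal width is the minimum over stations in
[0.30, 0.70]. Walking outward from 0.30 toward the proximal end, the
proximal metaphyseal–diaphyseal junction is the first station whose width
**strictly exceeds** 1.20× that minimum; the distal junction is symmetric
from 0.70 outward. The multiplier is configurable; 1.20 places the
junction on the flare ramp while staying clear of width-measurement noise
(±1 px on a ~24 px shaft is 4%). A bone with no detectable flare (e.g. a
uniform bar) falls back to stations 0.15 and 0.85 with a warning. The
axis joins the chord midpoints at the two junction stations.

**Inferior calcaneal tangent.** The convex hull of the calcaneal outline
(8-connected boundary pixels) is computed; among lower-hull edges (outward
normal pointing toward +y) the edge with the greatest horizontal span is
selected. Because rasterization breaks a straight border into several
near-collinear hull edges, the tangent is refit by orthogonal regression
through all hull vertices within a tolerance (0.75 px or 0.75% of the
hull width, whichever is larger) of the winning edge's line, then slid
plantarward to remain a supporting line of the hull. The tangent contacts
are the extreme hull vertices on that supporting line, projected onto it.
By construction the entire bone lies on or above the returned line within
rasterization tolerance.

**Weightbearing surface.** The line through the lowest pixel of the
calcaneus (ties broken toward smaller x, the posterior heel) and the
lowest pixel of the first metatarsus (ties toward larger x, the distal
head). Clinical practice often uses the fifth metatarsal head for the
anterior contact, but only three bones are segmented here; using the
first metatarsus instead is a documented deviation, harmless when both
contacts lie on the same physical floor line. With no metatarsus the
fallback is a horizontal line through the calcaneal contact.

**Overrides.** Any subset of the eight landmarks can be replaced by
measurer-supplied coordinates (provenance is tracked per point); supplying
all eight is fully manual measurement and bypasses extraction. Overrides
must stay inside the raster and respect the posterior-to-anterior ordering
invariants.

## Reliability statistics

*Dice.* \(2|A\cap B| / (|A|+|B|)\) per bone label by direct pixel
counting; 1.0 when the label is absent from both masks.

*Intra-observer ICC.* One-way random single-measures ICC(1,1)
\((MS_B - MS_W)/(MS_B + (k-1)MS_W)\), with the exact F confidence
interval: with \(F = MS_B/MS_W\), \(F_L = F / F_{0.975}(n-1, n(k-1))\),
\(F_U = F \cdot F_{0.975}(n(k-1), n-1)\), bounds
\((F_L-1)/(F_L+k-1)\) and \((F_U-1)/(F_U+k-1)\). Sessions are treated as
unlabelled repeats, the standard model for repeatability.

*Inter-observer ICC.* Two-way random single-measures **absolute
agreement** ICC(A,1)
\((MS_R - MS_E)/(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))\), with
the McGraw–Wong confidence interval using Satterthwaite degrees of
freedom. Absolute agreement (not consistency) is used because systematic
reader offsets are genuine disagreement when measurements are compared
against each other and against a reference standard. A zero-variance
table returns an ICC of 1 with a degenerate interval and a warning —
perfect agreement is the semantically correct limit, not a failure.

*ICC differences.* Analytic intervals for a difference of dependent ICCs
depend on modelling choices that are hard to pin down; instead the package
uses a subject-level paired bootstrap (default 2000 replications):
subjects are resampled with replacement and both ICCs recomputed on each
resample, which preserves the within-subject correlation between the two
conditions (including correlation between readers, which analytic
formulas typically ignore). The 95% CI is the percentile interval; the
two-sided p-value is \(2\min(\hat P(d\le 0), \hat P(d\ge 0))\) with the
(b+1)/(B+1) correction, so p can never be exactly 0.

*Diagnostic metrics.* Sensitivity, specificity and accuracy in percent
with Wald intervals \(\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/m}\) clipped
to [0, 100]. The Wald form was adopted because it exactly reproduces, at
two-decimal rounding, the published interval arithmetic this package's
tests verify (e.g. 40/42 → lower bound 88.80). A metric whose denominator
class is absent is reported as NA rather than fabricated. Multi-reader
pooling is a micro-average: confusion counts are summed across readers
and the metrics recomputed on the pooled counts; with equal per-reader n
this equals the mean of the reader metrics. Paired comparisons of a
metric between two measurement conditions use the same subject-level
bootstrap as the ICC difference (default 1000 replications); resamples
where the metric is undefined are skipped and counted.

*Agreement bands.* ICC > 0.80 "very good", (0.60, 0.80] "good",
(0.40, 0.60] "moderate"; at or below 0.40 the label "fair/poor" is an
extrapolation beyond the three named clinical bands.

## The synthetic generator

Real weightbearing radiographs of validated cohorts are not openly
available, so every stage is tested against a generator that emits
silhouette "radiographs" with exact ground truth. Bones are stylized
parametric polygons, not anatomic outlines; the landmark constructions
only exploit the width-profile and tangency structure of the bones, which
the silhouettes reproduce:

- **calcaneus**: a chamfered quadrilateral whose inferior edge makes
  exactly the requested pitch angle with the horizontal ground line;
- **talus**: a tapered capsule along the requested talar declination,
  posterior (body) width 1.7× the anterior (neck) width;
- **first metatarsus**: a shaft along the requested metatarsal
  declination with diaphyseal full width 0.6 length-units and metaphyseal
  flares 1.5× that width ramping over the outer 15% of the bone.

The lowest pixels of the calcaneus and metatarsus are placed exactly on
the ground row, so the weightbearing surface is horizontal and the truth
pitch is realized exactly; the truth Meary angle is the difference of the
two declinations by construction. The image channel is the mask with
per-bone intensities plus additive Gaussian noise (sd 8 of 255); masks are
noise-free ground truth because the geometry consumes masks, not
intensities. Optional vertex jitter (`boundary_noise_sd`, default 0)
roughens the silhouettes at the cost of exact truth. Default canvas
384×512 at 40 px per length-unit; everything is reproducible from
`rng_seed`, and left-sided samples are exact mirrors of the right-sided
ones.

Cohorts stratify by the Meary criterion: a PP stratum with truth Meary
uniform in [−25°, −5°) and pitch in [8°, 16°], and a non-PP stratum with
Meary in [−3°, 12°] and pitch in [20°, 32°]; metatarsal declination is
uniform in [6°, 14°] and the talar declination realizes the drawn Meary
angle. These ranges are a design choice that brackets the clinical
cutoffs with margin (no truth angle within 1° of a cutoff), so
classification tests are not dominated by boundary flakiness; they are
*not* a model of any real patient population's angle distribution.

Mask degradation emulates imperfect segmentation: balanced random erosion
and dilation of each bone's boundary until the per-bone Dice against the
original reaches the target within ±0.02, preserving 4-connectivity
(re-drawing the perturbation if a draw fragments the bone). This permits
testing the pipeline at the published segmentation quality levels
(Dice ≈ 0.93–0.98).

What the generator does **not** emulate: radiographic physics, soft
tissue, overlapping bone projections, the navicular/cuboid/fifth
metatarsus, anatomically realistic outlines, or real segmentation-model
failure modes (which are structured, not i.i.d. boundary noise). Passing
tests therefore demonstrate the correctness and stability of the geometry
and statistics, not clinical performance on real radiographs.

## Numerical choices and degenerate inputs

- Rasterization: even-odd scanline fill at integer pixel centres; an
  isolated corner pixel left by the fill is removed by keeping each
  bone's largest 4-connected component.
- Fragmented labels (real segmenters can split a bone): accepted with a
  warning; all geometry uses the largest 4-connected fragment.
- Chord bands and collinearity tolerances scale with bone extent so the
  constructions are invariant under uniform scaling; the floor values
  (0.6–0.8 px) are the rasterization noise floor.
- Principal-axis ties (isotropic shapes) resolve toward +x; junction
  detection uses strictly-greater comparison at the 1.20 multiplier.
- Invariances verified by tests: translation and integer pixel-replication
  scaling change both angles by < 0.1°; rigid rotation of the whole scene
  by up to ±10° changes them by < 0.7°. Fractional nearest-neighbour
  resampling (e.g. ×0.5) discards boundary information and is not held to
  the 0.1° bound.
- All stochastic operations (generator, degradation, bootstraps) are
  bit-reproducible from explicit integer seeds and restore the caller's
  RNG state.

## Problem sizes

The shipped tests exercise 50-sample synthetic cohorts for ground-truth
recovery (mean absolute error ≈ 0.2° for the Meary angle and ≈ 0.1° for
pitch at default resolution), 200 random tables for ICC-oracle
equivalence at 10⁻¹⁰, and bootstraps of 300–1000 replications; these
sizes give stable results while keeping the default suite fast.

## Known limitations

- The anterior weightbearing contact uses the first metatarsal head
  (fifth metatarsus is not segmented).
- The talar chord stations and the junction multiplier are operational
  choices; other clinics' drawing conventions correspond to other
  parameter values.
- The bootstrap ICC-difference inference is not numerically identical to
  any particular analytic dependent-ICC interval; published p-values
  computed with such formulas will differ even on identical data.
- DICOM support covers single-frame monochrome files in little-endian
  transfer syntaxes (the common export for radiographs); compressed,
  multi-frame or colour DICOM is out of scope.

## Configuration

`run_config()` collects the tunables (chord stations, junction
multiplier, sign convention, cutoffs, bootstrap size, seed), optionally
from a YAML file with per-call overrides; every command logs its resolved
configuration so any two runs with identical configuration and inputs
produce identical outputs.
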