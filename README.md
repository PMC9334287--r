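# footangles

Radiographic flatfoot (pes planus) assessment from per-bone masks of
lateral weightbearing foot radiographs.

Flatfoot is diagnosed and staged on standing lateral radiographs using two
standard angles. The **Meary angle** (talo–first metatarsal angle) is the
angle between the long axis of the talus and the long axis of the first
metatarsus; arch collapse drives it negative, and values below **−4°**
indicate pes planus. The **calcaneal pitch** is the angle between the line
outlining the inferior border of the calcaneus and the weightbearing
surface; values below **18°** indicate pes planus. Both angles are
notoriously reader-dependent: where exactly each bone axis is drawn varies
between observers, which limits the reproducibility of diagnosis and of
surgical follow-up.

`footangles` is for researchers building or validating (semi-)automated
measurement tools for these angles. Given label masks of the talus, first
metatarsus and calcaneus — from any external segmentation model, or from
the package's own synthetic generator — it:

- derives the angle-defining landmarks geometrically:
  - *talar axis*: the line through the midpoints of chords across the
    talar **body** and talar **neck**, taken perpendicular to the bone's
    principal axis;
  - *metatarsal axis*: the line through the chord midpoints at the
    proximal and distal **metaphyseal–diaphyseal junctions**, detected
    from the bone's width profile (the junction is where the width first
    exceeds 1.20× the mid-shaft minimum);
  - *inferior calcaneal tangent*: the widest lower convex-hull edge of the
    calcaneus, refit through all collinear boundary vertices;
  - *weightbearing surface*: the line through the lowest points of the
    calcaneus and the first metatarsus;
- supports programmatic landmark overrides (the batch counterpart of a
  measurer adjusting a suggested landmark), up to fully manual
  measurement;
- computes both angles, applies the cutoffs (strict inequalities;
  boundary values are non-PP), and writes standard CSV/JSON/PNG artifacts;
- implements the complete reader-reliability statistics used in validation
  studies of such tools: Dice similarity coefficients; single-measures
  intraclass correlation coefficients under the one-way random model
  (intra-observer, exact F confidence interval) and the two-way random
  absolute-agreement model (inter-observer, McGraw–Wong interval);
  subject-level paired bootstrap inference on ICC differences; Altman
  agreement bands; sensitivity/specificity/accuracy with Wald intervals;
  micro-averaged reader pooling; and paired bootstrap comparison of
  diagnostic metrics between measurement conditions.

Sign convention: the Meary angle is reported as metatarsal declination
minus talar declination, so arch collapse (talus tilted more plantarward
than the metatarsus) is negative, consistent with the < −4° cutoff. The
opposite convention is available via `sign_flip = TRUE`.

## Worked example

```r
library(footangles)

# a synthetic lateral "radiograph": talus tilted 20 deg plantarward,
# first metatarsus 10 deg, calcaneal pitch 22 deg
spec <- foot_spec(talar_declination = 20, metatarsal_declination = 10,
                  calcaneal_pitch = 22, rng_seed = 1)
sample <- generate_foot(spec)
sample
#> <foot_sample> 384x512 right foot: Meary -10.0 deg, pitch 22.0 deg
#>   (PP-by-Meary/non-PP-by-pitch)

measure_foot(sample$mask)
#> <foot_measurement> right foot (automatic landmarks)
#>   Meary angle:       -9.71 deg  -> pes planus
#>   Calcaneal pitch:   21.99 deg  -> non-pes planus
```

The ground truth (−10°, 22°) is recovered within a fraction of a degree,
and the classification follows the cutoffs: Meary −9.71 < −4 is pes
planus, pitch 21.99 ≥ 18 is not.

```r
# inter-observer agreement of a 6-subject x 3-reader ratings table
x <- matrix(c(9,10,8, 6,7,5, 8,8,9, 7,5,6, 10,12,11, 6,4,5),
            6, 3, byrow = TRUE)
icc_twoway_random_single(x)
#> <icc_result> twoway_random_single_agreement: 0.845 (95% CI 0.511-0.974),
#>   n=6 k=3 [very good]

# diagnostic metrics with Wald intervals from confusion counts
diagnostic_from_counts(tp = 40, fn = 2, tn = 41, fp = 12)
#> <diagnostic_summary> tp=40 fn=2 tn=41 fp=12
#>   sensitivity   95.24% (88.80-100.00)
#>   specificity   77.36% (66.09-88.63)
#>   accuracy      85.26% (78.14-92.39)
```

A command-line front end over the same functions ships in
`inst/cli/footangles.R` with the subcommands `simulate`, `measure`,
`evaluate-seg` and `reliability`.

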