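Package: footangles
Title: Automated Meary Angle and Calcaneal Pitch Measurement from Foot
    Radiograph Bone Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric extraction of the anatomical landmarks that define the
    Meary angle (talo-first metatarsal angle) and the calcaneal pitch on
    lateral weightbearing foot radiographs, starting from per-bone label masks
    of the talus, first metatarsus and calcaneus. Computes both angles,
    classifies pes planus against the standard clinical cutoffs (Meary < -4
    degrees, pitch < 18 degrees), and provides the complete reader-reliability
    statistical suite used to validate such tools: Dice similarity
    coefficients, single-measures intraclass correlation coefficients
    (one-way and two-way random models) with 95% confidence intervals, paired
    bootstrap inference on ICC differences, Altman agreement bands, and
    diagnostic sensitivity/specificity/accuracy with Wald intervals and
    reader pooling. A synthetic foot-silhouette generator with known
    ground-truth landmarks and angles makes every stage testable without
    clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
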