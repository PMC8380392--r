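Package: vestcomp
Title: Quantification of Vestibular Compensation in Rodent Lesion Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification chain for behavioral and cellular readouts of
    vestibular compensation after unilateral vestibular lesion in rodents.
    Computes posturographic metrics from dynamic weight-bearing recordings
    (force-weighted barycenter, statokinesigram, barycenter inertia,
    laterality index, rearing time, abdomen load, circling), open-field
    locomotor kinematics (distance, velocity, acceleration, body torsion),
    image-derived quantities (landing support surface, membrane
    immunofluorescence intensity, counting-frame cell counts, colocalization
    and survival percentages), and a cumulative vestibular-syndrome score.
    A statistical layer provides D'Agostino-Pearson normality screening,
    independent and split-plot two-way ANOVA, and Tukey multiple comparisons
    reported as studentized-range q ratios. A synthetic-cohort generator
    with group-specific exponential recovery kinetics makes every pipeline
    stage testable end to end, including parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
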