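Package: spinemech
Title: Motion-Segment Biomechanics: Hysteresis, Creep and Failure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for vertebra-disc-vertebra motion-segment
    mechanical tests in small-animal spine studies. Parameterizes cyclic
    tension-compression and torsion hysteresis loops (limb stiffnesses, range
    of motion, neutral-zone length, load and torque range), fits a
    five-parameter viscoelastic solid (elastic spring in series with two
    Kelvin-Voigt arms) to constant-load creep tests, detects failure strength
    and angle-to-failure on torsion-to-failure ramps, computes disc height
    index and histomorphometric ratios, and runs the per-sex two-way
    genotype-by-diet ANOVA layer with Tukey post-hoc comparisons. A synthetic
    recording and cohort generator emulates the full factorial experiment so
    every stage can be exercised and validated without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
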