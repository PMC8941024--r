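Package: nestclim
Title: Microclimate, Solar Irradiance Quality Control and Nest Development
    Analysis for Incipient Leaf-Cutting Ant Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the microclimate experienced by founding
    leaf-cutting ant (Atta sexdens) queens in sunny and shaded environments and
    the development of their incipient nests. Computes solar geometry and
    extraterrestrial irradiance, applies physically-possible-limit quality
    control to 5-minute pyranometer series and integrates them to daily
    irradiation totals (MJ/m2), scores agreement between paired microclimate
    series with the Willmott index, derives initial-chamber volumes from
    excavated nest dimensions, and runs the comparison battery used for such
    field studies: equal-proportions mortality test, Shapiro-Wilk routing,
    two-way factorial ANOVA with Tukey letters, the Scheirer-Ray-Hare rank
    test, and Dunn's post-hoc test with false-discovery-rate correction. A
    synthetic-data generator emulates the field inputs (irradiance, coupled
    temperatures, nest censuses) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
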