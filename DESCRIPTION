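Package: granulofit
Title: Deconvolution and Phenotyping of Bimodal Starch Granule Size
    Distributions
Version: 0.1.0
Authors@R:
    person("granulofit", "developers", email = "granulofit@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing binned volumetric particle-size traces of
    cereal starch granules, as produced by Coulter-counter class
    instruments. Converts log-binned volume-percentage traces to
    percent-density, deconvolves them into A-type and B-type log-normal
    components by bounded nonlinear least squares, extracts granule
    phenotypes (B-type volume percentage, mean A/B diameters, granules per
    mg grain, percentage of small granules), detects bimodality along a
    developmental time course, and compares genotypes with one-way ANOVA
    and Tukey-adjusted pairwise contrasts. Includes a synthetic
    granule-population and measurement simulator so that the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
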