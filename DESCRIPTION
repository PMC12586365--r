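Package: rhizodyn
Title: Growth Dynamics and Resource Allocation of Rhizomatous Clonal Plants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing seasonal growth dynamics of rhizomatous
    clonal grasses monitored across patches of different sizes. Fits three
    nonlinear growth families (power logistic, BiHill, and a bimodal
    two-component dose-response sigmoid) to per-cluster trait increment
    series, extracts derivative-based phenological parameters (onset, rapid
    growth, peak rate, stabilisation and termination dates, and the growth
    periods between them, including a second phase for bimodal rhizome
    growth), and quantifies resource-allocation shifts along the patch-size
    gradient via trait-increment ratios, standardized major axis (SMA)
    allometry with a slope-versus-isometry test, and group comparisons
    (Brown-Forsythe homogeneity check, classic or Welch one-way ANOVA, LSD
    or Games-Howell post hoc with compact letter displays). A seeded
    synthetic-campaign generator emulates the monitoring design so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    car,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
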