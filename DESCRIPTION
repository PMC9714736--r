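Package: echinofert
Title: Temperature and pH Effects on Echinoderm Fertilization and Sperm Performance
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-stressor reproduction experiments in
    broadcast-spawning echinoderms (sand dollars, sea urchins). Generates
    seeded synthetic fertilization and sperm-tracking datasets with the
    structure of single-factor temperature and factorial temperature-by-pH
    assay designs; computes sperm curvilinear velocity (VCL) and motility
    from 2-D tracks; fits a registry of thermal performance curve (TPC)
    models by bounded multistart nonlinear least squares, ranks them by
    small-sample AICc, and derives maximum rate, thermal optimum and
    thermal breadth with residual-bootstrap confidence intervals;
    implements a fertilization kinetics model linking sperm swimming
    velocity to predicted fertilization and fits its rate-constant ratio;
    and provides aligned-rank-transform (ART) factorial ANOVA with effect
    sizes, Bonferroni post-hoc contrasts and rank correlations. A
    deterministic pipeline orchestrates all stages from a config file.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
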