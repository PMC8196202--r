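Package: cohortsimplex
Title: Archetype Geometry, Enrichment and Trajectory Analysis for Cohort
    Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a minimal-volume enclosing simplex (line, triangle,
    tetrahedron, ...) to a z-scored cohort feature matrix in reduced
    principal-component space, following the Pareto task inference view of
    phenotypic trade-offs: data points are treated as approximate convex
    combinations of a small number of extreme profiles (archetypes).
    Significance of the fitted simplex is assessed with a column-shuffle null
    on the simplex-to-hull volume ratio (t-ratio), archetype uncertainty by
    bootstrap, and the number of archetypes by a corrected scan.  Archetypes
    are characterized by first-bin enrichment of continuous (Welch t) and
    discrete (hypergeometric) traits under Bonferroni control, trade-offs are
    profiled via distance and principal-component correlations, and
    longitudinal visits are projected into the fitted model space to rank
    individual trajectories and flag out-of-simplex excursions.  A synthetic
    cohort generator with full ground truth (simplex-distributed samples,
    planted enrichable traits, tumble/drift/escape trajectories) makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
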