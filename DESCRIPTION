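Package: organoidsim
Title: Off-Lattice Agent-Based Simulation and Morphometric Classification
    of Tumor Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of three-dimensional tumor organoids with a
    center-based, off-lattice agent model: cells interact through Hookean
    repulsive and adhesive springs, relocate by overdamped dynamics, progress
    through a four-phase cell cycle, and arrest under contact inhibition when
    their local neighborhood is too crowded. Organoid morphology is quantified
    by projection-averaged diameter, radius of gyration and a Monte-Carlo
    estimate of the accessible surface area of the union of cell spheres.
    Includes a growth-curve calibration gate based on the coefficient of
    determination, a replicated parameter sweep over cell radius, division age
    and contact-inhibition threshold that produces heatmaps and morphocharts,
    and k-medians clustering of organoids into four morphophenotypic classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
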