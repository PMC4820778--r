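Package: villomorph
Title: 3D Morphometry of Isolated Placental Villous Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative 3D analysis of skeletonized tracings of isolated
    peripheral villous trees of the human placenta. Reads SWC tracings,
    decomposes them into branches and nodes, assigns terminal-distance
    orders (bT0, bT1, bT2), and measures planar branching angles,
    tortuosity, and frustum-based length, surface area and volume per
    branch. Aggregates measurements per specimen, classifies clinically
    normal placentas into high- and low-tortuosity subgroups at a
    preterminal tortuosity cutoff, and runs the full comparison battery:
    Kruskal-Wallis with Dunn's post-hoc contrasts, Student's t, rose
    diagrams with circular kernel mode detection, and Hartigan's dip test
    with a Monte-Carlo null. Includes a synthetic cohort generator with
    recorded ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
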