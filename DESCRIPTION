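Package: capsidkit
Title: Icosahedral Capsid Architectures and Genome-Based Capsid Size Prediction for Tailed Phages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the geometry and allometry of tailed-phage icosahedral
    capsids. Implements the generalized triangulation-number (T-number) algebra
    over the four Archimedean icosahedral lattices (hexagonal, trihexagonal,
    snub hexagonal, rhombitrihexagonal), builds 3D polygonal cage meshes of any
    capsid architecture with a polyhedron-to-sphere sphericity parameter and
    OBJ/OFF/BILD writers, derives structural metrics (shell thickness, genome
    packing density, per-protein surface areas) from capsid measurement tables,
    fits log-log allometric models relating genome length and capsid diameter
    to the T-number with standard errors and prediction intervals, and
    classifies phage genomes to their nearest model-mean capsid architecture to
    flag small-capsid (T <= 4) candidates. Includes synthetic-data generators
    for capsid measurement tables and multimodal genome-length collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
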