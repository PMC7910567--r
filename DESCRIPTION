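Package: icebindr
Title: Ice Growth, Polymer Binding and Free-Energy Analysis for Molecular Configurations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantifying ice growth and polymer-ice
    interaction in molecular configurations: Steinhardt s6 ice/liquid
    classification and largest-cluster detection, geometric hydrogen-bond and
    polymer binding-time analysis, alpha-shape occupied volume and projected
    ice contact area, ice-front tracking and overgrowth classification, and
    well-tempered metadynamics free-energy reconstruction over the radius of
    gyration. Includes generators for synthetic hexagonal-ice slabs, liquid
    layers, vinyl-alcohol/vinyl-amine polymers and scripted growth movies, plus
    readers and writers for GRO, PDB and extended-XYZ structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
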