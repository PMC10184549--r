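Package: cavex
Title: Landmark-Guided Extraction and Alpha-Shape Volumetry of Skeletal Cavities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic extraction of skeletal cavities and fossae (nasal cavity,
    maxillary sinuses, orbits, upper oral cavity, frontal sinuses and other
    enclosed voids) from 3D surface meshes of crania, driven by a configuration
    of anatomical landmarks. Cavities are isolated by landmark-defined cutting
    planes and line-of-sight (point-of-view and laser-scanner-emulation)
    surface selection, and their volumes are computed from 3D alpha-shapes
    built on a Delaunay tetrahedralisation, by empty-voxel counting with an
    exact tetrahedron-sum cross-check. Includes readers and writers for PLY,
    STL and OBJ surface meshes, quadric edge-collapse decimation, a
    deterministic generator of phantom "crania" with analytically known cavity
    volumes for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
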