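Package: cortifrac
Title: Simulation of Cortical Bone Fractures on Triangle Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates long-bone fractures by projecting two-dimensional
    fracture patterns (transverse, oblique, spiral, wedge, comminuted)
    onto three-dimensional two-layer cortical bone meshes. The mesh is
    fragmented along the projected pattern using quality-guided cutting
    strategies (approximation, subdivision, hybrid), fragments are closed
    across the cortical thickness by a constrained triangulation of the
    fracture zone that leaves the medullary canal hollow, and controlled
    perturbations add surface roughness. Simulated fractures are compared
    with reference fractures through height maps over the fracture zone
    (mean map values, ranges, and thickness-ratio scaling). Includes a
    deterministic synthetic generator of two-layer cortical shells; STL,
    PLY and OBJ mesh input/output; fracture-zone detection on fragment
    meshes; and pattern extraction back to two dimensions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
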