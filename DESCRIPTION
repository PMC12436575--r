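Package: osteogrow
Title: Osteoconnectivity-Based Simulation of Bone Ingrowth into Porous
    Swelling Bone Anchors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Finite-element simulation of sequential bone ingrowth into
    porous, hygroscopically swelling co-polymeric bone anchors. Generates
    synthetic salt-leached porous anchor geometries, computes the
    swelling-induced radial pressure at the bone-anchor interface with a
    plane-strain hygro-elastic solver, and evolves apparent bone density
    in the pore space with a strain-energy-density remodeling rule gated
    by an osteoconnectivity (element adjacency) matrix, so that new bone
    forms only next to existing bone. Post-ingrowth mechanics include
    apparent compressive stiffness and a push-out fixation model with
    Coulomb friction and Johnson-Cook plastic failure of newly formed
    bone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
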