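Package: cyanomech
Title: Structural Mechanics of Filamentous Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the bending mechanics of filamentous
    cyanobacteria (and other slender microbial filaments) from microfluidic
    flow-cell deflection experiments. Implements the laminar flow field of a
    rectangular channel (Boussinesq series solution), low-Reynolds-number
    cylinder drag, linearized cantilever beam integration, and a least-squares
    inverse procedure that estimates the bending stiffness and a solid-body
    rotation from paired rest/deflected filament shapes. Also provides
    filament shape statistics (skeleton tracing, tangent-angle and curvature
    profiles, Pratt circle fits, worm-like-chain persistence length), derived
    cell-wall mechanics (wall thickness, maximal wall stress, bending energy
    density) with delta-method uncertainty propagation, and a synthetic-data
    generator that emulates every input of the pipeline for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    jsonlite,
    withr,
    stats,
    tools,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    yaml
Config/testthat/edition: 3
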