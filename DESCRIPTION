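Package: clonetree3d
Title: 3D Spatio-Temporal Lineage Trees of Cellular Clones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and renders three-dimensional lineage trees of cellular
    clones from agent-based simulations of tumor evolution. Branches connect
    mother and daughter cells in a coordinate system spanning two tissue axes
    and one scaled time axis, so that each clone's trajectory shows where in
    the tissue it arose and grew, not only when. Trees can be drawn for a
    single clone or for all clones, either with every cell ever recorded or
    pruned to the lineages that survive to the final time point, optionally
    over a four-band quantized map of a microenvironmental factor such as a
    drug gradient. The package also bundles an off-lattice agent-based tumor
    growth simulator (proliferation, crowding, random and drug-induced death,
    mutation-born drug-resistant clones, reaction-diffusion drug transport
    from point vessels) that emits datasets in the package's plain-text
    exchange format, together with readers, writers and a dataset validator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
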