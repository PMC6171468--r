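Package: gliaflux
Title: Compartmental Neuro-Glio-Vascular Energy Metabolism Simulation and
    Surface-Mesh Morphometrics
Version: 0.9.0
Authors@R:
    person("Jules", "Renard", email = "jrenard@example.org",
           role = c("aut", "cre"))
Description: Simulates glutamate-driven brain energy metabolism in a
    compartmental neuron/astrocyte/extracellular-space/capillary unit
    (glycolysis, glycogenolysis, lactate shuttling, mitochondrial
    oxidation, creatine and NAD(H) pools, Na/K pumping), optionally driven
    by a Hodgkin-Huxley membrane with concentration-dependent reversal
    potentials, and tiles the unit model over a cubic voxel grid driven by
    synaptic release event streams.  A companion morphometrics suite
    quantifies labeled triangle surface meshes: radiance-transfer
    absorption maps from glycogen granules (GLAM), nearest-neighbor
    granule tallies, contact surface areas, organelle minimum distances
    and planar cross sections.  Includes procedural generators for
    synthetic neuropil scenes, granule distributions, Poisson event
    streams and drive protocols, so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
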