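Package: trxmap
Title: Difference Maps and Extrapolated Structure Factors for Time-Resolved Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for time-resolved (pump-probe) protein crystallography:
    direct-summation structure factors with Cromer-Mann form factors, amplitude
    scaling and q-weighted isomorphous difference structure factors, FFT Fourier
    synthesis of difference electron-density maps with sigma-level normalisation,
    signed difference-peak detection with nearest-atom attribution, extrapolated
    structure factors with negative-density alpha scanning and photoactivation
    population estimation, map-comparison statistics (difference-difference maps,
    local Pearson correlation in spheres), chromophore geometry metrics (torsions,
    Kabsch superposition, radial displacements), and photolysis photon-budget
    arithmetic. Ground-truth synthetic toy crystals (two-state amplitude mixing at
    a known population with Gaussian amplitude noise) make every stage testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
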