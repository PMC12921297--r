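Package: flashrecon
Title: Dose Reconstruction and Oxygen-Depletion Analysis for Laser-Driven
    Ultra-High Dose-Rate Electron Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for picosecond laser-driven relativistic
    electron beam dosimetry and radiochemistry at ultra-high (FLASH) dose
    rates. Provides a two-temperature exponential beam spectrum model,
    deterministic water-equivalent continuous-slowing-down (CSDA) transport
    through layered beamlines with hard-edge dipole magnets, radiochromic
    film dose-map input/output and region statistics, iterative spectrum
    reconstruction from film region doses, in-tank dose estimation with
    X-ray background correction, G-value based molecular-oxygen consumption
    yields, origin-constrained yield fitting from oxygen-meter time series,
    and a synthetic shot generator so the full pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
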