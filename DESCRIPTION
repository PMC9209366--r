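Package: cabinaer
Title: Size-Resolved Simulation of Particle and CO2 Concentrations in Vehicle Cabins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A size-resolved box model of passenger-car cabin air quality. Simulates
    per-size-channel particle concentrations (25 channels, 10 nm to 2.5 um) under HVAC
    filtration, recirculation, surface deposition and pressure-driven envelope
    infiltration, together with a cabin CO2 mass balance with an occupant breath
    source. Provides closed-form steady states and stiff transient integration,
    speed-dependent passive-ventilation and infiltration airflow submodels, a
    size-dependent cabin-filter efficiency table for new and aged filters with and
    without pre-ionization, synthetic traffic-like outdoor aerosol generation,
    sensitivity and recirculation sweeps, and the standard air-quality model
    evaluation statistics (FB, MG, VG, NMSE, FAC2, Pearson r) with published
    acceptance criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
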