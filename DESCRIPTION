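Package: vitreoflow
Title: Intravitreal Particle Disposition Analysis for Organotypic Ocular Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of intravitreal particle disposition in
    perfused whole eyes. Implements the closed-form poroelastic scaling of
    an intravitreal injection (advection time constant, Darcy velocity and
    transport length in the vitreous humour) with a numerical radial
    relaxation oracle; constant-flow perfusion quality control (pressure
    transducer calibration, outflow facility, inclusion gating and drug
    response detection); fluorescent microbead quantification (bead stock
    arithmetic, serial-dilution standard curves, plate-sample inversion,
    percent-of-injected normalisation, anterior dispersion-rate regression
    and species scaling ratios); particle counting with equivalent-diameter
    sizing from grayscale micrographs; and seeded synthetic-data generators
    that emulate every measurement stage so the full pipeline is testable
    without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
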