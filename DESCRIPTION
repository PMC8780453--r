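Package: sacmsim
Title: Simulated Supervisory Control of Automated Hemorrhage Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discrete-time simulation of a supervisory controller that
    coordinates two closed-loop trauma-care sub-systems: an adaptive fluid
    resuscitation controller that drives an infusion pump from mean arterial
    pressure via normalized pressure-volume relationships, and an automated
    pneumatic tourniquet that occludes an extremity bleed and reports
    loosening or mechanical failure. A flow-loop "patient" plant with
    configurable pressure-volume curves, pulsatile pressure waveforms,
    extremity and internal hemorrhage paths, and a cuff-occlusion model
    stands in for benchtop hardware, so controller tuning experiments and
    multi-complication trauma scenarios can be reproduced end-to-end on a
    desktop. Includes scenario definition files, telemetry logging, fluid
    balance accounting, interval binning, and heatmap export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
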