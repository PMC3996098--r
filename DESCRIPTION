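Package: dtitherm
Title: Bioheat Modelling of Heel Deep Tissue Injury for Dynamic Infrared Thermography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Finite-element solution of the Pennes bioheat equation on a layered
    two-dimensional heel cross-section with an embedded deep tissue injury (DTI)
    lesion. Simulates the steady skin temperature field and the dynamic
    infrared thermography protocol (one minute of 15 degree Celsius surface
    cooling followed by convective thermal recovery) for healthy tissue and for
    ischemic, inflammatory and multilayer lesion stages, and extracts the
    skin-surface thermal signatures (recovery curves at the sub-lesion point,
    periphery temperature profiles, and lesion-minus-healthy temperature
    differences) that distinguish the stages.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
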