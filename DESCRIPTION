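Package: memsaliva
Title: Simulated Memristive Neuromorphic Recognition of COPD from Saliva Attributes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end simulator of a mixed-signal neuromorphic classifier for
    chronic obstructive pulmonary disease (COPD) versus healthy controls from
    saliva dielectric permittivity and demographic attributes. Clinical records
    are thermometer/one-hot binarized into 23-bit patterns, a small 23-4-2
    sigmoid network is trained with mini-batch Adam and dropout, its 106 analog
    parameters are collapsed onto 10 signed discrete levels, and the quantized
    network is deployed onto a simulated 1T-1R RRAM synapse array (10 binary
    devices per parameter) whose read-out model includes device-to-device
    current variability, switching failures, non-linear I-V read-out, finite
    drive-voltage precision and per-read energy. Includes a synthetic cohort
    generator, a reader for the public Exasens CSV dialect, stratified 5-fold
    cross-validated evaluation with repeated hardware runs, and a command-line
    pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
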