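Package: ventdp
Title: Non-Invasive Transpulmonary Driving Pressure from Electrical
    Impedance Tomography and Airway Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate transpulmonary driving pressure (DP_L), lung
    elastance (EL) and elastance-derived inspiratory transpulmonary pressure
    (PI) in mechanically ventilated ARDS patients without an esophageal
    balloon, by combining airway-opening pressure mechanics with regional
    ventilation distribution from electrical impedance tomography (EIT).
    Includes a ventilator-waveform analyzer (breath segmentation, occlusion
    pause detection, airway and esophageal mechanics), EIT regional analysis
    (ensemble tidal image, four ventrodorsal regions of interest, weighted
    regional compliance), a five-regressor linear prediction model for DP_L
    (published coefficients or pooled-OLS refit on a patient-by-PEEP panel),
    agreement statistics (repeated-measures correlation, Bland-Altman limits
    of agreement, simple regression), a synthetic ARDS cohort generator based
    on two-compartment linear respiratory mechanics under volume-controlled
    ventilation, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
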