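Package: carboxyfit
Title: Rubisco Kinetics, FvCB Leaf Modelling and Carboxysome Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for transplastomic plants expressing
    cyanobacterial Form-1A Rubisco and carboxysomes. Provides dissolved-gas and
    partial-pressure unit conventions (including dual-basis CO2/O2 specificity),
    Michaelis-Menten estimation of Rubisco catalytic parameters from radiolabel
    assay series, the Farquhar-von Caemmerer-Berry C3 assimilation model (minimum
    of Rubisco- and electron-transport-limited rates) with a closed-form CO2
    compensation point, least-squares inversion of A-Ci curves for leaf Rubisco
    site content or turnover rate, carboxysome particle morphometry (rod
    classification, class proportions, replicate size-distribution modes), and a
    seeded synthetic-data generator emulating every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
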