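Package: petkin
Title: Quantification of Reversible PET Radioligand Kinetics from Arterial Input
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying brain pharmacokinetics of reversible PET
    radioligands (developed around the SV2A tracer [18F]UCB-H) from regional
    time-activity curves and arterial blood data. Builds metabolite-corrected
    arterial plasma input functions from whole-blood, plasma and parent-fraction
    tables; fits one- and two-tissue compartment models by weighted nonlinear
    least squares, including a coupled fit that shares the K1/k2 ratio (V_ND)
    across regions; estimates the total distribution volume by Logan and MA1
    graphical analysis; computes test-retest reliability statistics (absolute
    test-retest variability and intra-class correlation); and analyses
    displacement studies (SUV normalisation, percent displacement, receptor
    occupancy arithmetic). A synthetic-study generator produces complete blood
    and time-activity data sets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
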