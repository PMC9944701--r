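Package: tetrodose
Title: Whole-Body PBPK Modelling and Paediatric Dosimetry for Tc99m-Tetrofosmin
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK) model of
    the myocardial perfusion agent Tc99m-tetrofosmin built from tissue
    time-activity data (percent of administered dose per organ), with
    maximum-likelihood estimation under per-tissue proportional error,
    mechanistic tissue-to-plasma partition-coefficient prediction by the
    Rodgers-Rowland method, allometric scaling of permeability and clearance
    parameters to paediatric physiologies (ages 1, 5, 10 and 15 years), and a
    MIRD dosimetry chain: radioactive decay, bladder and gastrointestinal
    emptying, residence times, S-value absorbed doses, ICRP-103 effective
    doses, and maximum administered activities for children. Includes a
    synthetic-data generator mirroring the imaging study design for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
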