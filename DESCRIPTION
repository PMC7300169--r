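Package: ossdosim
Title: Optimal Sampling Schedules for Radioligand Therapy Dosimetry by
    Simulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for designing measurement schedules in
    177Lu radioligand therapy dosimetry. Generates virtual patients with
    kidney and tumour-lesion time-activity curves, perturbs the true
    activities with a systematic plus stochastic multiplicative log-normal
    noise model for planar and SPECT/CT quantification, estimates
    time-integrated activity coefficients (TIACs) with a mono-exponential
    planar fit, a hybrid planar/SPECT rescaling and a single-time-point
    approximation, and ranks candidate sampling schedules by a joint
    kidney/tumour root-mean-squared error computed over Monte-Carlo
    replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
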