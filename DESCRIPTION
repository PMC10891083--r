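Package: micropam
Title: Reduced Human Cortical Microcircuit Simulation of GABAergic
    Modulation in Depression with EEG Biomarker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a reduced human layer 2/3 cortical microcircuit
    (adaptive leaky integrate-and-fire neurons; pyramidal cells with
    somatic-basal and apical compartments; SST, PV and VIP interneurons)
    with conductance-based synapses, outwardly rectifying tonic GABA-A
    inhibition and Ornstein-Uhlenbeck background drive.  Expresses
    depression (reduced SST-mediated inhibition) and positive allosteric
    modulator (PAM) interventions as multiplicative conductance
    transforms, fits tonic conductances to voltage-clamp current targets,
    and provides the downstream biomarker pipeline: sliding-window firing
    rate distributions with skew-normal fits and optimal-decision
    detection metrics, dipole-based EEG via a four-sphere volume
    conductor, Welch power spectra and band powers, aperiodic/periodic
    spectral parameterization, wavelet oscillation-event detection,
    effect sizes and dose-response fitting, and a condition-sweep
    experiment runner with synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
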