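Package: gbokit
Title: Gamma-Band Oscillation Analysis for Multielectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("MEA", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pharmacologically evoked gamma-band
    oscillations (GBOs) recorded on perforated multielectrode arrays in
    ex vivo hippocampal slices. Provides a synthetic recording generator
    with known ground truth, zero-phase Butterworth preprocessing to 1 kHz
    local field potentials, multitaper power spectra with Slepian tapers,
    Morlet wavelet spectrograms, band power and Q-factor estimation,
    sigmoidal onset kinetics (GBO90) and fall-time analysis, pairwise
    magnitude coherence within and between hippocampal subfields with
    thresholded coherence graphs, and linear mixed-effects models of
    coherence with nested slice/electrode random intercepts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    lme4,
    igraph,
    rhdf5,
    optparse,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
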