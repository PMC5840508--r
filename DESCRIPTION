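Package: WaveletInfo
Title: Wavelet-Information Decoding of Single-Trial Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts and quantifies class information from single-trial
    event-related potentials (EEG/LFP). Epoched multichannel trials are
    decomposed with a five-level orthonormal Haar multiresolution transform;
    wavelet coefficients are ranked by their mutual information with the class
    labels, estimated from bootstrap sub-ensemble averages; the most
    informative coefficients feed a uniform-prior naive Bayes decoder under
    leave-one-out cross-validation. Includes multichannel coefficient pooling,
    permutation significance testing, spatiotemporal selection-rate maps, a
    single-trial peak amplitude/latency baseline decoder, and a synthetic
    evoked-potential simulator with spectrally realistic background noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, jsonlite, data.table
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), e1071, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
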