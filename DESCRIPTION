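Package: cmrf
Title: Cardiac Magnetic Resonance Fingerprinting Simulation and
    Self-Supervised Deep-Image-Prior Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end cardiac magnetic resonance fingerprinting (MRF)
    toolbox: ECG-triggered FISP sequence scheduling, extended-phase-graph
    fingerprint simulation, dictionary and low-rank SVD subspace
    construction, a numerical cardiac phantom and coil-map generator,
    golden-angle spiral acquisition with an exact non-uniform DFT,
    GRAPPA-operator gridding (GROG) preprocessing, baseline
    reconstructions (per-TR gridding with dictionary matching, and a
    sparse plus locally-low-rank subspace reconstruction), a pretrained
    fingerprint-generator network, and a self-supervised deep-image-prior
    reconstruction (DIP-MRF) that trains an untrained convolutional
    image-reconstruction network and a voxel-wise parameter-estimation
    network against a single scan's undersampled k-space data to produce
    T1, T2 and complex M0 maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
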