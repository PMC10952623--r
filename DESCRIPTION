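Package: cardioqti
Title: Cardiac Q-Space Trajectory Imaging with Tensor-Valued Diffusion
    Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for q-space trajectory imaging (QTI) of the heart with
    tensor-valued diffusion encoding. Loads and characterizes
    diffusion-encoding gradient waveforms (b-tensors, motion-encoding
    moments, dephasing-vector power spectra, concomitant-field Maxwell
    index, extraction of linear-encoding waveforms from a planar one),
    builds multi-shell multi-shape acquisition protocols, fits the
    covariance-tensor signal representation and the powder-averaged
    kurtosis model, derives microstructure metrics (MD, FA, microscopic
    FA, isotropic/anisotropic/total mean kurtosis, orientation
    coherence), and simulates multi-Gaussian fiber phantoms with exact
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
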