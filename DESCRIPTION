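Package: mscomplexity
Title: Microstate and Complexity Analysis of Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Space-time complexity analysis of multichannel EEG built around
    microstate segmentation. Segments EEG into microstates (global field
    power peak extraction, polarity-invariant atomize-and-agglomerate
    hierarchical clustering, elbow-based template-count selection,
    back-fitting) and computes complexity measures both on the resulting
    symbolic microstate sequence (Lempel-Ziv complexity, mean information
    gain, fluctuation complexity, Shannon entropy, entropy rate, excess
    entropy) and on continuous channel or source-region signals (Lempel-Ziv
    complexity, sample entropy, permutation entropy, Higuchi fractal
    dimension, Wiener entropy / spectral flatness, and its windowed
    variance). Includes a synthetic-EEG generator with known ground truth
    (Markov microstate sequences, latent topographies, 1/f noise), a
    preprocessing chain (band-pass, decimation, average reference,
    pre-trigger epoching, sliding windows), and a statistics layer
    (assumption checks, one-way repeated-measures ANOVA,
    Benjamini-Hochberg FDR, Scheffe post hoc contrasts, Cohen's d,
    correlation banding, and noncentral-F sample-size computation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    nortest,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
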