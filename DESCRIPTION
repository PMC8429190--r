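Package: gbembed
Title: Model Embeddability for Symmetric Group-Based Substitution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for symmetric group-based phylogenetic substitution models
    on finite abelian groups: discrete Fourier transform (character table)
    machinery, G-compatible labeling functions and their exhaustive
    enumeration up to isomorphism, construction and spectral analysis of
    group-convolution rate and Markov matrices, a model-specific Markov
    embedding test deciding from the Fourier eigenvalues whether a transition
    matrix is the exponential of a rate matrix respecting the model symmetry,
    and exact (rational vertex-enumeration) and Monte Carlo volume
    computations quantifying how large the model-embeddable set is for the
    hachimoji (eight-state) and general Jukes-Cantor models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    withr
Config/testthat/edition: 3
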