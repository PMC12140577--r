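Package: lgec
Title: Latent-Manifold Effective Connectivity Modelling of Brain Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models parcellated BOLD dynamics on a low-dimensional latent
    manifold. A variational autoencoder embeds time-by-time spatial patterns
    into a few latent modes, each mode is modelled as a Stuart-Landau
    oscillator near a supercritical Hopf bifurcation, and the directed
    coupling between modes (latent generative effective connectivity, LGEC)
    is inferred by iteratively fitting zero-lag and forward-shifted
    functional connectivity. Includes noise-probe decoding of latent modes
    back to source-space patterns, association with reference resting-state
    networks, condition-level statistics, a Gaussian-kernel one-versus-one
    support vector machine for condition fingerprinting, and a synthetic-data
    generator with known ground-truth coupling for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
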