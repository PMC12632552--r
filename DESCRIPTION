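Package: slae
Title: Strictly Local All-Atom Environment Autoencoding for Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes each protein residue's strictly local all-atom
    environment into a compact rotation- and translation-invariant 128-d
    token with an SE(3)-equivariant edge-state graph network, and decodes
    token sets back to all-atom coordinates, sequence logits and pairwise
    interaction energies with a rotary-attention transformer. Provides the
    multi-task pretraining objective (smooth lDDT, frame-aligned point
    error, sequence cross-entropy, energy regression), a synthetic
    all-atom peptide generator for desk-scale experiments, a surrogate
    inter-residue energy labeler, and latent-space analysis tools
    (post-hoc kNN codebook quantization, linear latent interpolation,
    per-residue-type Frechet distance, native-decoy cosine margins).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
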