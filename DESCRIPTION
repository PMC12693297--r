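Package: mepsim
Title: Multimodal Siamese Similarity Learning from Molecular Electrostatic
    Potential and Reduced Density Gradient Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns a molecular similarity metric from two image-derived
    modalities: molecular electrostatic potential (MEP) surface renders,
    processed by a small convolutional network, and gray-level co-occurrence
    matrix (GLCM) texture features extracted from reduced density gradient
    (RDG) non-covalent-interaction diagrams, processed by a multilayer
    perceptron. Both branches are fused into a shared embedding trained with
    a triplet loss whose anchor/positive/negative triplets are mined from
    Tanimoto similarity of 2048-bit radius-2 Morgan fingerprints. Similarity
    between compounds is reported as inverse embedding distance 1/(1+d), and
    model decisions are inspected with Grad-CAM heatmaps over the image
    branch and gradient saliency over the texture branch. A synthetic
    fixture generator produces MEP-like and RDG-like image families with
    matched SMILES pools so the whole pipeline is testable without
    quantum-chemistry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
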