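Package: cfnet
Title: Protein Interaction and Complex Inference from Co-Fractionation
    Mass Spectrometry and Sequence Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers protein-protein interactions and protein complexes from
    co-fractionation mass spectrometry (CF-MS) elution profiles combined with
    chaos-game (FCGR) encodings of protein sequences and trainable protein
    embeddings. Provides elution-matrix preprocessing and padding, reference
    complex handling and positive/negative/experimental pair labeling, a
    convolutional pair classifier with residual input reinjection and a
    pair-difference head, Markov clustering and topological-overlap based
    complex detection with adaptive dendrogram cutting, gradient saliency
    attribution, and cluster evaluation by composite, GO semantic similarity
    (GOGO) and colocalization scores, plus a seeded synthetic-data generator
    for offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
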