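Package: dtigat
Title: Drug-Target Interaction Prediction with Masked Graph Attention over
    Similarity Neighborhoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-target interactions from language-model (or mock)
    encodings of protein and drug sequences. Per-modality masked multi-head
    graph attention networks operate over similarity-derived neighborhood
    graphs (Pearson correlation of encodings, Tanimoto similarity of circular
    fingerprints, or pairwise alignment identity), fuse attention embeddings
    with the raw encodings through weighted residual connections, and classify
    pairs with a multilayer perceptron trained under binary cross-entropy.
    Includes the cold-start evaluation protocol (warm, cold-drug and
    cold-protein splits with balanced or 1:10 negative sampling, leakage
    experiments), encoder-quality diagnostics (mean pairwise similarity,
    top-N neighbor-support statistics, zero-shot neighborhood prediction),
    and a block-structured synthetic data generator for end-to-end testing
    without external datasets or pretrained models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    Biostrings,
    ChemmineOB
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
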