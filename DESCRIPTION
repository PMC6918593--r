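Package: protlm
Title: Bidirectional Language Models and Transfer Learning for Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats each protein as a sentence of amino-acid words and learns an
    ELMo-style bidirectional language model (character-convolution word encoder,
    two recurrent layers per direction, sampled-softmax training) whose layer
    activations provide contextual per-residue embeddings. Embeddings are pooled
    to per-protein vectors and fed, alongside classical encodings (one-hot,
    BLOSUM65, evolutionary profiles, k-mer skip-gram), into small multi-task
    networks predicting secondary structure and intrinsic disorder per residue,
    and subcellular localization and membrane status per protein. Includes a
    synthetic-protein generator with a hidden-state grammar for end-to-end
    testing, and an evaluation suite (Q3, Q8, Q2, Q10, Matthews correlation,
    the Gorodkin multiclass correlation, bootstrap standard errors).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
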