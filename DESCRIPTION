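Package: ldra
Title: Predicting lncRNA-Drug Resistance Associations with Graph Convolution and Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Link prediction on sparse binary lncRNA-drug resistance association
    networks. Node similarities are derived from Gaussian interaction-profile
    (GIP) kernels on association profiles; a two-layer graph convolutional
    encoder followed by multi-head graph-attention layers learns lncRNA and
    drug embeddings, and a sigmoid inner-product decoder scores candidate
    associations. Includes balanced and unbalanced 10-fold cross-validation
    with AUC, AUPR, F1 and MCC metrics, a planted-block synthetic data
    generator for offline benchmarking, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
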