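Package: dtiscreen
Title: Drug-Target Co-Embedding, Virtual-Screening Metrics and Top-k Retrieval
Version: 0.1.0
Authors@R: person("dtiscreen", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Learns a shared co-embedding space for drugs (Morgan fingerprint
    bit vectors) and protein targets (attention-pooled per-residue
    embeddings) in which a scaled-cosine sigmoid predicts interaction and a
    dot product predicts binding affinity (pK). Includes negative-sampling
    dataset assembly, random/unseen-entity/homology-aware splits with
    brute-force audits, virtual-screening metrics (AUROC, AUPR, BEDROC,
    enrichment factors), an exact and approximate top-k co-embedding index
    for library-by-proteome screening, residue-level attention
    interpretation against bound structures, and a synthetic-data generator
    with planted latent interaction structure and planted binding-site
    motifs so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
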