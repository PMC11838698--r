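# dtiscreen

Drug-target interaction (DTI) prediction by co-embedding, for
cheminformatics and virtual-screening work at desk scale.

Structure-based virtual screening (docking) is far too slow to scan whole
chemical libraries against whole proteomes. `dtiscreen` implements the
vector-based alternative: drugs and protein targets are projected into one
shared embedding space in which geometry encodes interaction, so screening a
library against a target collapses to a top-k nearest-neighbour query.

## The model

Let `f(D)` be a frozen drug featurization (Morgan fingerprint, 2048 bits,
radius 2) and `g(T)` a frozen per-residue protein featurization (an `L x E`
matrix from a pluggable encoder; a deterministic toy encoder ships with the
package, real protein-language-model adapters plug in through
`register_provider()`). A multi-head attention-pooling layer with learned
per-head queries aggregates `g(T)` into one vector, and two MLPs project
both modalities into the co-embedding space:

    Zd = Cd(f(D)),   Zt = Ct(pool(g(T)))

Two scoring heads share this architecture:

    P(Y = 1 | Zd, Zt) = sigmoid(alpha * cos(Zd, Zt)),  alpha = 5   (classification)
    pK_hat            = Zd . Zt                                    (affinity, pK = -log10 Kd)

Training minimizes binary cross-entropy (classification) or mean squared
error (affinity) with Adam, checkpointing the best validation epoch. The
attention weights are retained per head and per residue, enabling
binding-site-level interpretation of predictions.

Around the core model the package provides:

* dataset assembly: Kd thresholding (`Kd < 30` = interacting), uniform
  negative sampling at configurable ratios, train/val/test splitting
  (random, unseen-drug, unseen-target, homology-aware with audited 90% /
  70% identity bounds);
* virtual-screening metrics: AUROC, AUPR, BEDROC (default alpha 85),
  enrichment factors at 0.5/1/5%, all oracle-tested;
* an exact top-k co-embedding index (plus a reference LSH approximate
  backend) and batch library x proteome screening;
* attention interpretation against bound structures: binding residues by a
  4.5 A heavy-atom contact rule, binding vs non-binding attention
  enrichment, and PDB export with attention in the B-factor column;
* a synthetic-data generator with planted latent interaction structure and
  planted sequence motifs, so everything above is testable end-to-end with
  no downloads.

## Worked example

```r
library(dtiscreen)
# a small synthetic world: 120 drugs, 60 targets, 3000 labelled pairs
spec <- synthetic_spec(n_drugs = 120, n_targets = 60, n_pairs = 3000, seed = 42)
ds <- generate_synthetic(spec)
rec <- dataset_records(ds)
feats <- assemble_features(rec$drugs, rec$targets)
splits <- make_splits(ds$interactions, split_spec("random", seed = 42))

model <- init_model(model_config(n_heads = 4, d = 32, dk = 16, dv = 16, seed = 1),
                    n_bits = feats$n_bits, embed_dim = feats$embed_dim)
res <- fit(model, feats, ds$interactions[splits$train, ],
           ds$interactions[splits$val, ], task = "classify",
           config = fit_config(lr = 2e-3, batch_size = Inf, epochs = 250,
                               patience = 50, seed = 1))
test <- ds$interactions[splits$test, ]
scores <- predict_pairs(res$model, feats, test)
str(evaluate_screen(scores, test$label), digits.d = 3)
```

prints (about a minute on one CPU):

```
List of 9
 $ n           : int 600
 $ n_actives   : int 302
 $ auroc       : num 0.844
 $ aupr        : num 0.851
 $ bedroc      : num 1
 $ bedroc_alpha: num 85
 $ ef_0.5      : num 1.99
 $ ef_1        : num 1.99
 $ ef_5        : num 1.99
```

AUROC/AUPR ~0.85 on held-out pairs shows the model recovered the planted
latent structure from fingerprints and sequences alone. This little world is
half actives, so the maximum possible enrichment factor is N/n = 1.99 and
BEDROC saturates - EF and BEDROC are informative on realistic, scarce-active
screens, not on a 50% prevalence toy (see the methods vignette).

Retrieval is the same ranking as the probability head (the sigmoid is
monotone in the cosine):

```r
emb <- embed_entities(res$model, feats)
idx <- build_index(emb$Zd, model_fingerprint = emb$fingerprint)
query_topk(idx, emb$Zt["T0001", ], k = 5)
#>   rank    id     score
#> 1    1 D0081 0.6359571
#> 2    2 D0079 0.5859697
#> 3    3 D0096 0.5707148
#> 4    4 D0059 0.5499413
#> 5    5 D0008 0.5468145
```

The same pipeline is scriptable: `simulate`, `featurize`, `train`, `score`,
`evaluate`, `index build|query`, `screen`, `attention` via `dti_cli()` (or
the `inst/cli/dtiscreen` launcher); every run writes a `*.manifest.json`
with the resolved configuration, input digests and seeds.

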