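# dtigat

Drug–target interaction (DTI) prediction from sequence-derived encodings,
with masked multi-head graph attention over similarity neighborhoods.

## What problem this solves, and for whom

Sequence-based DTI models must generalize to *cold-start* entities — drugs
or proteins with no known interactions. `dtigat` is for computational
chemists and bioinformaticians who have fixed-length encodings of proteins
and drugs (typically exported from pretrained protein/chemical language
models, e.g. 1280-d protein and 768-d drug vectors) and want to (a) train a
neighborhood-aware interaction classifier, (b) evaluate it under the
warm/cold-start repeated-split protocol, and (c) diagnose *whether their
encoder's similarity structure is informative at all* before training
anything.

## The model

Each protein has an encoding $x_i \in \mathbb{R}^p$, each drug
$y_j \in \mathbb{R}^q$. Similarity matrices (Pearson correlation of
encodings by default) are thresholded into adjacencies $S_x, S_y$ that mask
a per-modality multi-head graph attention network:

$$c_{ij} = \mathrm{LeakyReLU}\!\left(a\,[W x_i \,\|\, W x_j]\right),\qquad
\alpha_{ij} = \frac{\exp c_{ij}}{\sum_{r \in N_i} \exp c_{ir}},\qquad
x_i' = \sigma\!\Big(\sum_{j\in N_i} \alpha_{ij} W x_j\Big),$$

with $h$ heads concatenated per layer and head widths tied so $kh = p$
(and $lh = q$ for drugs). Pairs are classified by an MLP on residual-fused
representations,

$$\tilde I_{ij} = \mathrm{MLP}\big([Z_{x,i} + \beta x_i] \,\|\,
[Z_{y,j} + \gamma y_j]\big),$$

trained with binary cross-entropy. Setting $Z \equiv 0,\ \beta=\gamma=1$
(`use_gat = FALSE`) recovers the encoder-only MLP baseline — the ablation
the package's experiments compare against. The attention forward pass,
analytic backpropagation and Adam are implemented in base R and are
verified against loop references and finite differences in the test suite.

The package also implements the evaluation protocol (warm / cold-drug /
cold-protein splits at 0.79/0.01/0.20, balanced 1:1 or unbalanced 1:10
negative sampling, affinity binarization, leakage experiments, 10-repeat
AUROC/AUPRC aggregation), encoder diagnostics (mean similarity tables,
top-N neighbor support, zero-shot neighborhood-only prediction) and a
block-structured synthetic generator so everything runs with no downloads.

## Worked example

```r
library(dtigat)

# A block-structured synthetic dataset: 80 proteins x 80 drugs in 4 latent
# clusters; similar entities share interaction partners.
cfg <- synthetic_config(n_proteins = 80, n_drugs = 80, n_blocks = 4,
                        p_dim = 16, q_dim = 16, interaction_density = 0.08,
                        seed = 42)
ds <- generate_synthetic_dataset(cfg)
ds$interactions
#> <interaction_set> 80 drugs x 80 proteins; 512 positives, 0 negatives

# Cold-protein split: test proteins never occur in training.
sp <- make_split(ds$interactions, "cold_protein", seed = 0)
sp
#> <data_split> mode cold_protein, balance balanced_1_1, seed 0
#>   train   798 pairs (399 positive, 399 negative)
#>   val      14 pairs (7 positive, 7 negative)
#>   test    212 pairs (106 positive, 106 negative)

gx <- neighborhood_graph(pearson_similarity(ds$proteins), quantile = 0.95,
                         basis = "pearson_encoding")
gy <- neighborhood_graph(pearson_similarity(ds$drugs), quantile = 0.95,
                         basis = "pearson_encoding")
gx
#> <neighborhood_graph> 80 nodes, 158 undirected edges (basis pearson_encoding,
#>   threshold 0.9508, self-connections TRUE)

fit <- dtigat(ds$proteins, ds$drugs, sp$train, gx, gy,
              config = gat_config(h_protein = 4, h_drug = 4,
                                  mlp_hidden = 32L, max_epochs = 150),
              val_pairs = sp$val)
fit
#> Masked graph-attention DTI model
#>   80 proteins (p = 16), 80 drugs (q = 16)
#>   GAT: 1 x 4 heads (protein), 1 x 4 heads (drug); beta = 1, gamma = 1
#>   MLP hidden: 32; trained 70 epochs (best at 50, monitored val_auprc)
#>   final training loss 0.4248

scores <- predict(fit, sp$test, type = "response")
auroc(scores, sp$test$label)   # 0.830
auprc(scores, sp$test$label)   # 0.788
```

A test AUROC of 0.83 on proteins the model never saw interact means the
attention over encoding-similar neighbors, plus the encodings themselves,
carries most of the block structure. The encoder diagnostic quantifies that
premise directly — the fraction of each protein's interactions shared by at
least 3 of its 5 nearest encoding-space neighbors:

```r
neighbor_support(ds$interactions, pearson_similarity(ds$proteins),
                 side = "protein")
#> <neighbor_support> side protein, N = 5, min_support = 3: mean 14.8% of
#>   interactions supported (80 entities with interactions)
```

The usual S3 verbs work on the fit: `summary()`, `coef()`, `plot()` (loss
curve), `residuals()`, `simulate()`, and `save_checkpoint()` /
`load_checkpoint()` for bitwise-reproducible persistence. `run_experiment()`
wraps the whole repeated-split protocol, and `zero_shot_predict()` scores
pairs from neighborhood structure alone with no trained model. A
command-line front end covering the same pipeline
(`simulate`, `encode`, `build-graph`, `split`, `train`, `predict`,
`evaluate`, `diagnose`) ships in `inst/exec/dtigat.R`.

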