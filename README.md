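# gvtr

Graph-convolutional vision transformers for training image classifiers **from
scratch on small datasets**, with a secondary semi-supervised
node-classification mode for citation-style graphs.

Plain vision transformers need large-scale pre-training because dot-product
attention has no built-in preference for local structure. `gvtr` implements a
transformer block in which that bias is supplied by graph convolution *inside*
the attention mechanism:

* Image patches are graph nodes. Their adjacency combines a fixed 8-neighbor
  spatial prior `A_I` with learned semantic weights `E` (a softmax over
  pairwise cosine distances): `A = (A_I + I) ⊙ E`.
* Queries and keys are graph-convolutional projections
  `x^{q/k} = (D_A^{-1/2} A D_A^{-1/2}) x W_{q/k}`, giving scaled dot-product
  scores `S_i = softmax(q_i k_iᵀ / sqrt(d/h))` per head.
* When heads are narrow (`d/h < n`) the score logits are rank-deficient (the
  *low-rank bottleneck*). A talking-heads stage mitigates it: per-head
  scalar features `F = h × n` from concatenated queries/keys, bilinear pool
  `C = FFᵀ`, sigmoid shrinkage gates `Z = σ((C W_c) ⊙ u⁻¹)`, sparse
  selection `Ŝ_i = M_i S_i M_i` with `M_i = diag(Z[i,])`, and learned
  cross-head mixing `R_i = Σ_j Φ_ij Ŝ_j`.
* Values are aggregated by a second graph convolution over the symmetrized
  relation matrix, `x_i^v = (D^{-1/2} R̃_i D^{-1/2}) x_i W_{vi} + x_i`.
* Between two intermediate blocks, second-order graph pooling
  `X' = (U Xᵀ) X`, `A' = C A Cᵀ` (`C = U Xᵀ`) reduces the token count
  (64 → 16 in the default 7-block model, before block 5).

The package also ships the architecture's analytical apparatus — the
per-block operation-count model (`flop_count()`, coefficients `12u³` vs
`9u³` at `n = d`), the spectral low-pass characterization
`p(λ) = (1 − λ)^α` of stacked graph convolutions (`spectral_response()`),
and the low-rank diagnostic (`attention_logit_rank()`) — plus synthetic
image/graph generators, a seeded AdamW + cosine-decay training loop built on
a minimal reverse-mode autodiff engine, and a thin CLI (`inst/cli/gvt`).

## Worked example

Train a tiny model from scratch on the built-in synthetic motif dataset
(4 classes × 50 images, 32 px, one textured motif per class at a
class-specific location):

```r
library(gvtr)

ds  <- make_image_dataset()                      # 160 train / 40 test
cfg <- gvt_config(blocks = 2, hidden = 16, heads = 2, tokens = 16,
                  pool_to = 0, classes = 4, image_size = 32, seed = 1)
out <- gvt_train(cfg, train_config(batch_size = 16, epochs = 20, seed = 1), ds)
tail(out$history, 3)
#>  epoch           lr train_loss eval_accuracy
#>     18 1.354569e-05   1.065083         0.975
#>     19 3.409674e-06   1.064015         0.975
#>     20 0.000000e+00   1.063790         0.975

ev <- gvt_evaluate(out$model, ds)
ev$accuracy       # 0.975
ev$per_class      #   1   2   3   4
                  # 0.9 1.0 1.0 1.0
```

The model learns the class-defining local motifs from 160 images with no
pre-training: 97.5% test accuracy, with the per-class breakdown showing the
single residual confusion. The run is exactly repeatable for a fixed seed.

The default full-size configuration mirrors the published `(blocks, hidden,
heads, tokens)` tuple `(7, 64, 8, 64)` with pooling to 16 tokens:

```r
m <- build_model(gvt_config(seed = 1))
m
#> Graph-attention transformer (image mode): 7 blocks, d=64, h=8, n=64, pooled to 16 after block 4
#> classes: 10  ablation: full  parameters: 35258

flop_count(64, 64)[c("vit_flops", "gvt_flops", "vit_coeff", "gvt_coeff")]
#> $vit_flops 3145728   $gvt_flops 2359296   $vit_coeff 12   $gvt_coeff 9
```

(Parameter counts are smaller than the published budgets for the same tuples;
see the methods vignette for why the grouped stem and mean-pool head land
lighter.)

Node classification on a planted-partition citation-style graph:

```r
g   <- make_citation_dataset(nodes = 200, classes = 4, feature_dim = 16,
                             homophily = 0.9, label_rate = 0.1, seed = 1)
cfg <- gvt_config(blocks = 2, hidden = 16, heads = 2, tokens = 200,
                  pool_to = 0, classes = 4, mode = "graph",
                  feature_dim = 16, seed = 1)
out <- gvt_train(cfg, train_config(epochs = 100, schedule = "constant"), g)
```

## Command line

```sh
Rscript inst/cli/gvt synth    --kind image --out toyset --seed 1
Rscript inst/cli/gvt train    --data toyset --checkpoint run.rds --epochs 20 --batch-size 16
Rscript inst/cli/gvt evaluate --data toyset --checkpoint run.rds
Rscript inst/cli/gvt analyze  --n 64 --d 64 --alpha 3
```

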