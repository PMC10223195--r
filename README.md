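# octafuse

Vessel segmentation for en-face OCTA angiograms with a U-shaped
convolutional network whose skip connections are replaced by an **efficient
cross-fusion transformer** (ECT) and whose decoder fusion is gated by
**efficient channel cross-attention** (ECCA). The package is aimed at
researchers in retinal image analysis who want a fully inspectable,
desk-scale implementation of this architecture family: every forward and
backward pass is written in R on top of BLAS matrix operations, so there is
no framework boundary between the model description and what actually runs.

## The model

The backbone is a four-level U-Net: each level applies two 3×3
convolutions with batch normalization and ReLU; 2×2 max-pooling halves the
resolution between levels, and the decoder mirrors this with bilinear
upsampling followed by convolution. The deepest encoder output starts the
decoding path, so all four scales X₁..X₄ provide skip connections.

Instead of copying X_i to the decoder, the ECT fuses all four scales at
once. Each scale is layer-normalized, projected to queries, keys and values
by 1×1 convolutions, and shrunk to a shared token grid of k = (H/r)(W/r)
positions (r = 16 by default, so k = 19·19 = 361 on a 304×304 angiogram).
Keys and values are concatenated across scales along the embedding axis and
attention is computed per head on the channel axes,

    ECA_i = softmax( Q'ᵢᵀ K' / √d_Σ ) V'ᵀ ,

a d_i × d_Σ score matrix whose size — and therefore whose cost — is
independent of the image resolution once k is fixed. The attended tokens are
merged across heads, restored to the scale's resolution (bilinear upsample +
1×1 convolution, giving Â_i), and refined with a residual convolution
block:

    E_i = X_i + Â_i + Conv(ReLU(BN(X_i + Â_i))) .

At each decoder stage the ECCA module gates the fused skip E_i against the
decoder feature D_i through pooled channel descriptors,

    N_i = L1·σ(AvgPool(E_i)) + L2·σ(AvgPool(D_i)) ,   E'_i = σ(N_i) ⊙ E_i ,

and the gated skip is concatenated with D_i. Four ablation variants are
built from the same configuration surface: `base` (plain U-Net wiring),
`ect`, `ecca`, and `full`.

The package also ships the complete pixel-classification metric suite (AUC,
sensitivity, specificity, accuracy, Cohen's kappa via the marginal
expansion, G-mean, Dice, FDR), the training recipe (Adam, lr 6e-4, batch
size 2, weight decay 1e-4, per-iteration poly schedule with power 0.9,
±10° rotation augmentation, binary cross-entropy on logits), and a
deterministic synthetic angiogram generator producing branching vessel
trees with pixel-level and centerline-level ground truth, so the entire
pipeline is exercisable without any external dataset.

## Worked example

Train the tiny full variant on eight synthetic 64×64 angiograms and
evaluate on two held-out ones:

```r
library(octafuse)
params    <- vessel_tree_params()
train_set <- lapply(1:8, function(i) synthetic_sample(params, 100 + i))
test_set  <- lapply(1:2, function(i) synthetic_sample(params, 900 + i))

cfg   <- model_config(variant = "full", base_width = 8L,
                      channel_widths = c(8L, 16L, 32L, 64L))
model <- build_model(cfg, seed = 1L)
count_parameters(model)
#> [1] 333617

fit <- train_model(model, train_set, train_config(epochs = 60L, seed = 1L))
tail(fit$history$loss, 1)
#> [1] 0.4148

preds  <- lapply(test_set, function(s) predict_vessels(fit$model, s$image))
report <- evaluate_dataset(preds, lapply(test_set, `[[`, "pixel_mask"))
print(report[nrow(report), ], digits = 3)
#>       image   auc   acc g_mean kappa  dice   fdr   sen   spe
#> 3 aggregate 0.989 0.964  0.964 0.871 0.892 0.167 0.962 0.965
```

The aggregate row is the per-image mean: the small model separates vessel
from background almost perfectly by rank (AUC 0.99) and reaches Dice 0.89
on unseen draws from the same generator. `evaluate_dataset(...,
aggregation = "pooled")` pools all pixels into one confusion matrix
instead.

The same pipeline is available from a shell via the installed `exec/octafuse`
script (subcommands `generate`, `train`, `eval`, `predict`, `ablate`,
`count-params`); every run writes its resolved configuration and seed next
to its outputs.

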