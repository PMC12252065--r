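# harspectrum

Label-efficient representation learning for human activity recognition
(HAR) from multichannel wearable-sensor streams, implemented as six
paradigms spanning the supervision spectrum:

1. **Supervised** — residual temporal convolutional network (TCN) with
   dilated causal convolutions, trained with cross-entropy on raw
   windows.
2. **Unsupervised** — residual autoencoder on handcrafted window
   statistics, trained with the reconstruction loss
   `Φae = (1/N) Σ ||x − g(f(x))||²`.
3. **Weakly supervised (single-task)** — Siamese weight-shared TCN
   trained with the margin contrastive loss on pairwise
   same/different-activity constraints:
   `y·D²/2 + (1−y)·max(0, δ−D)²/2`, `D = ||f(xa) − f(xb)||`.
4. **Weakly supervised (multi-task)** — a second person-identification
   head on the shared trunk, `α·Φact + β·Φpers`.
5. **Self-supervised** — the autoencoder plus temporal-consistency
   (`Φtc`, neighbors `{t−2..t+2}` within a person's stream) and
   feature-consistency (`Φfc`, k = 5 nearest neighbors in feature
   space) objectives: `(1−α−β)·Φae + α·Φtc + β·Φfc`.
6. **Weakly self-supervised** — two stages: self-supervised
   pre-training on all data, then fine-tuning with
   `(1−α−β−γ)(Φae^a+Φae^b) + α(Φtc^a+Φtc^b) + β(Φfc^a+Φfc^b) + γ·Φsimi`
   using pairwise constraints drawn from a small stratified label
   budget (1–10 %).

Label-free paradigms are evaluated by k-means on the learned
embeddings with the optimal (Hungarian) cluster-to-class mapping,
reporting accuracy and macro-F1.

The package is self-contained: it includes a synthetic stream
generator with per-activity stationary signatures and per-person
nuisance variation, sliding-window segmentation, the seven-statistic
feature extractor, and a small reverse-mode gradient engine (dense /
dilated causal conv / batch norm / pooling / residual blocks, Adam),
all in base R. It targets method study at desk scale, not large-scale
training.

## Worked example

```r
library(harspectrum)

cfg     <- synth_config(seed = 1)          # 4 persons, 3 activities, 3 channels
streams <- generate_streams(cfg)
windows <- bind_windows(lapply(streams, segment_windows,
                               window_seconds = 2, step_seconds = 1))
windows
#> sensor_windows: 704 windows of 50 samples x 3 channels @ 25 Hz

feats <- extract_features(windows)
nbrs  <- build_neighborhoods(feats)        # P (radius 2) and Q (k = 5)

tc <- training_config(paradigm = "selfsup", epochs_stage1 = 300,
                      learning_rate = 3e-3, seed = 1)
model <- train_selfsup(feats, nbrs, tc,
                       encoder_spec(ncol(feats$X), embedding_dim = 8,
                                    hidden_dims = c(32, 16)))
reps <- embed_dataset(model, feats)
cl   <- kmeans_cluster(reps, k = 3, seed = 1)
cluster_accuracy(cl$assignments, reps$activity)
#> clustering_result: k = 3, accuracy 0.6065, macro-F1 0.6153
```

The accuracy is the fraction of windows whose k-means cluster maps to
their true activity under the best one-to-one cluster-to-class
assignment; on this synthetic replicate the plain autoencoder reaches
0.572 and the consistency-trained model 0.607 (seed-1 replicate; means
over replicates are what the experiment harness reports). A Siamese
TCN trained on pairwise constraints (`train_weak_single`) reaches
≈ 0.98 on the same data.

`run_experiment()` and `run_ablation()` automate the paradigm grid,
label-fraction sweep and loss-component ablation; a thin CLI
(`inst/cli/harspectrum`) exposes `synth`, `window`, `features`,
`train`, `evaluate` and `ablate` subcommands.

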