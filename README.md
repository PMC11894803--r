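# phenobridge

Phenotype-conditioned diffusion modelling and state bridging for gene
expression matrices (GEMs).

`phenobridge` is for computational biologists who want to ask, of a bulk
RNA-seq cohort with two phenotype states (say *tumor* and *normal*): which
genes move, and how far, when a sample is transported from one state to the
other? It answers this with a denoising diffusion probabilistic model
(DDPM) trained on both states at once, conditioned on the phenotype label,
and used in two modes:

- **Augmentation** — draw new synthetic expression profiles for either
  phenotype by running the stochastic reverse chain from Gaussian noise.
- **Perturbation (state bridging)** — encode real tumor samples to the
  step-T latent along the deterministic (σ = 0) implicit-diffusion ODE
  under the *tumor* condition, then decode the same latents under the
  *normal* condition. Rows stay paired, so each gene gets a signed
  per-sample perturbation; genes whose pooled score lies beyond ±2 SD of
  the score distribution are called **core genes**.

## The model

Forward diffusion corrupts a normalized expression row x₀ ∈ [−1, 1]ᴳ with
the closed-form marginal

    x_t = √(ᾱ_t) · x₀ + √(1 − ᾱ_t) · ε,   ε ~ N(0, I),

where ᾱ₁ > … > ᾱ_T is the cumulative signal-retention schedule (linear-β
by default, T = 1000, β ∈ [1e−4, 0.02]). A conditional transformer
ε_θ(x_t, t, c) — one token per gene, learned position + sinusoidal timestep
+ learned condition embeddings, pre-norm encoder blocks — is trained to
predict ε by minimizing E‖ε − ε_θ‖². Sampling uses either the stochastic
ancestral update (augmentation) or the deterministic implicit (DDIM) update

    x_{t−1} = √(ᾱ_{t−1}) · x̂₀ + √(1 − ᾱ_{t−1}) · ε_θ,
    x̂₀ = (x_t − √(1 − ᾱ_t) · ε_θ) / √(ᾱ_t),

whose iteration defines the invertible ODE used for bridging. A single
model serves both directions; only the condition embedding changes.

Around the model sits the screening pipeline: log2(n+1) transform,
per-gene min-max scaling to (−1, 1) fitted on a stratified 67/33 train
split, partitioning of gene sets into disjoint 16-gene subsets, 2-D UMAP
embedding (n_neighbors = 90, min_dist = 0.3) scored by the phenotype-label
silhouette, selection of subsets beyond ±1 SD of the silhouette mean, and
MMD + RBF-SVM evaluation of synthetic data. A hypergeometric
over-representation test with Benjamini–Yekutieli correction annotates the
resulting core-gene lists against GMT collections.

## Worked example

Everything below runs on synthetic data with known ground truth: 16 genes
of which 4 (`sig_1..sig_4`) are shifted by 3 log2 units in the tumor
class.

```r
library(phenobridge)

sim <- generate_two_state_gem(synthetic_spec(
  n_per_class = 200, n_genes = 16, n_signal = 4, effect_size = 3, seed = 11))
pp <- preprocess_gem(sim$gem, train_fraction = 0.67, seed = 11)

schedule <- make_schedule(100L)
model <- init_denoiser(
  denoiser_config(embed_dim = 64, n_blocks = 2, n_heads = 4,
                  feedforward_dim = 128), n_genes = 16, seed = 11)
model <- train_denoiser(model, pp$train, schedule,
  train_options(batch_size = 32, learning_rate = 1e-3,
                n_iterations = 2000, ema_decay = 0.995, seed = 11))

ck <- list(model = model, schedule = schedule, scaler = pp$scaler,
           gene_ids = colnames(pp$train$values),
           label_levels = model$label_levels)
res <- perturb(ck, sim$gem, "tumor", "normal", n_ode_steps = 100)
head(pool_scores(list(res), k_sd = 1), 5)
```

```
    gene subset       score direction          z  core
1  sig_1  genes -0.64040246        -1 -1.8455077  TRUE
2  sig_4  genes -0.63865090        -1 -1.8388675  TRUE
3  sig_2  genes -0.58143410        -1 -1.6219569  TRUE
4  sig_3  genes -0.56777408        -1 -1.5701714  TRUE
5 null_7  genes  0.05350228         1  0.7851058 FALSE
```

The four planted genes carry the largest perturbation magnitudes — all
negative, i.e. expression is pulled *down* toward the normal-state mean —
and are the only genes beyond one standard deviation of the pooled score
distribution (`core`). Null genes sit near zero. In the same session, a
radial-kernel SVM fitted on the real training samples classified 95% of
the bridged tumor rows as *normal*, the operational meaning of a
successful state transfer.

The same workflow is scriptable end to end (`simulate`, `screen`,
`train`, `augment`, `perturb`, `core-genes`, `evaluate`) through
`run_stage()` with a YAML config, or from a shell via the thin wrapper in
`inst/exec/phenobridge`.

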