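---
title: "Diffusion-based state bridging for gene expression: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-based state bridging for gene expression: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model and its assumptions, the preprocessing contract, the screening
statistic, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data validation does
and does not establish.

## The problem

Bulk RNA-seq cohorts often carry two phenotype states — tumor and normal
tissue being the canonical pair. Differential-expression tests rank genes
marginally; `phenobridge` instead asks a counterfactual question: *if this
tumor sample were transported to the normal expression state, which genes
would have to move, and how far?* The transport is performed by a
diffusion model conditioned on phenotype, and the per-gene displacement is
the effect readout.

## Generative model

### Forward process and training objective

Each preprocessed sample row $x_0 \in [-1,1]^G$ is corrupted by the
standard diffusion marginal

$$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon,
\qquad \epsilon \sim \mathcal N(0, I),$$

with $\bar\alpha_t$ strictly decreasing from near 1 to near 0 over $T$
steps. The network $\epsilon_\theta(x_t, t, c)$ — $c$ the phenotype index
— is trained on the simple noise-prediction objective
$\mathbb E\,\lVert\epsilon - \epsilon_\theta\rVert^2$ with $t$ uniform and
the condition taken from each sample's label. One model serves both
phenotypes; the label enters only through a learned embedding added to
every token, which is the minimal mechanism consistent with using a single
network for both transport directions.

The schedule family is configuration, not a claim: linear-$\beta$
($T=1000$, $\beta \in [10^{-4}, 0.02]$, the standard DDPM default) with a
squared-cosine alternative. The toy problems in the tests use $T = 100$:
with 16 features there is no benefit to a thousand noise levels, and the
shorter chain keeps CPU training within minutes.

### Denoiser architecture

The noise predictor is a transformer encoder over *gene tokens*: the
scalar expression of each gene is projected to an `embed_dim`-vector (one
token per gene), a learned per-gene position embedding identifies the
gene, and sinusoidal-then-projected timestep plus learned condition
embeddings are added before `n_blocks` pre-norm blocks (multi-head
self-attention, GELU feed-forward, residuals). A final linear head returns
one value per gene, so output shape always equals input shape for any gene
count. Per-gene tokens let attention model gene–gene dependence directly,
which is the point of using a transformer rather than an MLP on the
concatenated row.

Implementation note: the forward *and backward* passes are written in R
against BLAS, with the batched per-sample attention products in
RcppArmadillo. Optimization is Adam with an exponential moving average
(EMA) of the weights used for all sampling. The GELU is the sigmoid
approximation $x\,\sigma(1.702x)$; its error ($<10^{-2}$) is far below
the noise scale of the objective.

Two training-related parameters deserve care:

- **`ema_decay`** must be matched to the iteration budget. The EMA starts
  at the random initialization, whose residual weight after $n$ updates is
  $d^{\,n}$. With the DDPM-conventional $d = 0.999$ and only 2000
  iterations, 13% of the sampling weights would still be noise; the toy
  configurations therefore use $d = 0.995$ ($0.995^{2000} \approx
  4\times10^{-5}$). The package default remains 0.999, appropriate for
  long runs.
- **`learning_rate`** defaults to $10^{-4}$; the small toy models train
  with $10^{-3}$, which is stable at that scale and converges in the
  2000-iteration budget.

### Sampling modes

*Augmentation* runs the stochastic ancestral reverse chain from
$x_T \sim \mathcal N(0, I)$ using the forward-posterior variance at each
step, conditioned on the requested phenotype, and clips the final samples
to $[-1,1]$ (the normalized data domain; clipping is a no-op for a
well-trained model).

*Perturbation* iterates the $\sigma = 0$ implicit (DDIM) update, which is
deterministic and invertible: encoding integrates $t: 0 \to T$ under the
source condition, decoding integrates $T \to 0$ under the target
condition. Both use an evenly spaced ladder of `n_ode_steps`
(default 100) timesteps; the model is always evaluated at the lower end
of each sub-interval on the way up and the upper end on the way down,
making decode the exact reverse traversal of encode. Row pairing is
preserved by construction, so `perturbed - original` is meaningful per
sample and per gene.

The per-gene **perturbation score** is the mean signed difference in
normalized space, and its sign is the direction. This is the minimal
consistent definition given that scores and directions are reported
separately; magnitudes drive all rankings, and outputs are also provided
on the original FPKM-like scale via the stored scaler.

## Preprocessing contract

The chain is $\log_2(n+1)$, then per-gene min–max scaling to $(-1, 1)$.
The $+1$ pins unexpressed genes at exactly zero. Choices made where the
convention was open:

- The scaler is fitted on the **training split only** and applied with
  clipping to held-out or inference data — fitting on everything would
  leak test information into the model's input representation.
- Constant genes map to 0, the interval midpoint, keeping them inert.
- The stratified 67/33 split takes `floor(fraction * n)` training samples,
  apportioned across labels by largest remainder (proportions preserved to
  one sample); the remainder is the test set. Floor-then-remainder is
  arbitrary but deterministic and documented.
- Inversion is exact (to $10^{-9}$) for non-constant, non-clipped genes,
  so perturbed matrices can be reported in expression units.

## Screening: silhouette on UMAP embeddings

Gene sets are shuffled and cut into disjoint subsets of exactly 16 genes
(incomplete remainders dropped, so all subsets are symmetric). Each
subset's samples are embedded in 2-D with UMAP (`n_neighbors = 90`,
`min_dist = 0.3` — values that balance local and global structure in bulk
expression data; reduced automatically for small matrices) and scored by
the mean silhouette of the phenotype labels.

The silhouette uses the classical Rousseeuw definition — $b(i)$ is the
*minimum mean distance to another cluster's members* — rather than a
nearest-centroid variant; the classical form is the one implemented by
standard libraries and is verified in the tests against two independent
implementations. Singleton clusters contribute $s(i) = 0$.

Subsets are flagged *high* or *low* cluster potential when their score is
strictly beyond the mean ± `k_sd` × **population** standard deviation of
all screened subsets (a census, not a sample, hence the population
normalizer). The random background (`random_background()`) repeats the
screen on random gene draws and summarizes mean and SD, mirroring the
random-control protocol used with curated collections.

UMAP itself is delegated to the reference `umap-learn` implementation via
a batched Python subprocess with a fixed `random_state` — there is no
maintained UMAP implementation for R in this toolchain, and re-deriving
one would add risk without adding science. All subsets of a screen are
embedded in one subprocess, so the interpreter and JIT cost is paid once.

## Core genes and enrichment

Scores from disjoint subsets are pooled into one distribution; a gene is
a **core gene** when $|s_g - \bar s| > k\,\hat\sigma$ with $k = 2$ by
default, strict inequality, population SD. The rule is two-sided: strong
movement in either direction qualifies. Whether to normalize scores
per subset first was an open question; the pooled-raw-score rule is the
simplest and is exposed via `k_sd` and per-subset inputs so either
convention can be computed.

Core-gene lists are annotated by a one-sided hypergeometric
over-representation test against GMT collections, with
Benjamini–Yekutieli adjustment (`stats::p.adjust`, valid under arbitrary
dependence between sets) and a configurable significance threshold
defaulting to the stringent $10^{-10}$ used with very large curated
collections.

## Evaluation metrics

- **MMD**: biased V-statistic with Gaussian kernel; the biased form is
  guaranteed non-negative, which matches its use as a distance readout.
  Bandwidth defaults to the median heuristic on pooled pairwise distances.
- **SVM accuracy**: radial-basis `e1071::svm`, $C = 1$, $\gamma = 1/(d
  \cdot \mathrm{Var})$ (the "scale" convention), fitted on the train
  split. Reported in percent. For synthetic data the intended labels are
  taken as truth.
- `build_eval_report()` assembles the baseline row (test vs train) and one
  row per gene-feature size, the standard augmentation protocol.

## What the synthetic generator emulates — and what it does not

`generate_two_state_gem()` draws per-gene baseline means uniformly in
log2 units (default 2–10, the span of typically expressed genes), adds
Gaussian log-scale noise (sd 1), shifts the planted signal genes by
`effect_size` log2 units in the tumor class, and maps back through
$2^x - 1$ so the preprocessing chain recovers the Gaussian structure.
Defaults used throughout the tests: 200 samples per class, 16 genes, 4
signal genes, effect size 3.

It deliberately does **not** model: count noise (negative binomial
mean–variance coupling), gene–gene correlation beyond the planted shift,
batch effects, outlier samples, or compositional constraints. Passing
tests therefore demonstrate that the machinery is correct and that the
workflow recovers planted, well-separated signal; they do not demonstrate
robustness to the full pathology of real cohorts. The monotonicity
checks (MMD and silhouette increasing with effect size) are trend
validations at desk scale.

## Numerical choices and degenerate inputs

- Timestep $t = 0$ is the "no noise" convention ($\bar\alpha_0 = 1$);
  `ddim_step` to $t_{\text{prev}} = 0$ lands on the data manifold.
- `ddim_step` rejects $\sigma_t^2 > 1 - \bar\alpha_{t_\text{prev}}$, the
  feasibility bound of the implicit family.
- Softmax in attention is max-stabilized; layer norm uses
  $\varepsilon = 10^{-5}$.
- Empty gene lists partition to an empty list (not an error); a single
  cluster is an error for the silhouette; zero-variance inputs are an
  error for the Pearson correlation.
- Non-finite training loss aborts with the iteration number rather than
  continuing silently.

## Problem sizes used in the validation suite

The test and acceptance runs use: 16-gene/400-sample training problems at
$T = 100$ for 2000 iterations (batch 32, embed 64, 2 blocks, 4 heads,
feed-forward 128); bridging with 50–100 ODE steps; screening over a
96-gene matrix with a 50-draw random background; five seeded replicates
for the planted-gene recovery claim. These sizes were chosen so the full
pipeline exercises every code path at interactive timescales while the
planted effects remain comfortably detectable.

## Known limitations

- Training is CPU-bound and single-threaded beyond BLAS; hundreds of
  genes with thousands of iterations is the practical ceiling here.
- Conditioning is a two-class additive embedding; ordinal or continuous
  covariates are out of scope.
- The bridge preserves row pairing and determinism by construction, but no
  optimal-transport property is asserted or tested.
- Gene identifiers are matched as exact strings; no symbol/accession
  mapping is attempted.
- The enrichment module is a local over-representation test; it does not
  replicate any web service's annotation universe.
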