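---
title: "Generative variant design from protein family alignments: models and methods"
author: "FamilyVAE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative variant design from protein family alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(FamilyVAE)
```

# Overview

FamilyVAE implements a data-driven enzyme-engineering workflow built around
a convolutional variational autoencoder (VAE) trained on a protein multiple
sequence alignment (MSA). The workflow has five stages, each exposed as
plain functions on S4 objects:

1. **Curation** — score and remove alignment-distorting homologs, short
   sequences and off-family records, then slice columns to the designated
   wildtype ("target") sequence.
2. **Modeling** — train the VAE on similarity-weighted one-hot sequences.
3. **Sampling** — generate near-wildtype variants by scaling the variance
   of the wildtype's latent encoding.
4. **Validation** — information-theoretic fidelity diagnostics comparing
   model samples to the training family.
5. **Attribution** — consensus-design control library and ridge regression
   of measured phenotypes on binary mutation indicators.

A synthetic-family simulator with analytically known statistics makes every
stage testable without any external data.

# Curation

Structurally dissimilar homologs reveal themselves by forcing mostly-gap
columns into the MSA. With column gap fraction $g_j = N^j_{\mathrm{gap}}/N$,
each sequence $i$ receives a gappiness score

$$s_i = \sum_{j \in G_i : g_j > w} g_j,$$

the sum over the columns where sequence $i$ itself is gapped *and* the
column's gap fraction strictly exceeds the threshold $w$. Defaults are
$w = 0.9$ and removal at $s_i > 10$, followed by removal of sequences whose
ungapped length falls below 290 residues and (optionally) of records whose
description lacks a configured keyword. Choices worth noting:

* **Strict inequality** in $g_j > w$: a column at exactly fraction $w$
  contributes nothing.
* **One scoring pass**: gap fractions are computed on the input alignment;
  scores are not recomputed as sequences are removed. Filtering is
  therefore idempotent.
* **Filter order** is gappy → short → keyword. The final retained set does
  not depend on the order, but the per-reason tallies do; the order above
  is the one reported.
* **Keyword matching** is a case-sensitive substring by default; the
  description metadata of public sequence records is too inconsistent for
  whole-word matching to be a safe default.
* Ambiguity codes (B, J, X, Z, U, O) are rejected on read unless the caller
  opts into mapping them to the gap letter.

Slicing then drops every column where the target row is gapped, making
column indices equal to 1-based target residue positions (the coordinate
system used by mutation names such as `A135T` and `ΔK70`). Dropped column
indices are reported 0-based in the machine-readable report.

# Encoding, weighting and batching

Sequences are one-hot encoded over the fixed 21-letter alphabet
`ACDEFGHIKLMNPQRSTVWY-` (20 amino acids, then the gap). The alphabet order
is serialized with every checkpoint. An aligned row of width $L$ becomes an
$L \times 21$ binary matrix; for the 322-column OTC-style alignment this is
the $(322, 21)$ representation.

Training batches are drawn **with replacement** with probability
proportional to $\mathrm{id}(x_i, t)^{2.25}$, the fraction of sequence
identity to the target raised to the 2.25 power, which concentrates
training on the neighborhood of the wildtype without discarding distant
homologs. Identity counts gap–gap columns as matches with the full
alignment width as denominator — the simplest symmetric convention; it is
configurable via the `exponent` argument and documented because alignments
with heavy gapping are sensitive to it. Weights enter training only through
the sampler, never as loss multipliers. The target is always forced into
the training split because the sampling stage must encode it.

# The model

The encoder applies three blocks of (3×3 same-padding convolution, ELU,
2× max-pool along the length dimension only); the flattened features feed
two affine heads emitting the latent mean $Z_\mu$ and log-variance
$\log Z_\sigma^2$. The decoder mirrors this: an affine map from $z$,
three blocks of (2× nearest-neighbour length upsampling, 3×3 convolution,
ELU), a final 3×3 convolution to one channel, and a softmax over the
alphabet dimension, yielding a categorical distribution per position.
Default filter counts are 128/96/64 (encoder) and 64/96/128 (decoder) with
a 64-dimensional latent space; weights are Kaiming-normal initialized.

The objective is the negative evidence lower bound

$$\mathcal{L} = \underbrace{-\mathbb{E}_q[\log p_\theta(x \mid z)]}_{\text{cross-entropy}}
  + \beta \, D_{KL}\!\left(q_\phi(z \mid x) \,\|\, \mathcal{N}(0, I)\right),$$

with the KL weight $\beta$ annealed linearly from 0 on the first epoch to 1
on the last to avoid posterior collapse. Optimization is Adam
(learning rate $10^{-3}$, the optimizer default) for 30 epochs with batch
size 128 in the reference configuration.

Design choices in the architecture that were genuinely open:

* **Geometry.** The one-hot matrix is treated as a single-channel 2-d
  image; kernels are 3×3 with same-padding. Pooling and upsampling act on
  the length dimension only, so alphabet-local structure is never
  coarsened.
* **Padding.** Three 2× poolings require the length to be divisible by 8;
  inputs are padded on the right with gap-letter columns to the next
  multiple of 8 (322 → 328) and decoder outputs are cropped back. The gap
  letter is the least informative filler.
* **Batch normalization is omitted.** The blocks are conv–ELU–pool
  without normalization layers; at the scales this package targets,
  training converges well without them, and omitting them keeps the model
  a pure function of its parameters (no train/eval mode distinction,
  exactly reproducible encodings).
* **Latent heads.** Mean and log-variance are independent affine maps of
  the flattened encoder features; log-variance is clamped to $[-15, 15]$
  purely as an overflow guard.
* **Numerics.** Decoder probabilities are clamped at $10^{-8}$ before the
  log in the cross-entropy; the closed-form Gaussian KL
  $\tfrac12\sum_d (e^{\ell_d} + \mu_d^2 - 1 - \ell_d)$ is used, and both
  losses are means per sequence, in nats.
* **Test loss** is reported both at the epoch's annealed $\beta$ and at
  $\beta = 1$, since convergence monitoring is only comparable across
  epochs on the $\beta = 1$ scale.
* **Gradients.** All layers are differentiated in closed form (the
  compiled kernels implement im2col convolution and its adjoint); the test
  suite checks every layer against central finite differences. Max-pool
  ties receive the first-argument subgradient, the usual convention.

Training is seed-reproducible: initialization, batch draws and
reparameterization noise all flow from one integer seed through R's RNG.

# Near-wildtype sampling

To propose variants, the target is encoded once to $(\mu, \sigma^2)$ and
latent vectors are drawn from $\mathcal{N}(\mu, s \cdot \mathrm{diag}(\sigma^2))$
at increasing variance multipliers $s$; each draw is decoded and the modal
letter taken per position (argmax). Scale 0 is the maximum-a-posteriori
decode. The sweep keeps decoded sequences that differ from the target,
discards any exceeding the mutation cap (default 16, ≈5% of a 322-residue
protein), and deduplicates exactly, crediting each unique variant to the
first scale that produced it.

Open choices and their defaults:

* **Schedule.** The published procedure "repeatedly increased the
  variance"; the default ladder is geometric
  (0, 0.25, 0.5, 1, 2, 4, 8, 16) with 100 draws per scale, configurable.
* **Stopping.** The sweep stops at the first scale that yields any
  over-cap sequence (reading "until we reached an upper limit" as a
  stopping rule); a filter-and-continue mode is available.
* **Variance vs sigma.** The multiplier scales the *variance* by default;
  a flag scales the standard deviation instead — the two differ only in
  how the schedule is parameterized.
* **Deletions** decoded as gap letters are kept and named `ΔXn`; they are
  real design moves, not artifacts to resample away.

# Fidelity diagnostics

Model quality is judged by whether samples reproduce the family's
first- and second-order statistics. Per-column letter frequencies are plain
counts $\tilde p_j^a = n_j^a / N$ with the gap as a 21st letter and no
pseudocounts. Site entropy is $H_j = -\sum_a \tilde p \log \tilde p$ and
pair mutual information is

$$I_{j,k} = \sum_{a,b} \tilde p_{j,k}^{a,b}
  \log \frac{\tilde p_{j,k}^{a,b}}{\tilde p_j^a \tilde p_k^b}
  = H_j + H_k - H_{j,k},$$

computed via the entropy form with the double-sum form retained as an
independent cross-check (the suite requires agreement to $10^{-10}$).
Logarithms are natural (nats) by default. The report gives squared Pearson
correlations of the pooled frequency scatter and of the upper-triangle MI
scatter between training data and samples, plus the correlation between
per-sequence Hamming distance to the target and Euclidean distance between
latent means — overall and for the closest 5% of sequences (ceiling count,
ties by input order). Latent distance uses $\mu$ only, not sampled $z$,
so the statistic is deterministic.

For these diagnostics, samples are **posterior-predictive**: each draw
encodes a family sequence picked uniformly with replacement, samples its
latent Gaussian, decodes, and draws letters from the decoder's categorical
distributions. Two alternatives were considered and are available through
arguments. Sampling latents from the standard-normal prior measures pure
generative quality, but at the compact model scales this package trains,
the aggregated posterior does not fill the prior, so prior samples partly
decode off the family manifold and the diagnostic conflates decoder
fidelity with prior coverage; the posterior-predictive version isolates
how faithfully the model reproduces the statistics of the family it
encodes. Argmax letter realization (instead of categorical) systematically
sharpens frequencies and is reserved for variant proposal, where modal
sequences are wanted.

# Consensus design

The consensus sequence takes each column's most frequent non-gap letter
(a consensus protein cannot carry alignment gaps); ties break
deterministically by alphabet order, and a column that is entirely gap is
an error. Substitutions converting the target to the consensus define a
combinatorial library of $2^k$ on/off combinations, enumerable exactly for
$k \le 25$ or sampled uniformly without replacement. Sampling uniformly at
the amino-acid level is a deliberate simplification: the published control
library was encoded with degenerate codons whose nucleotide-level biases
(and occasional extra amino acids) are out of scope here.

# Mutation-effect regression

Measured phenotypes (specific activity in µmol/min/mg; melting temperature
in °C) are attributed to individual mutations with the linear model
$y = x^\top\beta + \varepsilon$ on binary mutation indicators plus a single
binary `library` covariate (0 = VAE library, 1 = consensus library),
because the two libraries are assayed separately. Replicates are averaged
per variant, then standardized to z-scores with the sample ($n-1$) standard
deviation. The ridge estimate

$$\hat\beta = (X_c^\top X_c + \lambda I)^{-1} X_c^\top z_c$$

is computed in closed form on centered data with an **unpenalized
intercept** (required for well-posedness alongside the group covariate).
The default penalty is $\lambda = 1$ on standardized responses —
a reproducible default — with leave-one-out cross-validation over a log
grid available via the closed-form LOO identity $e_i / (1 - h_{ii})$.
Multi-residue deletions are encoded as their constituent single-position
deletion columns co-occurring. Coefficient pairs for the two responses are
reported by sign quadrant (`++` improves both, `--` harms both, mixed
quadrants trade off), sorted by Euclidean magnitude.

# The synthetic family

The simulator emulates exactly the statistical structure the diagnostics
measure: designed per-column site profiles, designed coupled column pairs
with closed-form mutual information, an identity gradient to the target,
and phenotypes that are a linear function of mutation indicators plus
Gaussian noise. Each non-target sequence draws a mutation rate uniformly
from [0, 0.6] (hence identities ≈40–100%), replaces target letters at that
rate with draws from site profiles over three non-target letters, draws
coupled pairs jointly from their designed joint distribution (a balanced
two-state joint, MI = log 2, by default), and receives gaps at rate 0.01
per uncoupled column. Coupled columns stay gap-free so their designed MI
is exact in expectation, and couplings are explicit joint distributions
rather than a Potts model so the oracles are closed-form and sampling is
cheap.

What the simulator deliberately does **not** emulate: phylogenetic
correlation between sequences (rows are exchangeable draws), insertions,
alignment errors, and higher-order (>pairwise) couplings. Passing the
pipeline's tests on this family therefore demonstrates correctness of the
implementation and learnability of marginal and pairwise structure — not
performance on real, tree-correlated MSAs.

# Problem sizes and reproducibility

The reference configuration (width 322, 3818 sequences, filters 128/96/64,
latent 64, 30 epochs) is what the defaults encode. The package's own test
and demonstration runs use a scaled family — width 64, 2000 sequences, one
coupled pair, 20 epochs, encoder filters 16/12/8, latent 16, batch 128 —
chosen so the complete train–sample–diagnose cycle runs in minutes on a
single CPU core while leaving the learning problem nontrivial (the model
must still recover ~60 site profiles, the identity gradient and the
designed coupling). The quick-turnaround fixtures in the unit tests are
smaller still (width 32, 300 sequences). All reported quantities are
computed at run time by the functions described above; seeds are explicit
arguments everywhere randomness enters.

# Known limitations

* Training is CPU-bound dense linear algebra; paper-scale models are
  feasible but slow (hours, not minutes) in this implementation.
* The Hamming–latent correlation of a freshly initialized model is
  meaningless; diagnostics assume a trained model and do not warn
  otherwise.
* The consensus library models substitutions only; positions where the
  target is gapped relative to the family are skipped.
* Ridge attribution assumes additivity; epistatic pairs will be absorbed
  into main effects.
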