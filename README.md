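# FamilyVAE

Generative variant design from protein family alignments.

## The problem

Engineering a more stable, more active enzyme means searching an
astronomically large sequence space with very few experimental shots.
One productive shortcut is the evolutionary record: a multiple sequence
alignment (MSA) of a protein family encodes which residues tolerate change
and which co-vary. FamilyVAE packages a complete data-driven design loop
around that idea, built for workflows like re-engineering human ornithine
transcarbamylase (OTC, a urea-cycle enzyme) from an alignment of a few
thousand homologs:

1. **Curate** the MSA around a designated wildtype ("target"): remove
   homologs that force mostly-gap columns (gappiness score
   `s_i = sum of column gap fractions > w` over the columns where sequence
   *i* is gapped; defaults `w = 0.9`, cutoff `s_i > 10`), drop short and
   off-family records, and slice columns to the target's ungapped
   positions.
2. **Model** the family with a convolutional variational autoencoder (VAE)
   over one-hot sequences (`L x 21`: 20 amino acids + gap). Three
   conv/ELU/max-pool encoder blocks produce a latent Gaussian
   `(Z_mu, Z_sigma)`; a mirrored decoder with nearest-neighbour upsampling
   and an alphabet softmax reconstructs sequences. Training minimizes the
   negative ELBO, `cross-entropy + beta * KL(q(z|x) || N(0, I))`, with
   `beta` annealed linearly 0 to 1 across epochs, Adam, and batches drawn
   with replacement weighted by `identity(seq, target)^2.25`.
3. **Sample near-wildtype variants**: encode the target, scale the
   variance of its latent Gaussian upward, decode draws by per-position
   argmax, deduplicate, and cap mutations per variant (default 16).
   Gap letters decoded inside the target's coordinates are deletions
   (`ΔK70`); substitutions are named like `A135T`.
4. **Validate** the model with information-theoretic diagnostics: per-site
   frequencies and entropies `H_j`, pairwise mutual information
   `I_{j,k} = H_j + H_k - H_{j,k}`, squared Pearson agreement between
   training data and model samples, and the correlation between Hamming
   distance to the target and Euclidean distance between latent means.
5. **Attribute phenotypes to mutations**: build a binary design matrix of
   mutation indicators plus a library covariate (VAE vs consensus
   control library), average and z-score replicate measurements
   (specific activity, melting temperature), and fit ridge regression
   `beta = (Xc'Xc + lambda I)^-1 Xc'z` with an unpenalized intercept;
   report coefficient sign quadrants. A consensus-design control library
   (column-wise modal residues, `2^k` combinatorial variants) is built
   from the same alignment.

A synthetic-family simulator with *known* site profiles, a designed
coupled column pair of exact mutual information `log 2`, an identity
gradient to the target, and phenotypes generated from known linear
mutation effects makes the entire pipeline testable offline; it is
first-class, tested code.

## Worked example

A complete cycle on a small synthetic family (widths and epochs chosen so
this runs in about a minute; see the methods vignette for the scaled
study configuration):

```r
library(FamilyVAE)

cfg  <- familyConfig(L = 32, N = 400, nCoupledPairs = 1, seed = 5)
aln  <- generateFamily(cfg)
aln
model <- buildVAE(vaeConfig(32, latentDim = 8,
                            encoderFilters = c(12, 10, 8),
                            decoderFilters = c(8, 10, 12)), seed = 1)
model <- trainVAE(model, aln, splitTrainTest(aln, seed = 2),
                  trainingWeights(aln), epochs = 8, batchSize = 64, seed = 3)
model

rep <- fidelityReport(model, aln, nSamples = 500, seed = 9)
rep

vs <- varianceSweep(model, targetSequence(aln),
                    samplingSchedule(scales = c(0, 0.5, 1, 2, 4),
                                     samplesPerScale = 50,
                                     maxMutations = 8, seed = 2))
vs
head(variantTable(vs)[, c("id", "scale", "hamming", "mutations")], 4)
```

```
FamilyAlignment: 400 sequences x 32 columns (target 'target')
  gap fraction: 0.009
SequenceVAE (trained): L=32, |A|=21, latent=8
  encoder filters: 12/10/8; decoder filters: 8/10/12
  last epoch: train total 64.7732, test total 70.5329
FidelityReport
  frequency R^2:          0.7012
  mutual information R^2: 0.0029
  Hamming~latent R^2 (all / closest 5%): 0.7730 / 0.9435
VariantSet: 53 unique variants of a 32-residue target
  Hamming distance to target: 4-8 (mean 5.83)
        id scale hamming                     mutations
1 vae_0001   0.0       4           R10G,S12R,Y29D,I32A
2 vae_0002   0.5       6 R10G,S12R,W16L,I27Y,Y29D,I32A
3 vae_0003   0.5       5      R10G,S12N,Q21V,Y29I,I32A
4 vae_0004   0.5       5      R10G,S12R,Q21V,Y29D,I32A
```

Reading the output: after only eight epochs this deliberately small demo
model already tracks the family's per-site frequencies (R² 0.70) and its
latent geometry follows sequence distance, most strongly among the
sequences closest to the target (R² 0.94) — the neighborhood variant
sampling explores. The variance sweep proposes unique near-target
variants, each annotated with its generating variance scale, mutation
count, and named mutations; mean mutation load rises with the scale. At
the study configuration (width 64, 2000 sequences, 20 epochs — what
`scripts/acceptance.R` runs), frequency R² reaches ≈0.99 and the model's
samples separate a designed coevolving column pair from uncoupled
background.

For phenotype attribution:

```r
lib  <- simulateMutationLibrary(paste0("A", 1:10, "C"), nVae = 30,
                                nConsensus = 30, seed = 3)
beta <- setNames(seq(-0.9, 0.9, length.out = 10), paste0("A", 1:10, "C"))
ph   <- generatePhenotypes(lib$variant_id, lib$mutations, lib$library,
                           phenotypeConfig(beta, -beta, seed = 4))
res  <- mutationEffectRegression(
          lib$variant_id, lib$mutations, lib$library,
          activity = as.matrix(ph[, 3:5]), tm = as.matrix(ph[, 6:8]),
          lambda = "loocv")
head(res$quadrants)
```

A command-line front end with `curate`, `train`, `sample`, `diagnose`,
`consensus`, `simulate` and `regress` subcommands is installed at
`inst/scripts/familyvae`.

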