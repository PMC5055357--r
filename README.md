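# dualOCCF

Genome-wide chemical–protein (off-target) interaction prediction by
**dual-regularized one-class collaborative filtering**: a weighted
nonnegative matrix factorization of the sparse chemical–protein
association matrix, with graph-Laplacian regularization on both a
chemical–chemical similarity network (Tanimoto coefficient over
ECFP-style fingerprints) and a protein–protein similarity network
(BLAST bit-score ratios). It is aimed at computational chemists and
chemogenomics groups who have a sparse matrix of known binding pairs
and want ranked target predictions for each compound — including
cold-start compounds with few or no known targets — plus downstream
drug-repurposing analysis of the learned latent profiles.

## The model

Known associations form a sparse indicator matrix `R` (n chemicals ×
m proteins). Two nonnegative low-rank factors `U` (n × r) and `V`
(m × r) are fitted by minimizing

```
min_{U,V ≥ 0}  Σ_ij W_ij (R̃_ij − U_i·V_j)²
             + p_reg (‖U‖²_F + ‖V‖²_F)
             + p_chem · tr(Uᵀ(D_C − C)U)
             + p_prot · tr(Vᵀ(D_T − T)V)
```

where observed positives have weight `W_ij = 1` and target `R̃_ij = 1`,
and every unobserved entry has weight `p_wt` and imputed target `p_imp`
(the assumed probability that an untested pair truly binds — the
one-class treatment of implicit feedback). `C` and `T` are the
similarity matrices with degree matrices `D_C`, `D_T`; the Laplacian
terms force similar chemicals (and similar proteins) toward similar
latent rows, which is what rescues cold-start compounds. The default
setting is `p_wt = p_imp = p_reg = 0.1`, `p_chem = 0.75`,
`p_prot = 0.1`, `r = 300`, 400 multiplicative-update iterations.

The raw prediction score is `P_ij = U_i · V_j`. Optionally, raw scores
are calibrated against labeled active/inactive/ambiguous pairs through
a binned estimator (bin width 0.05, outliers above 1.10 dropped): the
ambiguous-score histogram is matched to a convex mixture
`w1·active + (1−w1)·inactive`, and each bin's adjusted score is
`B_i = pos / (pos + floor((w2/w1)·neg))`.

Evaluation follows a 10-fold cross-validation protocol reporting the
true positive rate (recovery) of held-out pairs at top-percentile
cutoff ranks, stratified by the chemical's number of known targets
(NT1/NT2/NT3), the protein's ligand count (L1to5 … L21more) and the
chemical's maximum structural similarity to the training set
(Tc0.5to0.6 … Tc0.9to1.0). Row profiles of `U` ("low-rank drug
profiles") feed a cosine-similarity drug–drug network (edges at
S_cos > 0.3, structurally novel pairs flagged at Tanimoto < 0.5) that
is clustered with the Markov Cluster algorithm for repurposing
candidates.

## Worked example

```r
library(dualOCCF)

dat <- generateSynthetic(syntheticSpec(seed = 1))   # 200 x 100 block world
dat$observed
#> InteractionTable: 200 chemicals x 100 proteins
#>   pairs: 192 active, 0 inactive, 0 ambiguous

cfg <- occfConfig(rank = 50, nIter = 400, seed = 1) # pChem = 0.75 default
model <- fitOccf(dat$observed, thresholdSimilarity(dat$C), dat$T, cfg)
model
#> FactorModel: U 200 x 50, V 100 x 50
#>   objective: 680.827 -> 121.513 (401 recorded values)

ranks <- heldoutRanks(model, dat$observed, dat$heldout)
tprAtCutoff(ranks$rank, topPercentCutoff(100, 0.05))
#> [1] 0.2291667
```

The objective decreases monotonically from its initialization value;
the final number is the held-out recovery at the top 5 % of the
protein panel, about 4.5× the 0.05 random-ranking null on this
instance (and it drops to roughly the null when `pChem = 0` — the
chemical similarity carries most of the cold-start signal). Top
predictions for one compound:

```r
predictTopK(model, chemical = 1, k = 3)
#>   protein     score rank proteinId
#> 1      17 0.3987349    1  prot0017
#> 2      10 0.3602931    2  prot0010
#> 3      13 0.3584749    3  prot0013
```

A command-line wrapper over the same functions is installed at
`system.file("scripts", "dualocf", package = "dualOCCF")` with
subcommands `simulate`, `fit`, `predict`, `benchmark`, `calibrate` and
`repurpose`; every run writes a `manifest.json` with the resolved
configuration and seeds.

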