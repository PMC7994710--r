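# coevopair

Tools for studying how far interface mutual information (MI) can resolve
interaction partners between two coevolving protein families — and why,
mostly, it cannot.

## The problem

Given row-matched multiple sequence alignments (MSAs) of two interacting
families A and B, a *pairing* `z` is a permutation matching each A row to a
B row. Physically coupled residues at the complex interface (column pairs
whose Cβ–Cβ distance in a representative structure is ≤ 8 Å) carry a
coevolutionary signal, quantified per contact as

    Î_AB(z) = (1/N) Σᵢ Σ_{x,y} f(xᵢ, yᵢ | z) ln[ f(xᵢ, yᵢ | z) / (f(xᵢ) f(yᵢ)) ]

in nats over the 21-letter alphabet (20 amino acids + gap), with
pseudocount smoothing (λ/Q for singles, λ/Q² for joints, λ = 0.001).
Maximizing Î_AB over the M! pairings with a minimal mutation-only elitist
genetic algorithm (population 8, top-50 % elite, one partner swap per
offspring) probes the degeneracy of this score: the number of pairings
with near-native MI vastly exceeds M, so optimized solutions reach
native-level MI while pairing few rows correctly. Their errors split into
mismatches among similar sequences (type i — forgiven when the wrong
partner lies within the 20th percentile of family B's Hamming-distance
distribution; discounted TP rate > 30 %) and among dissimilar ones
(type ii). A k-nearest-neighbour vote (k = 10) separates the two types in
the plane of relative Î_AB against the correlation between optimized and
native per-contact MI vectors, and an evolutive/coevolutive decomposition
compares interface MI with the MI of arbitrary inter-family column pairs.

The package implements the full stack: paired-alignment data model and
I/O, contact extraction from PDB/mmCIF structures, the MI machinery, the
genetic algorithm (compiled incremental core with an exactly equivalent
R reference engine, and a within-species move set for paralogous
families), TP-rate assessment with mismatch discounting, solution typing,
KNN separation, system grouping and cross-system correlations, plus a
synthetic generator of coevolved alignment pairs with controllable
coupling strength, similarity-cluster structure and species composition.

## Worked example

Generate a clustered synthetic family pair, optimize six replicates, and
assess the solutions:

```r
library(coevopair)

dat <- generateSyntheticPair(synthSpec(M = 60, N = 20, LbgA = 20, LbgB = 20,
                                       epsilon = 0.8, qEff = 6, nClusters = 6,
                                       seed = 11))
nat <- interfaceMI(dat$pair, dat$cmap)
nat
#> MIResult: N = 20 | I^_AB = 0.5031 nats/contact | total = 10.0626 | I/H sum = 15.2902

trajs <- runReplicates(dat$pair, dat$cmap,
                       gaConfig(generations = 5000L, seed = 1), nat,
                       replicates = 6L)
sols <- lapply(trajs, function(t)
  assessSolution(dat$pair, dat$cmap, finalPairing(t), nat))
solutionTable(sols)
#>    tpRaw tpDiscounted relativeMI rNative    type      kind
#> 1 0.0000       0.0000      0.468   0.785 type_ii optimized
#> 2 0.0000       0.0667      0.520   0.799 type_ii optimized
#> 3 0.1333       1.0000      1.000   1.000  type_i optimized
#> 4 0.0000       0.0667      0.460   0.815 type_ii optimized
#> 5 0.1833       1.0000      1.000   1.000  type_i optimized
#> 6 0.0667       1.0000      1.000   1.000  type_i optimized

rnd <- assessSolution(dat$pair, dat$cmap, scramblePairing(60, seed = 9), nat,
                      kind = "random")
assignGroup(sols, rnd)
#> [1] "G3"
```

Read the output back to front: three replicates found the native-level
optimum (relative MI 1.000) yet paired at most 18 % of rows correctly —
their mistakes are swaps among similar sequences, so the 20th-percentile
discount lifts their TP rate to 100 % (type i). The other three froze on
degenerate arrangements with near-zero TP even after discounting
(type ii). An even split makes this a group-3 system.

`runPipeline(runConfig(...))` chains the same steps (simulate/load →
optimize → evaluate → classify → report) into a run directory with a
seed-stamped manifest; `inst/scripts/coevopair.R` is a thin command-line
wrapper over it. The methods vignette
(`vignettes/partner-matching.Rmd`) documents the model, the estimators,
every tunable default and the generator's design.

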