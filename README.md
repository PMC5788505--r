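# pathmapr

Integrative mapping of linear metabolic pathways from heterogeneous
restraints.

## The problem

Genome and metagenome sequencing outpaces experimental enzyme
characterization: large families of "orphan" enzymes sit in genome
neighborhoods that clearly encode catabolic pathways whose substrates,
intermediates, and enzyme order are unknown. No single computational
source — docking screens, ligand-set similarity, generic reaction
chemistry, thermal-shift screening — is reliable enough on its own to
assign such a pathway. `pathmapr` is for the systems/chemical biologist
who has several such noisy sources and wants the ensemble of linear
pathway models that best satisfies *all* of them, with an honest account
of the ensemble's precision.

## The method

A pathway model of length K is a linear graph alternating ligand and
protein nodes, `m1 — p1 — m2 — … — pK — m(K+1)`, drawn from candidate
pools. Every information source becomes a restraint expressed as a
Z-score, and the composite score of a model is

    Z_Pathway = Z_VS + Z_CT + Z_SEA + Z_CM + Z_HTS + Z_HS (+ Z_GC)

* **Z_VS** (virtual screening): `-(1/N) Σ z_i` over all scored
  enzyme-substrate and enzyme-product pairs, where each protein's raw
  docking scores are Z-normalized over its own screen.
* **Z_CT** (chemical transformations): per substrate–enzyme–product
  triad, the substrate is transformed by the enzyme's SMIRKS reactions;
  the Tanimoto coefficient between the transformed molecule (Morgan
  fingerprints, chirality encoded, up to 16 stereoisomer assignments for
  undefined centers) and the product is Z-scored against all candidate
  metabolites, and triad Z-scores are averaged. A dummy node (unknown
  enzyme) scores its triad by direct substrate–product similarity.
* **Z_SEA** (ligand-set similarity): pair E-values become
  `S_AB = w_AB · min(w_AA, w_BB)/50` with `w = min(-log10 E, 50)`,
  Z-normalized over all candidate pairs and averaged over consecutive
  pathway pairs.
* **Z_CM** (pathway boundary): Z-scored maximum similarity of the final
  metabolite to central metabolism.
* **Z_HTS / Z_HS**: Z-scored similarity of a screened (or homology
  annotated) protein's substrate to its screening hits (or reference
  substrate).
* **Z_GC** (genome context, optional): Z-scored overlap between the
  model's protein pair set and a gene-cluster pair set.

Terms whose information is missing are simply omitted. Good-scoring
models are found by Metropolis Monte Carlo simulated annealing
(temperature `T = 0.3·0.2^N + 0.1` over the normalized step number N;
moves swap two same-type nodes or replace a node with an unused
candidate). Independent runs are merged; unique models scoring within
`cutoff_sd` (2.0 by default) random-model standard deviations of the best
are the good-scoring ensemble, which is clustered by normalized Hamming
distance (hierarchical, average linkage, cut at 0.2), summarized as
enzyme–ligand edge frequencies, and exported as a union-network JSON
document.

A planted-pathway synthetic generator (`generate_problem()`) emits every
input in the package's plain-text exchange formats around a chemically
exact reaction chain, so the whole stack is testable without any docking
infrastructure.

## Worked example

```r
library(pathmapr)

# a planted length-4 problem: 4 true enzymes + 3 decoys, 13 metabolites
prob <- generate_problem(synthetic_config(K = 4, seed = 3))

fit <- pathway_map(prob, config = sampler_config(
  n_steps = 10000, n_runs = 8, n_random_models = 1000, seed = 11
))
print(fit)
#> Integrative pathway map
#>   lengths modeled: K = 4
#>   K=4: 414 good-scoring / 1697 unique sampled (best 17.439, cutoff 13.333)
#>   clusters (Hamming cut 0.2): 67
#>   top model: glycerol -> enz1 -> glyceraldehyde -> enz2 -> glycerate -> enz3 -> glycerate-3P -> enz4 -> hydroxypyruvate-3P

summary(fit)$best_breakdown
#>   z_vs   z_ct  z_sea   z_cm  z_hts   z_hs
#> 1.1359 3.1285 2.4490 5.3254 2.2570 3.1434
```

The top model is exactly the planted pathway
(`identical(fit$models[[1]]$key, canonical_key(prob$planted))` is
`TRUE`): the sampler recovered the true enzyme order and all five
intermediates from noisy docking scores, reaction chemistry, ligand-set
similarity, the endpoint restraint, screening hits and one homology
annotation combined — while under docking alone the same pathway
typically ranks in the hundreds (see `full_scoring_mean_rank` vs
`docking_only_mean_rank` below). The breakdown shows every restraint
contributing; `cutoff = best − 2·SD(random models)` separates the 414
good-scoring models that form the reported ensemble.

A thin command-line wrapper covers the same workflow from a shell
(`inst/cli/pathmap.R`: subcommands `synth`, `build-candidates`, `map`,
`analyze`, `ablate`).

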