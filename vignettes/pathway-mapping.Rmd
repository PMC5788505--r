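---
title: "Integrative pathway mapping: model, restraints, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative pathway mapping: model, restraints, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the pathway model and its assumptions, each restraint term with its
normalization, the sampler, the analysis stage, the synthetic
planted-problem generator, and the numerical and design decisions that
were genuinely open.

## The pathway model

A candidate pathway of length $K$ is a linear graph of $2K+1$ nodes
alternating ligands and proteins, beginning and ending with a ligand. The
representation makes three assumptions:

* **Linearity.** Only linear topologies are sampled; branched or cyclic
  pathways are out of scope.
* **Uniqueness.** No protein or metabolite appears twice in one model.
  Real pathways can revisit a cofactor, but cofactors are deliberately
  not modeled as pathway nodes here — nodes are the pathway-defining
  identities only.
* **Identity-only nodes.** No stoichiometry, cofactor bookkeeping, or
  flux: an edge asserts "this enzyme acts on this ligand", nothing more.

Pathways of unknown length are modeled by running each plausible $K$
independently and reporting the per-length ensembles side by side; the
combined model list is ranked by raw composite score. Cross-length
Hamming distance is defined as 1, so clusters never mix lengths. How to
trade pathway length against score in a single number is genuinely
unresolved; the package deliberately reports, rather than hides, that
choice.

A transporter solute-binding protein occupies a protein position like an
enzyme, with its solute at the preceding ligand position. Having no
reaction, it is scored in the transformation term by the same direct
substrate–product similarity rule as a dummy node.

## Restraints and normalization

Every information source enters as a Z-score so heterogeneous units
become commensurate; missing information simply omits a term rather than
penalizing a model. Higher composite score is better; the leading minus
sign in the docking term converts "lower docking score is more favorable"
into that convention.

Populations behind each normalization:

* **Docking**: each protein's own full score table (so per-protein
  Z-scores have population mean 0 and SD 1 by construction).
* **Transformations**: per (enzyme, substrate) pair, the Tanimoto
  coefficients between the transformed substrate and *all candidate
  metabolites* — mirroring the per-row docking scheme. A substrate that
  matches none of an enzyme's reaction motifs contributes similarity 0
  before normalization; an all-zero population is uninformative and the
  guard maps it to Z = 0.
* **SEA**: all unordered pairs of non-dummy candidate proteins.
* **Endpoint**: all candidate-by-central pairwise similarities (not the
  per-candidate maxima), matching the "all comparisons" population
  wording of the source data convention; the scored statistic is the
  final ligand's maximum similarity to central metabolism.
* **Screening hits / homology**: the per-candidate statistic (maximum
  similarity over hits; similarity to the reference) over the candidate
  set. The alternative population — the full docked library — is a
  config-level choice; the candidate set is used because it is the
  sampling space the statistic competes in.
* **Gene cluster**: the overlap statistic over all protein subsets of
  size 3 up to the candidate count, enumerated exhaustively up to $2^{20}$
  subsets and sampled (seeded, $10^5$ draws) beyond.

The `-log` in the SEA weight is taken base 10 (the usual significance
convention for E-values); the cap at 50 makes the base immaterial for
strongly significant pairs. Missing SEA self-pairs default to the maximal
self-weight 50 with a warning, since the confidence factor only lowers
scores.

All populations are computed once when the scorer is compiled, so scoring
is a pure function of the node sequence: this is what makes millions of
Monte Carlo evaluations cheap (table lookups) and reproducible.

## Chemistry

Molecules are compared by Morgan (circular) fingerprints of radius 2
folded to 2048 bits with chirality encoded — the community default
parameterization; chirality matters because sugar-acid interconversions
often differ only stereochemically. Two empty fingerprints score
similarity 0 (no evidence). Generic reactions are SMIRKS strings applied
at every matching site; products are canonicalized and deduplicated, and
product comparisons use the maximum over at most 16 distinct stereoisomer
assignments of unassigned centers (products of generic transforms
routinely lose stereo assignments). Enumeration is delegated to the
chemistry toolkit's stereoisomer enumerator (unassigned centers only,
unique structures, capped at 16), which is deterministic; the cap keeps
worst-case cost bounded. Tautomer normalization and protonation-state
enumeration are intentionally out of scope.

The endpoint, screening-hit and homology terms use plain (chirality-aware)
fingerprint similarity: their inputs are curated molecules with defined
stereochemistry, unlike transformation products.

## Sampling

Metropolis Monte Carlo with simulated annealing maximizes the composite
score. Moves: swap two same-type nodes, or replace a node with an unused
same-type candidate; the move class is chosen uniformly when both are
available, positions and replacements uniformly among legal options.
Constrained positions are never violated. A worse proposal is accepted
with probability $\exp(-D/T)$, $D$ the score decrease; the temperature
follows $T = 0.3 \cdot 0.2^{N} + 0.1$ in the normalized step number $N$,
falling from 0.4 to 0.16. All accepted states (including the random
start) are recorded, deduplicated by canonical key; per-run seeds are
master seed + run index, so ensembles are reproducible and trivially
parallel.

The good-scoring cutoff is `best − cutoff_sd × SD(random models)` with
`cutoff_sd = 2.0` by default and 1.5 supported for long pathways, where
the larger model space otherwise inflates the ensemble. Reference-scale
settings (5,000,000 steps, 1000 runs, 10,000 random models) are the
defaults of `sampler_config()`; every analysis in the package's tests and
acceptance script runs the same code at desk scale (thousands of steps,
4–8 runs), sizes chosen so that small planted instances demonstrably
converge — on instances small enough to enumerate, the sampled optimum
matches exhaustive enumeration across seeds.

## Analysis

Good-scoring models are clustered by normalized Hamming distance with
average-linkage hierarchical clustering cut at 0.2. The linkage is not
dictated by the method; average linkage is the robust default for a flat
cut and is recorded in the export metadata. Cluster representatives are
the best-scoring members (ties broken lexicographically by key).
Edge-frequency tables rank, per protein, how often each enzyme–ligand
edge occurs in the ensemble — the quantity that shows how restraint
integration re-ranks ligands relative to raw docking. Convergence is the
fraction of final clusters discovered after the first $r$ runs; a curve
that plateaus before the last run indicates adequate sampling. The
union-network JSON export (`format: "netimp/1"`) is canonical: nodes and
edges sorted, numbers at full precision, so export → import → export is
byte-identical.

## The synthetic generator

`generate_problem()` plants a true pathway inside a complete, fully
self-contained problem. Its defaults are the package's reference study
conditions and are not tuning knobs:

* A curated five-step chain of real molecules connected by exact
  transformations: glycerol → glyceraldehyde → glycerate →
  3-phospho-glycerate → phosphohydroxypyruvate → hydroxypyruvate
  (oxidations, a phosphorylation, a dephosphorylation). Exactness is
  what lets the transformation term carry signal.
* `K = 4` with 3 decoy proteins and 8 decoy metabolites drawn from a
  curated pool of small organics (including deliberate near-confounders:
  ethylene glycol, glycolaldehyde, lactate).
* Docking: unit Gaussian noise; true enzyme–ligand pairs shifted 1.5
  population SDs toward favorable (`docking_signal = 1.5`,
  `docking_noise = 1.0`).
* SEA: adjacent true protein pairs at E ≈ 10⁻²⁰ against a background
  drawn uniformly on [0.3, 1]; self pairs at 10⁻⁵⁰. The exponent 20 is a
  typical strongly significant ligand-set similarity; the cap at 50 makes
  larger exponents equivalent.
* Endpoint: central metabolism is a fixed set of genuine central
  metabolites plus the chain's terminal compound (the pathway-boundary
  knowledge the method assumes); screening hits contain the true first
  substrate plus one decoy; one homology reference annotates the second
  enzyme with its true substrate.
* Signal knobs are exchangeable at zero: with `docking_signal = 0` the
  true-pair shift vanishes identically; with `sea_signal = 0` true pairs
  draw from the background distribution; with `transform_fidelity = 0`
  every planted step product is a random decoy and every transform a
  random motif. This is what makes the null-signal control a fair
  exchangeability test.

With default signals the planted pathway is constructed to be the global
optimum, and on instances small enough to enumerate this is verified
exhaustively at generation time. What passing planted-recovery tests
shows — and what it does not: the generator emulates the *statistical
structure* of the real inputs (per-screen Z structure of docking, E-value
scales, exact-vs-noisy chemistry), not their physics. Real docking scores
are not Gaussian, real metabolite libraries are KEGG-scale (the pool here
is desk-scale by design, with a size knob), and real reaction annotations
are incomplete. Recovery here demonstrates that the integration machinery
works; it cannot certify accuracy on any particular real system.

## Numerical choices and degenerate inputs

* Population (ddof = 0) standard deviations throughout: every
  normalization population is a complete reference population, not a
  sample.
* Zero-spread populations yield Z = 0 with a warning at the user-facing
  `zscore()`; compiled tables apply the same guard silently per row
  (an uninformative row is legitimate, e.g. a substrate matching no
  motif).
* A pathway with no scored docking pair has its docking term *absent*,
  not zero-by-division; likewise SEA with fewer than two consecutive
  non-dummy proteins, and screening/homology terms whose protein is not
  in the model.
* Ties in model ranking and cluster representatives break
  lexicographically by canonical key, making every reported ordering
  deterministic.
* Candidate-library construction treats "similarity above 0.75" as
  strict, and expands transformations for a single round (products of
  products are not expanded).
* The exhaustive enumerator refuses instances beyond a configurable
  ceiling (default $10^7$) rather than silently running for hours.

## Known limitations

* Scoring treats restraints as independent evidence; correlated sources
  (e.g. docking and screening hits against the same site) are summed
  without reweighting.
* The transformation term takes the *maximum* over an enzyme's transforms
  and product sites, which rewards any consistent reaction but cannot
  distinguish which of several annotated activities is used.
* Ensembles quantify sampling precision, not posterior probability; the
  score is not a calibrated likelihood.
* The chemistry backend runs in a Python subprocess; problem compilation
  batches all of it into a handful of calls, but per-molecule latency
  makes single-fingerprint calls (as in interactive exploration) slower
  than bulk use.
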