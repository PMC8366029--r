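---
title: "Binding-site trees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site trees: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pockettree)
```

## The model

A binding-site tree (also called a binding-cavity similarity tree) is a
tree built with phylogenetic tooling from only the substrate-binding-pocket
residue columns of a protein family alignment. The underlying assumption is
that substrate specificity is governed mostly by the residues lining the
catalytic and binding cavities — typically one to two dozen positions —
while the rest of the chain carries fold-level evolutionary signal that is
irrelevant, and often misleading, for substrate classification. The tree is
therefore explicitly **not** an estimate of evolutionary history: active
sites with similar specificity can and do arise independently in distant
lineages, and one lineage can diversify its specificity cheaply. The tree
is a hypothesis-generation device: sequences co-clustering with annotated
enzymes are predicted to share their substrate preference.

The workflow in this package:

1. *Pocket derivation.* In a ligand-bound structure, a residue belongs to
   the pocket when at least one of its heavy atoms lies within a cutoff
   (default 5 Å, Euclidean between atom centers) of at least one ligand
   heavy atom. Hydrogens are excluded on both sides: published contact
   criteria are heavy-atom based and crystallographic hydrogens are mostly
   absent anyway. Literature-reported positions can be merged in with
   provenance `"literature"`.
2. *Designation.* Author residue numbers are mapped through the chain's
   resolved-residue order to dense sequence indices, and through the
   reference row's gap pattern to alignment columns.
3. *Extraction.* The reduced alignment keeps only designated columns. Swap
   groups handle loops where structurally equivalent residues occur in a
   different sequential order in different subfamilies: each subfamily tag
   declares a permutation of the swap columns, applied at extraction so the
   structurally equivalent residues share a reduced column. Swaps are
   declared in the seed configuration, never inferred: identifying them
   requires structure superposition and manual curation, which is outside
   this package's scope.
4. *Trees.* Distances on the profile, then classic neighbor joining.
5. *Classification and specificity statistics* (below).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `cutoff_A` | 5 | Å | conventional ligand-contact distance; pocket sets are monotone in it |
| distance `model` | `poisson` | substitutions/site | corrects multiple hits; `p` available for raw mismatch fractions |
| `gap_rule` | `pairwise_deletion` | — | complete deletion is too destructive on 19–21 column profiles |
| `max_distance` | 5.0 | substitutions/site | cap where `p >= 1` makes `-ln(1-p)` undefined; saturated pairs are warned about |
| `gap_open`, `gap_extend` | 11, 1 | score units | standard affine-gap magnitudes for protein alignment; a gap of length L costs `open + extend * L` |
| profile `pseudocount` | 0.1 | counts | Laplace smoothing of column frequencies before log-odds against a uniform 1/20 background |
| `k` (prediction) | 1 | neighbours | nearest-neighbour transfer mirrors reading the nearest annotated branch |
| promiscuous EC set | `1.1.1.1`, `1.1.1.-` | — | broad-specificity alcohol dehydrogenase codes; configurable per family |
| `n_perm` | 1000 | permutations | Z-score resolution ~0.03; runtime is seconds on a 21-column profile |
| `z_threshold` | −3 | σ | conventional candidate cutoff; flag sets are monotone in it |

## Numerical and convention choices

* **Harmony score.** The published Sequence Harmony tool quantifies the
  overlap of two per-column residue distributions (1 identical, 0
  disjoint). Its exact formula is not reproduced here; the score is
  realized as `1 - JSD(pA, pB)` (Jensen–Shannon divergence, base 2), which
  satisfies the same contract — bounded [0, 1], symmetric, continuous, 1
  iff equal, 0 iff disjoint supports — and is what the tests assert.
  Numeric agreement with the external server is therefore not promised,
  only directional and threshold behaviour.
* **Z-score sign.** Low harmony means strong separation, so candidates are
  flagged at *negative* Z (`z < -3`), matching the convention of reporting
  specificity-determining positions as Z < −3. A position whose permuted
  harmony is constant (`sd = 0`) gets `z = 0` and is never flagged.
* **Gap symbol.** Gaps participate as a 21st symbol in group profiles and
  relief distances: a gap in a pocket column can itself be a specificity
  signal. No pseudocount is used in group profiles so exact disjointness
  remains detectable.
* **Two-sample logo.** Enrichment per position/residue is tested with a
  two-sided Fisher exact test (valid at the small group sizes typical of
  annotated subfamilies, unlike t or binomial approximations); no
  multiple-testing correction by default, Bonferroni optional.
* **Residue volumes.** The embedded side-chain volume table follows the
  compilation conventional in the field, with the methionine/leucine pair
  as quoted in the workflow this package implements (M 166.7 Å³,
  L 162.9 Å³). Note that some printed volume tables interchange these two
  values; the interpretive claim — M and L are nearly isovolumetric but
  differently shaped — is unaffected.
* **Neighbor joining.** Classic Q-criterion agglomeration, ties broken
  toward the lowest index pair; negative intermediate branch lengths are
  clamped to zero with the deficit moved to the sibling edge, preserving
  the joined pair's path length. On additive matrices the input distances
  are reproduced exactly (tested to 1e-9). BioNJ is available via `ape`.
  Maximum-likelihood tree search (as used by desktop phylogenetics suites
  on these profiles) is deliberately out of scope: the binding-site-tree
  idea is distance-agnostic, NJ/BioNJ are the standard starting trees for
  those searches anyway, and reported log-likelihoods or Gamma shape
  parameters of ML runs are not reproduced here.
* **Bootstrap.** None by default: on a 19–21 column alignment resampling
  columns is uninformative. (This is also why `class_clustering` reports
  block counts and purities instead of support values.)
* **Altloc handling.** Highest occupancy wins, ties toward altloc `A` —
  the deterministic version of common practice.
* **Promiscuity.** A sequence votes in label propagation only when it
  carries exactly one EC number outside the promiscuous set; multi-EC or
  broad-code entries are reported but never vote.
* **Monophyly blocks.** Block counts are computed on the unrooted tree
  (the tree is re-rooted at a leaf outside the class before maximal pure
  subtrees are counted), so a class whose complement is a single clade
  counts as one block regardless of drawing orientation. Promiscuous
  leaves are ignored by default — they neither break nor join blocks.

## Label propagation

Default propagation uses pocket distances directly (k-nearest-neighbour
vote), not tree-branch membership: NJ topologies on very short profiles
can be unstable, while the underlying distances are not. Ties are resolved
deterministically (smaller mean distance, then lexicographically smallest
neighbour id) and reported. A tree-clade reading — assign the dominant
class of the smallest annotated enclosing clade — corresponds to how a
coloured tree is read by eye and can be emulated with `class_clustering`
plus the tree, but the distance route is the default because it is
reproducible under topology jitter.

## The synthetic world

`simulate_families()` generates the conditions the analysis assumes: a
superfamily of `n_families = 3` subfamilies × `seqs_per_family = 20`
sequences over one shared background consensus, with a planted residue
signature at 6 of the 21 pocket columns (distinct residue per family per
signature column), signature conservation `1 - within_rate = 0.95`, and
background mutation rate 0.2 per non-signature site. The 21-column profile
width matches a typical substrate-binding-pocket profile; the
150-column background stands in for the full-length alignment (real
two-domain dehydrogenase alignments run to a few hundred columns; 150 is
enough for background signal to dominate full-length distances while
keeping test runtime low). Residues are drawn uniformly over the 20 amino
acids — the simplest null that exercises every consumer; no indel process
and no tree-structured substitution is simulated.

Consequences for interpretation: a green simulation test establishes that
the pipeline recovers planted pocket signal and that pocket-only columns
outperform full-length columns when background noise is high
(`benchmark_pocket_vs_full`, background rate 0.45). It does **not**
establish performance on real families, where signatures are not
independent across columns, composition is biased, and alignment error
exists. Those limits are inherent to any desk-scale benchmark.

`make_toy_structure()` builds ligand-bearing toy structures as 3-atom
residue stubs on a spherical spiral around a 4-atom het group: pocket
members place an atom inside the cutoff, all other residues sit more than
2 Å beyond it. Only distances matter to the consumers, so no attempt is
made at stereochemical realism. The packaged reference stand-in
(`synthetic_reference_structure`) reuses this generator with the published
author numbering of a reference pocket (e.g. the 19-position ABL pocket of
the AOx reference), so the distance criterion can be validated against the
published list without a structure download; it is labelled synthetic
because its coordinates are unrelated to the real crystal structure.

## Degenerate inputs and edge behaviour

* An empty pocket (ligand too far from every residue) is an error ("no
  pocket found"), not an empty definition: a pocket definition is
  non-empty by construction.
* Pairs with zero jointly non-gap columns make the distance undefined and
  raise an error naming the pair.
* Saturated pairs (`p` near 1 on a short profile) are capped at
  `max_distance` with a warning listing them.
* Waters never count as ligands or pocket residues; metals and other het
  groups inside the cutoff are reported as context, not positions.
* The profile aligner breaks score ties deterministically (match over
  column-gap over insertion, leftmost placement), so identical inputs give
  byte-identical outputs.

## Scope decisions

Construction of the curated seed alignment itself — de-novo multiple
alignment, structure superposition, manual curation — is out of scope; the
package consumes a frozen seed and preserves it (profile alignment reports
insertions relative to the seed instead of opening new columns, matching
seed-preserving profile-alignment semantics). Database retrieval
(UniProt/NCBI/PDB fetches, BLAST/HMM searches) is likewise out of scope:
inputs are local files. Thermophile (or any other) organism tags are
user-supplied annotations, not inferred. Sequence-length admission bounds
(default 250–600 residues, the two-domain dehydrogenase window) are an
optional pre-filter, `filter_by_length()`.
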