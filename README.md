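# pockettree

Binding-site trees for functional classification of large enzyme families.

## The problem

Superfamilies such as zinc-dependent alcohol dehydrogenases (ADHs,
EC 1.1.1.\*), long-chain alcohol oxidases (AOxs) or amine dehydrogenases
(AmDHs) hold hundreds of thousands of sequences but only a few hundred
members with experimentally characterized substrates. Selecting candidate
enzymes (and candidate mutation sites) for engineering toward a new
substrate from such a pool is impractical with full-length phylogenetics:
substrate specificity is determined largely by the one-to-two dozen
residues lining the substrate binding pocket, not by the whole chain.

`pockettree` implements the *binding site tree* workflow around that
observation:

1. **Pocket derivation** — parse a ligand-bound structure (PDB format) and
   collect every residue with a heavy atom within a cutoff *d* (default
   5 Å) of a ligand heavy atom: `parse_pdb()`, `select_ligand()`,
   `pocket_residues()`.
2. **Column designation** — map those residue numbers through the
   structure's author numbering onto the columns of a frozen, curated seed
   alignment, including *swap groups* for loops whose structurally
   equivalent residues appear in different sequential order in different
   subfamilies: `structure_to_sequence_map()`, `designate_pocket_columns()`,
   `swap_group()`.
3. **Profile extraction** — reduce the alignment to the designated pocket
   columns only (a 19-21 column "pocket profile"): `extract_pocket()`.
   New, unannotated sequences are added against the frozen seed with a
   profile aligner (`profile_align()`, affine gaps, log-odds scoring);
   the seed columns are never modified.
4. **Tree building** — pairwise distances on the profile (p-distance or
   Poisson correction `d = -ln(1 - p)`, pairwise deletion by default) and
   neighbor joining: `pairwise_distance()`, `nj_tree()`, Newick I/O.
5. **Annotation propagation** — EC/substrate labels spread to
   uncharacterized sequences by pocket-distance k-nearest-neighbour vote
   (`predict_labels()`), with broad-specificity or multi-EC entries
   treated as promiscuous (`classify_promiscuity()`); clustering quality
   is quantified per EC class (`class_clustering()`), and tagged
   neighbours (e.g. thermophiles) of a query are ranked
   (`nearest_tagged()`).
6. **Specificity-determining positions** — between two subfamilies, each
   pocket column gets a harmony score (1 − Jensen–Shannon divergence of
   the two residue distributions; 1 = identical usage, 0 = disjoint), a
   permutation Z-score against a group-label-shuffle null (candidates at
   Z < −3), relief-style nearest-hit/nearest-miss weights, and
   two-sample-logo Fisher-exact enrichments: `position_zscores()`,
   `relief_weights()`, `two_sample_logo()`, `residue_volume()`.

A synthetic-data module (`make_toy_structure()`, `simulate_families()`,
`benchmark_pocket_vs_full()`) generates toy ligand-bearing structures with
known pocket membership and simulated superfamilies with planted pocket
signatures, so the whole pipeline is testable offline with known ground
truth.

## Worked example

```r
library(pockettree)

## pocket derivation on the packaged AOx reference world (a synthetic
## stand-in structure realizing the published 19-position ABL pocket)
pdb    <- synthetic_reference_structure("AOx")
model  <- parse_pdb(pdb, id = "1NAA-synthetic")
pocket <- pocket_residues(model, select_ligand(model, "ABL"), cutoff_A = 5)
pocket
#> Pocket definition: 1NAA-synthetic chain A, ligand ABL, cutoff 5.0 A
#> 19 positions: 278, 279, 282, 297, 310, 312, 562, 563, 584, 586, 590,
#>               607, 609, 686, 687, 688, 689, 732, 733

## simulate a 3-family superfamily, extract the 21-column pocket profile,
## build the binding site tree and ask how well the families cluster
sim     <- simulate_families(family_sim_spec())   # 3 x 20 sequences, seed 42
profile <- family_pocket_profile(sim)
tree    <- nj_tree(pairwise_distance(profile, model = "poisson"))
labels  <- classify_promiscuity(sim$annotations)
class_clustering(tree, labels)
#>     class n_leaves n_blocks best_purity
#> 1 9.9.9.1       20        1           1
#> 2 9.9.9.2       20        1           1
#> 3 9.9.9.3       20        1           1
```

Every family is monophyletic on the binding-site tree (`n_blocks == 1`),
so pocket similarity alone recovers the substrate grouping.

```r
## specificity-determining positions between families 1 and 2
g1  <- names(sim$truth)[sim$truth == "family1"]
g2  <- names(sim$truth)[sim$truth == "family2"]
rep <- position_zscores(profile, g1, g2, n_perm = 1000, seed = 17)
subset(as.data.frame(rep), flagged)
#>    position harmony     z relief flagged
#> 1         1   0.000 -33.5  0.975    TRUE
#> 2         2   0.000 -33.5  0.975    TRUE
#> 5         5   0.000 -34.6  0.950    TRUE
#> 6         6   0.145 -32.2  0.950    TRUE
#> 11       11   0.000 -35.9  1.000    TRUE
#> 15       15   0.000 -24.1  0.875    TRUE
```

The six flagged columns (Z ≪ −3, harmony near 0, relief near 1) are
exactly the six planted signature positions of the simulation — the same
triage that, on real subfamilies, separates e.g. a methionine/leucine
preference (side-chain volumes `residue_volume("M")` = 166.7 Å³ vs
`residue_volume("L")` = 162.9 Å³) at a single pocket position.

Packaged pocket definitions transcribed from published position lists are
available via `packaged_pocket("AOx")` (19 positions, reference 1NAA,
ligand ABL) and `packaged_pocket("AmDH")` (20 positions, reference 1C1D).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pockettree", package = "pockettree"))')
Rscript $CLI pocket   --pdb structure.pdb --ligand ABL --cutoff 5.0 -o pocket.json
Rscript $CLI extract  --msa seed.fasta --config seed.json -o pocket.fasta
Rscript $CLI tree     --pocket pocket.fasta -o tree.nwk
Rscript $CLI classify --pocket pocket.fasta --ann ann.tsv --queries ids.txt
```

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch against the
installed package: it derives the 19-position pocket from the synthetic
reference structure, simulates the default superfamily from the given
seed, builds the binding-site tree, measures family clustering and
hold-one-out classification on pocket versus full-length columns, runs
the permutation specificity scan, and writes the target report as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
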