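---
title: "Ligand-based virtual screening with fingerprint data fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based virtual screening with fingerprint data fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsfuse)
```

## The problem

Ligand-based virtual screening asks a deliberately simple question: given a
handful of molecules known to bind a target, which members of a large
untested library look like them?  `vsfuse` implements the classic
similarity-search funnel around that question — library prefiltering,
2D fingerprint similarity with data fusion, retrospective enrichment
validation against property-matched decoys, and a simplified 3D
pharmacophore screen — with every stage exercisable on synthetic data, so
the statistical machinery can be tested end to end without any external
database.

The motivating application is inhibitor discovery for lactate
dehydrogenase A (LDHA), the enzyme that converts pyruvate to lactate and a
prominent oncology target, but nothing in the package is specific to one
target: the inputs are SMILES libraries, activity labels, and pharmacophore
hypotheses.

## Library prefiltering

`filter_druglike()` keeps lead-like compounds: molecular weight within
150–450 g/mol, computed logP ≤ 5, Lipinski hydrogen-bonding caps
(donors ≤ 5, acceptors ≤ 10) and Veber flexibility/polarity caps
(rotatable bonds ≤ 10, TPSA ≤ 140 Å²).  The weight window and the logP cap
are the lead-likeness choices of the screening protocol this package
follows; the Lipinski/Veber caps use their canonical literature values
since only the rule names, not numbers, are part of that protocol.  All
thresholds are arguments of `druglike_rules()`.

Failure attribution is exclusive and deterministic — each rejected
compound is charged to the *first* failing rule in the fixed order mw,
clogp, hbd, hba, rotb, tpsa — so `n_passed + sum(failures) +
n_failed_parse == n_input` holds exactly and reports are reproducible.

`filter_reactive()` removes compounds with reactive or assay-interfering
substructures.  The shipped list (`default_alerts()`) is a small,
documented stand-in covering the classic electrophiles (acyl and alkyl
halides, aldehydes, Michael-acceptor enones, isocyanates,
epoxides/aziridines, quinones, azo compounds, anhydrides, peroxides);
production screens of vendor libraries should pass a complete REOS/PAINS
SMARTS collection through the `alerts` argument.

Descriptor calculation is delegated to Open Babel: logP is the
Wildman–Crippen atom-contribution estimator, hydrogen-bond acceptors are
the Lipinski N+O count, and rotatable bonds are counted with the standard
SMARTS pattern (non-ring single bonds between non-terminal heavy atoms,
triple-bond neighbours excluded).  The estimator identity matters for
reproducibility, so it is fixed and named here rather than configurable.

## The four 2D fingerprints

Similarity is always the Tanimoto index |A∩B|/|A∪B| over binary ("bit"
scaled) fingerprints.  Two empty fingerprints score 0 by convention: an
empty molecule carries no evidence of similarity.  Four complementary
fingerprint schemes are implemented:

* **MACCS structural keys** (`fp_maccs()`): the public 166-key set; key
  *k* is on when its SMARTS pattern has more unique matches than the key's
  count threshold.  Key 1 (isotope) has no SMARTS form and is never set;
  key 125 (more than one aromatic ring) and key 166 (more than one
  fragment) are computed from the molecular graph.  Pattern matching runs
  on Open Babel's SMARTS engine; the test suite pins the resulting key
  sets against an independent implementation of the same public
  definitions.

* **Radial** (`fp_radial()`): circular environments grown for
  `iterations = 2` rounds (the ECFP4-equivalent community standard; the
  parameter is exposed) around every heavy atom.  Atoms are typed by the
  daylight scheme — atomic number, valence, formal charge, hydrogen
  connections, heavy-atom connections.  Environment codes are built
  iteratively (each round hashes the centre's previous code with the
  sorted multiset of bond-token/neighbour-code pairs), which makes them
  canonical by construction.  A code is emitted only while the
  neighbourhood is still growing, so a lone atom contributes exactly one
  bit.

* **Dendritic** (`fp_dendritic()`): every fragment that is a simple path
  or a tree with exactly one branching vertex, up to five bonds.  "One
  branching vertex" is this package's reading of growth "in linear and
  branched directions"; the bond cap is configurable.  Paths are
  serialised in both directions and the lexicographic minimum is hashed;
  branch fragments serialise as the centre token plus the sorted list of
  leg strings.

* **MOLPRINT2D** (`fp_molprint2d()`): one environment per heavy atom — the
  centre's SYBYL atom type plus the sorted multiset of (graph distance
  1 or 2, SYBYL type) of its neighbours.  SYBYL types come from the MOL2
  conversion of each structure.

All hashed schemes map canonical fragment strings into the 2³² bit space
with FNV-1a (`fnv1a32()`), a published 32-bit hash pinned for bit-exact
reproducibility, and store only the on-bits; collisions are accepted, as
usual for bit fingerprints.  Fingerprints are invariant under atom
renumbering (a property the suite tests over hundreds of random
permutations), and bit-level compatibility with any proprietary
implementation is explicitly *not* a goal — enrichment statistics, not bit
identities, are the interface.

## Similarity fusion and the three screening methods

`similarity_search()` produces the full score table: one Tanimoto score
per (query, measure, library compound).  Two fusion reductions are
provided: `fuse_max()` (the best single score) and `fuse_sum()` (the plain
unnormalised sum; ranking by SUM equals ranking by the mean whenever every
compound fuses the same number of scores, a property the tests check).

* **Method A** ranks by each raw (query, measure) column separately.
* **Method B** (*similarity fusion*) fuses the measures per query.
* **Method C** (*group fusion*) fuses the queries per measure.

With 28 actives and four fingerprints these yield 112, 56 and 8 rankings.
Ties are broken by lexicographic compound id after the score.  Tie
handling is load-bearing: fused score tables contain large tie blocks, and
a different (e.g. random) policy would change enrichment factors at tight
cuts.  Determinism was chosen over optimism, and rankings are therefore
permutation-stable — shuffling the library input changes no (score, rank)
pair.

A corollary of group fusion worth knowing: any query active that is also a
member of the screened library reaches a MAX-fused score of exactly 1
through self-similarity, which is why intra-dataset validation of method C
always front-loads the query actives themselves.

## Enrichment metrics

`enrichment_factor()` implements
EF(x) = (hits in top *n*/*n*) / (N_act/N) with *n* = round(x·N), rounded
half away from zero with a floor of one.  That rounding rule is the only
one consistent with the printed values of the validation table this
package reproduces (12, 60 and 120 compounds at 1, 5 and 10% of 1198);
compounds are taken strictly by rank at the cut, with the global tie
policy deciding boundary ties — no fractional attribution.

One caveat is built into `screen_metrics()` rather than papered over: a
published table this package validates against contains two
similarity-fusion entries (14.2 at 1% with 5 retrieved actives; 8.5 at 5%
with 8) that are mutually inconsistent with the EF formula that reproduces
every other entry (the formula gives 17.8 and 5.7).  The implementation
does not tune its rounding to match them; reports carry the formula
values.

`roc_auc()` builds the stepwise ROC over all cut positions; its AUC equals
the Mann–Whitney statistic (fraction of active–decoy pairs where the
active ranks higher), which the tests verify by brute-force pair counting
for every ranking up to N = 50.  `bedroc()` implements the
Truchon–Bailey early-recognition score: the exponentially weighted sum
over active ranks, scaled to the robust initial enhancement and min–max
normalised to [0, 1].  At the default α = 20, 80% of the score comes from
the top 8% of the ranking — `bedroc_weight_fraction(20, 0.08)` evaluates
the closed form (1−e^(−1.6))/(1−e^(−20)) ≈ 0.80 — and as α → 0 BEDROC
approaches AUC-like behaviour.

## Actives, clusters and decoys

`cluster_actives()` performs agglomerative average-linkage clustering on
Tanimoto distance (1 − similarity), by default under MOLPRINT2D, cut at a
merge-height threshold.  The cut height is a required, explicit parameter:
published cluster counts generally do not determine whether a distance cut
or a fixed cluster count produced them, so nothing is inferred.
`select_representatives()` keeps up to three compounds per cluster — the
most potent first, then greedy MaxMin diversity — mirroring how
retrospective validation sets are typically assembled.

`generate_decoys()` builds DUD-E-style property-matched decoys: a
candidate is eligible for an active when all five property deltas
(MW ± 25 Da, clogP ± 1, donors/acceptors/rotatable bonds ± 1) are within
tolerance *and* its fingerprint Tanimoto to **every** active stays at or
below the 0.35 ceiling.  The matched property list comes from the
screening protocol; the tolerance values are this package's defaults in
line with common decoy-generation practice, and all of them are config
arguments of `decoy_spec()`.  Decoys are assigned per active between the
conventional 4 and 36 decoys/ligand bounds, and shortfalls are reported,
never silently padded.

## Pharmacophore screening

A hypothesis is 4–10 typed features (donor D, acceptor A, hydrophobe H,
aromatic ring R, positive/negative ionizable P/N) with tolerance spheres
and a minimum inter-feature distance of 2.97 Å.  Feature perception is
rule-based on the molecular graph (rules documented in
`?perceive_features`); rings sit at their centroid, hydrophobic carbon
groups at theirs, donors and acceptors on the heavy atom.

Conformers come from seeded distance-geometry embedding followed by
MMFF94 minimisation, with at most 255 conformers per molecule inside a
20 kcal/mol window of the per-molecule minimum — the caps mirror the
common FAST-style conformational analysis settings.  The proprietary
algorithm behind those settings is not reproducible, so the package uses
the seeded RDKit ETKDG/MMFF pipeline (shipped as a helper script) as its
deterministic stand-in; an earlier force-field route through Open Babel
was rejected because its minimiser is not reproducible across processes.

Matching is an exhaustive backtracking search over injective,
kind-compatible assignments of hypothesis features to perceived features,
pruned by pairwise distances (|d_ij(mol) − d_ij(hyp)| ≤ tol_i + tol_j).
Every surviving assignment is superposed by least-squares rigid alignment
(Kabsch); a conformer is a hit when every assigned feature lies inside its
tolerance sphere, and the fit value is the RMS residual, used only to rank
hits.  The tests hold the pruned search to exact agreement with an
unpruned brute-force enumeration, and to invariance under rigid motion of
the conformer.  `hypothesis_from_reference()` builds single-conformer
hypotheses (default tolerance 1.6 Å); common-feature alignment across
multiple actives is out of scope.

## What the synthetic benchmark emulates — and what it does not

`make_benchmark()` generates the study conditions this package is
organised around: 28 actives and 1170 decoys (1198 compounds), so methods
A/B/C emit exactly 112/56/8 rankings.  Actives are substituted variants of
one shared scaffold (an N-phenyl aminobenzoic acid, in the spirit of
carboxylate-bearing LDHA inhibitor chemotypes), decorated from a fixed
substituent vocabulary (methyl, halogens, hydroxyl, methoxy, amino,
carboxyl) and kept only if every pair stays above a radial-Tanimoto floor
of 0.4 — a moderate scaffold-series cohesion chosen once as realistic for
a congeneric series.  Decoys are drawn from twelve topologically unrelated
template families, kept only when property-matched to at least one active
and at or below the 0.35 similarity ceiling to all of them.  Both
constraints are re-verified post hoc by direct pairwise computation —
the generator's own bookkeeping is not trusted.  Synthetic potencies are
pIC50 values drawn uniformly on 5–8 (IC50 log-uniform between 10 nM and
10 µM, the potency range typical of screening actives).  The default
decoy count reproduces the validation-set *shape* (1170/28 ≈ 42
decoys/ligand); ratio-driven generation via `decoy_ratio` enforces the
conventional 4–36 window instead.

What passing tests on this benchmark show is that the statistical
machinery — fingerprints, fusion, EF/ROC/BEDROC, decoy eligibility — is
implemented correctly and that a planted similarity signal is recovered.
What they cannot show is performance on real chemistry: synthetic actives
are cleanly congeneric, decoys come from a small template grammar rather
than a 15-million-compound vendor library, and there is no activity cliff,
no tautomer/protonation ambiguity, and no assay noise.  Enrichment values
on the synthetic benchmark are therefore ceilings, not forecasts.

`make_planted_ranking()` bypasses chemistry entirely and plants labels at
known positions (top-block, uniform, or exponentially front-loaded), which
gives closed-form expectations: a top-block ranking has
EF(x) = min(N_act, n)/n · N/N_act and AUC = 1; uniform placement has
expected EF = 1.  `make_planted_pharmacophore()` does the same for the 3D
matcher: actives carry the hypothesis geometry plus Gaussian noise in a
random rigid frame, decoys carry scrambled geometry.

## Numerical choices and degenerate inputs

* Top-fraction counts round half away from zero (floor 1); R's default
  banker's rounding would give 119 at 10% of 1198 and break the worked
  values.
* Ranking ties: score descending, then compound id; applied identically
  everywhere a ranking is materialised.
* Tanimoto of two empty bit sets is 0 (documented convention).
* Clustering merges at exactly the threshold height are included in the
  cluster (`cutree(h = threshold)` semantics); exact merge-height ties
  follow `hclust`'s deterministic policy.
* Unparseable library entries are skipped and counted, never fatal;
  structures whose format conversions disagree on the atom sequence are
  treated as unparseable rather than silently mis-annotated.
* All generators save and restore the caller's RNG state; every stochastic
  entry point takes an explicit seed.
* Pipeline stages are content-addressed (FNV hash of parameters and input
  hashes): unchanged inputs are skipped with cached outputs, and reruns
  with the same config and seed give byte-identical summaries.

## Problem sizes used by the test suite

The suite validates the full 1198-compound benchmark (28 actives, four
fingerprint measures) once for the ranking-count contract and decoy
verification, and uses reduced instances elsewhere: a 6-active/40-decoy
benchmark for fusion and preparation tests, 5-active/30-decoy benchmarks
across a dozen seeds for the rank-separation property, 200+ random
rankings for the null-model EF average, and toy geometries for the
matcher-versus-oracle equivalence.  These sizes were chosen so the whole
suite exercises every code path at full statistical fidelity while
remaining comfortably runnable on a laptop.

## Known limitations

* The alert list is a stand-in, not a REOS/PAINS transcription; the
  Lipinski acceptor definition (N+O count) differs from SMARTS-based
  acceptor definitions on some heterocycles.
* Fingerprints are not bit-compatible with Canvas or any other proprietary
  implementation; only statistical behaviour is comparable.
* Formal charges are read from the structure as written; no
  protonation-state or tautomer enumeration is performed.
* Feature perception is a documented rule set, not a force-field or
  trained model; P/N perception in particular covers common
  amine/carboxylate chemistry only.
* Receptor-based hypothesis derivation, excluded volumes, docking and
  downstream physics (hydration-site analysis, MD, MM-GBSA) are out of
  scope.
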