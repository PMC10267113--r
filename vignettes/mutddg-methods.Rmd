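---
title: "Methods: deriving and modelling mutation-induced binding free-energy changes"
author: "mutddg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and modelling mutation-induced binding free-energy changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutddg)
```

# The model

Point mutations in a drug-target protein can weaken inhibitor binding and
cause drug resistance. `mutddg` quantifies this as a binding free-energy
change

$$\Delta\Delta G \;=\; R\,T\,\ln\frac{\mathrm{IC50}_{\mathrm{mut}}}{\mathrm{IC50}_{\mathrm{wt}}}$$

in kcal mol^-1, using the mutant/wild-type IC50 ratio from cell-line
drug-sensitivity screens as a proxy for the inhibition-constant ratio.
The approximation is standard: under the Cheng-Prusoff relation the IC50
ratio between two cell contexts assayed with the same drug and comparable
substrate conditions tracks the $K_i$ ratio, and the logarithm converts
it into an energy difference.

Constants and defaults:

* `GAS_CONSTANT_KCAL` = 1.9872e-3 kcal mol^-1 K^-1.
* Default temperature `T` = 298.15 K. At this temperature a 10-fold IC50
  ratio gives $\Delta\Delta G$ = `r round(computeDdg(10, 1), 2)`
  kcal mol^-1; at 300 K the same ratio gives
  `r round(computeDdg(10, 1, temperature = 300), 1)` kcal mol^-1. The
  assay temperature of a screen is rarely reported precisely, so we fix
  298.15 K (standard state) as the default and expose `temperature` as an
  argument everywhere the conversion happens.
* `RESISTANCE_THRESHOLD` = 1.36 kcal mol^-1: a sample is labelled
  resistant when its $\Delta\Delta G$ is **strictly greater** than the
  threshold, i.e. when binding drops by more than 10-fold.

`computeDdg()` is antisymmetric under swapping its arguments and additive
over chained ratios; both properties are enforced by the test suite.

# Mutation strings

`parseMutation()` accepts comma-separated, HGVS-protein-style strings:
substitutions (`V600E`), deletions (`A123del`, `E746_A750del`),
insertions between adjacent flanking residues (`A123_G124insFQE`), and
indels (`T123delinsAG`, `D580_P585delinsW`). Multi-residue deletion and
indel tokens name only the flanking wild-type residues; interior residues
are stored as `X` (unknown). A one-residue `delins` whose replacement is
one residue is normalized to a substitution.

The event set is classified six ways: `single_substitution`,
`multiple_substitution`, `deletion`, `insertion`, `indel`, and `complex`
(any mixture of kinds, or two or more non-substitution events).
`formatMutation()` serializes events in position-sorted order; this
canonical string is the key used to merge cell lines carrying the same
genotype and to deduplicate samples.

# Curation of screen tables

`curateSamples()` consumes three tables (drug sensitivity with replicate
IC50s in micromolar, cell-line mutation records, drug-target map) and
emits one sample per (target protein, drug, canonical mutation) bucket:

1. For each drug, cell lines mutated in two or more of the drug's known
   targets are discarded (`targetExclusivityFilter()`): the IC50 shift
   cannot be attributed to one protein.
2. Per target, the remaining cell lines split into wild-type controls (no
   recorded mutation on the target) and mutant buckets keyed by the
   canonical merged mutation string. Cell lines whose only recorded
   mutations fail to parse are excluded from both sides: they are not
   demonstrably wild-type.
3. Replicate IC50s are averaged per cell line, then across cell lines per
   bucket. The default averaging is **arithmetic in linear concentration
   space**; `averaging = "geometric"` is available and is the natural
   choice when ln-IC50 noise is believed to be symmetric. For noise-free
   inputs the two agree exactly.
4. $\Delta\Delta G$ and the resistance label follow from the bucket
   ratio.

Every sensitivity record is accounted for in the returned `log`
(emitted, no targets, multi-target discard, unparseable, no wild-type
control, no mutant bucket), so exclusions are auditable.

`coresetDedup()` keeps one sample per triple, preferring structure
sources in the order cocrystal > pymol_mutated > alphafold_folded >
docked > none, with ties broken by first-seen order. The priority order
encodes decreasing experimental fidelity of the complex geometry; ties
must be broken deterministically for reproducibility.

For predicted structures, `plddtFilter()` accepts a model only when its
mean per-residue pLDDT is strictly above 70 and no mutated site falls in
a poorly predicted region (pLDDT below 50). `alignmentResidueMask()`
returns the residues with pLDDT above 70 in both the wild-type and mutant
models (mutated sites excluded) as the positions a superposition engine
should fit on.

# Features

All features follow one convention: **ligand descriptors are absolute**
(the drug does not change when the protein mutates) and **every other
block is mutant minus wild-type** (`featureDelta()`).

* **18 ligand descriptors** (`ligandDescriptors()`): logP, molecular
  weight, H-bond acceptors/donors, TPSA and molar refractivity from Open
  Babel; rotatable bonds, ring counts, aromatic rings, heavy atoms,
  fraction of sp3 carbons, net formal charge, halogen and N/O/S counts,
  stereocenters and largest-ring size from the molecular graph.
  Standardization strips salt fragments (largest connected fragment by
  heavy atoms) and neutralizes charges that an implicit-hydrogen
  adjustment can balance; quaternary ammonium centers keep their charge.
  Stereocenters are *potential* stereocenters found by iterative
  neighborhood-label refinement (a tetravalent carbon with four
  distinguishable substituents), not a full CIP assignment — the cheaper
  invariant is stable across input formats that lack stereo annotations.
* **12 amino-acid-change features** (`aaChangeFeatures()`): deltas of
  hydropathy (Kyte-Doolittle), side-chain heavy atoms, side-chain volume
  (Zamyatnin), monoisotopic residue mass, formal charge at pH 7, side
  chain H-bond donors/acceptors, aromatic and polar flags, flexibility
  (Bhaskaran-Ponnuswamy), isoelectric point, and a sulfur flag. The
  block is antisymmetric by construction.
* **21 environment features** (`environmentFeatures()`): protein heavy
  atoms within 4/6/8/12 Å of the site point, ligand heavy atoms within
  4/6/8 Å, minimum and centroid ligand distances, 6-Å neighbor residues
  per property group plus total, a buriedness proxy (8-Å count per
  sphere volume), backbone vs side-chain and polar vs apolar neighbor
  atoms at 6 Å, and aromatic residues at 6 Å. The site point is the
  side-chain centroid of the mutated residue (C-alpha for glycine); the
  site's own atoms are excluded. Multi-site mutations are averaged over
  sites. Apo structures use a 99.0 Å sentinel for ligand distances and
  zero ligand counts.
* **6 interaction counts** (`interactionProfile()`), by geometric rules
  on heavy atoms only (hydrogen positions are typically absent from
  predicted models): hydrogen bonds (donor-acceptor heavy atoms ≤ 3.5 Å),
  hydrophobic contacts (apolar C-C ≤ 4.0 Å), salt bridges (opposite
  charge-group centroids ≤ 5.5 Å), pi-stacking (ring centroids ≤ 5.5 Å,
  interplanar angle ≤ 30° or 60-90°), cation-pi (cation to ring centroid
  ≤ 6.0 Å), halogen bonds (C-bound Cl/Br/I to acceptor ≤ 3.5 Å). The
  cutoffs are conventional mid-range values from the structural-biology
  literature; all are deterministic so counts are exactly reproducible.

External feature providers (for example scoring-function terms) attach
through `pluginFeatures()`: any callable returning a consistently named
numeric vector per complex is differenced mt − wt and appended as the
`plugin` block. `sampleFeatures()` assembles the full 57-feature native
vector.

# Benchmark harness

`runBenchmark()` evaluates estimators under three train/test scenarios
(`buildScenario()`), with the TKI-tagged samples always forming the test
set: (1) train on platinum-tagged samples from non-tyrosine-kinase
proteins; (2) train on all platinum-tagged samples; (3) train on all
non-TKI single-substitution samples. Train and test are forced disjoint
on (protein, drug, mutation) triples. Metrics are RMSE, Pearson r, and
AUPRC computed as non-interpolated average precision of ranking the
resistant labels by predicted $\Delta\Delta G$; each estimator runs 5
repetitions (seeds 0-4 by default) and the report carries means,
standard deviations, per-repetition values and scatter data. A failing
estimator is recorded with `NA` metrics without aborting the run.

Ten estimator slots ship in `builtinEstimators()`: decision tree, random
forest, extremely randomized trees, support-vector regression, elastic
net, lasso, bootstrap-aggregated trees, AdaBoost.R2, gradient boosting,
and a single-hidden-layer perceptron on standardized inputs.

# Synthetic data

Because real screen corpora cannot ship with the package, validation
rests on synthetic data with known ground truth:

* `genScreen()` inverts the $\Delta\Delta G$ relation:
  $\ln \mathrm{IC50} = \ln \mathrm{base} + [\mathrm{mutant}] \cdot
  \Delta\Delta G/(RT) + \mathcal{N}(0, \sigma)$. With $\sigma = 0$
  curation must recover every planted value exactly (the acceptance suite
  requires ≤ 1e-9); with $\sigma = 0.3$ and 32 mutant plus 32 control
  cell lines the per-sample error is exactly
  $RT\,(\bar\varepsilon_{\mathrm{mut}} - \bar\varepsilon_{\mathrm{wt}})
  \sim \mathcal{N}(0, RT\,\sigma\sqrt{2/32})$ under geometric averaging,
  giving an analytic bound the Monte-Carlo tests check against. The
  sizes (200 screens, 32 cell lines) keep the bound tight (expected mean
  absolute error ≈ 0.035 kcal mol^-1) while running in about a minute.
* `genToyComplex()` realizes complexes with **exact geometry**: the
  mutated residue's side-chain centroid sits at the origin and lone-CA
  shell atoms are placed at prescribed distances, so intended shell
  counts hold by construction and every geometric feature can be checked
  against an independent brute-force distance scan (the test suite does
  this on 100 random complexes).
* `genFeatureTable()` produces feature matrices with a planted linear
  signal and scenario tags, so harness metrics have known targets (an
  oracle estimator must score RMSE 0 / Pearson 1 / AUPRC 1; random
  scores must average to the resistant prevalence).

All generators take explicit seeds, restore the caller's RNG state, and
are bitwise reproducible.

# Numerical and design choices

* Strict inequalities at the quality gates (mean pLDDT > 70, resistant
  when $\Delta\Delta G$ > 1.36) make boundary behaviour unambiguous.
* IC50 values must be strictly positive and finite; malformed rows are
  soft-rejected with reasons at I/O time, never silently dropped.
* Sample tables serialize $\Delta\Delta G$ at 4 decimal places
  (10^-4 kcal mol^-1 is far below assay noise) with a schema-version
  header; feature tables carry a sidecar schema naming each feature's
  block and delta semantics.
* Pearson correlation of a zero-variance prediction is reported as 0
  with a warning (a constant baseline should score poorly, not crash);
  AUPRC with no positive labels is an error, since it is undefined.
* The environment block's wider-shell feature uses a 12-Å protein-atom
  count; together with the 8-Å count and the sphere-volume buriedness
  proxy it captures both local packing and the broader burial of the
  site.

# Limitations

* The IC50 route measures cellular, not biophysical, binding changes;
  transport, efflux and pathway effects are absorbed into
  $\Delta\Delta G$.
* Interaction counts use heavy-atom geometry with fixed cutoffs; no
  hydrogen placement or energy model is attempted.
* The ligand descriptor panel requires a molecule with at least one bond
  (descriptor backends cannot type single atoms); single-atom species
  still parse and pose.
* Stereocenter counting is a graph invariant, not a CIP assignment, and
  does not detect meso compounds or stereo centers depending on
  double-bond geometry.
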