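---
title: "Methods: structure-based amyloidogenicity prediction by steric-zipper threading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based amyloidogenicity prediction by steric-zipper threading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Short peptide fragments (roughly 4-10 residues) nucleate amyloid formation
of longer proteins.  Their aggregated state is the steric zipper: two tightly
packed beta sheets whose side chains interdigitate.  Sawaya-style symmetry
arguments admit ten packing classes -- strands within a sheet parallel or
antiparallel, sheets packed face-to-face or face-to-back, strands running
up-up or up-down -- of which seven have been confirmed crystallographically.

`zipthread` asks the structural question directly: *how well does a query
peptide fit each zipper class?*  The pipeline is

1. **Template library.** One idealized two-sheet assembly per confirmed
   class, built from ideal beta-strand geometry and the class's symmetry
   operation (`build_template()`, `template_library()`).
2. **Threading.** The query sequence is grafted onto every template; ten
   stochastic decoys per class are scored with a distance-dependent
   statistical potential, and the global minimum-score model is kept
   (`generate_decoys()`).
3. **Energy features.** The best model is decomposed into fourteen features:
   the statistical-potential score, a weighted total, and twelve component
   terms (van der Waals attraction/repulsion, intra-residue repulsion,
   screened electrostatics, desolvation terms, and backbone/side-chain
   statistics terms) (`compute_energy_terms()`).
4. **Classification.** Interpretable classifiers (L1 logistic regression by
   default; SVMs and a random forest for comparison) separate amyloid from
   non-amyloid on z-scored features (`train_classifier()`, `run_train()`).
5. **Interpretation.** Coefficients, forest importances and a Boruta
   all-relevant selector rank the features; the class of the lowest-energy
   model is reported as the peptide's most probable zipper class
   (`lr_coefficients()`, `boruta_select()`, `predict_zipper_class()`).

## Idealized templates instead of crystal structures

The package is fully self-contained: templates are constructed from ideal
geometry rather than downloaded crystals.  An importer
(`import_template()`) accepts experimental PDB files, strips non-protein
content, clusters chains into two sheets and pads each sheet to six strands
by translated copies -- but nothing in the default pipeline requires it.

Construction constants (all exposed in `geometry_params()`):

* backbone torsions phi = -120, psi = +120, omega = 180 degrees (ideal
  extended strand);
* inter-strand stacking 4.8 Angstrom along the fibril axis -- the canonical
  cross-beta repeat;
* inter-sheet separation 8.5 Angstrom -- a typical dry-interface distance
  between zipper sheets;
* standard backbone bond lengths and angles (N-CA 1.458, CA-C 1.525,
  C-N 1.329, C=O 1.231 Angstrom).

Antiparallel stacking rotates every second strand 180 degrees about the
sheet normal through its centroid; the second sheet is produced by the
class's face/orientation operation (a 180-degree rotation about the fibril
axis for face-to-face packing, an additional 180-degree rotation about the
normal for up-down orientation) followed by the inter-sheet translation.
Strand centroids therefore stack at exactly the configured spacing for
every class, while per-atom displacements between adjacent antiparallel
strands additionally reflect the backbone pleat -- the geometry tests
check the former for all classes and the exact per-CA translation for
parallel classes.  The unconfirmed classes 3, 9 and 10 are carried in the
catalog with documented placeholder operations (9 and 10 add a half-period
stagger of the second sheet) and are excluded from the default library.

Side chains are reduced to the beta carbon plus a single centroid
pseudo-atom placed along the CA->CB direction at a residue-specific
distance (2.4 Angstrom for alanine up to 5.9 for arginine).  This captures
packing and clash signal without a rotamer library; glycine carries neither
atom.  The class-4 reference sequence is an octapeptide; when a template is
built at a shorter length the native sequence is truncated from the
N-terminus, and padded with alanine when longer -- an arbitrary, documented
rule.

## Decoys and the statistical potential

The reference modeling protocol produces ten optimized models per class and
keeps the lowest statistical-potential score.  Full restraint-based
optimization is out of scope here; the package preserves the
"ten models, keep the best" semantics with cheap seeded perturbations:
decoy 0 is the unperturbed graft, and each further decoy jitters every
side-chain centroid (Gaussian, sigma 0.3 Angstrom per coordinate) and
applies a small rigid motion to the second sheet's centroids (rotation
uniform in +/-5 degrees about the fibril axis, translation uniform in
+/-0.5 Angstrom along the sheet normal).  Backbone atoms never move, so
every decoy superposes on its template exactly -- the perturbation explores
side-chain packing, which is where the reduced representation carries its
signal.  Ties are broken deterministically (lower class id, then lower
decoy index).  Per-decoy random streams derive from one master seed as
`seed + 1000 * class_id + decoy_index`, so a single integer reproduces an
entire run.

The scoring function is a trainable distance-dependent pair potential over
40 atom types (20 residues x {backbone, centroid}), binned at 0.5 Angstrom
to a 15 Angstrom cutoff, with counts from all inter-chain pairs and
intra-chain pairs at sequence separation >= 2.  Scores are
`-ln(p_obs / p_ref)` with an `r^2` reference state.  Smoothing adds a
reference-shaped prior with weight 1 (`pseudocount`); formulating the
pseudocount as a prior *weight* rather than an additive count makes the
table exactly invariant under duplication of the training corpus, which is
the natural consistency requirement for a frequency-ratio potential.  The
default table is trained on the seven idealized templates threaded with
their native sequences -- deterministic and dependency-free; users may
retrain on any structure collection (`train_pair_potential()`).

## The energy decomposition

All terms operate on the reduced atom set and are documented analogs of the
familiar Rosetta-style terms, not numerical reproductions.  Pairwise terms
count atom pairs four or more bonds apart (three or more within a residue
for the intra-residue repulsion; the intra-residue desolvation term keeps
the four-bond crossover its name implies).  Constants live in
`term_params()`:

* **fa_atr / fa_rep** -- the attractive (r >= r_min, smoothly switched to
  zero between 4.5 and 6 Angstrom) and repulsive (r < r_min) branches of a
  12-6 Lennard-Jones potential; the split point belongs to the attractive
  branch, so at exactly r_min the pair contributes -epsilon and zero
  repulsion.
* **fa_elec** -- Coulomb with distance-dependent dielectric
  epsilon(r) = 10 r, counted between 1.45 and 5.5 Angstrom, shifted to zero
  at the outer cutoff and held constant below the inner one.
* **fa_sol / fa_intra_sol_xover4** -- Lazaridis-Karplus-style Gaussian
  exclusion with lambda = 3.5 Angstrom; polar atoms carry positive
  desolvation free energies (burial penalized), apolar ones small negative
  values.
* **lk_ball_wtd** -- the same desolvation for polar centroids, weighted by
  the cosine of the angle between the centroid's polar direction (CB ->
  centroid) and the neighbor direction, floored at zero.
* **omega** -- a 2.0 energy/rad^2 spring on the peptide-bond torsion with
  minima at both 180 (trans) and 0 (cis) degrees.
* **rama_prepro, p_aa_pp, fa_dun** -- negative log probabilities from
  binned tables: Ramachandran mixtures over a 10-degree grid for
  general/glycine/proline residue classes with a pre-proline variant;
  P(residue | phi,psi bin) tilted by beta propensity; and a 12-bin
  side-chain direction table in the residue's backbone frame.  The tables
  are generated procedurally from documented analytic basins -- a shipped
  full-resolution P(aa | phi,psi) table would be several hundred kilobytes
  of text for no gain in fidelity, and the procedural construction is
  bit-reproducible.  Every table row normalizes to one, and the torsion
  grid is centered so canonical torsions (e.g. -120/+120) fall mid-bin,
  never on an edge.
* **ref** -- per-residue reference constants, i.e. a pure composition term.
* **ref15_like_total** -- the weighted sum of the twelve components with a
  documented weight vector.

The 14-feature vector order is fixed and exported
(`energy_feature_names()`).

## Classifiers and evaluation

Features are z-scored with training-set statistics only (stored inside the
trained model, so prediction on raw features is safe).  Backend settings
are frozen: L1 logistic regression at penalty C = 1 (glmnet,
lambda = 1/n); SVMs at cost 1 with linear, cubic-polynomial and RBF
kernels; a random forest of 100 trees with maximum depth 4.  The installed
forest backend (ranger) does not offer a cross-entropy split criterion, so
Gini impurity -- its closest available analog -- is used.  Splits and
cross-validation are stratified (five folds by default): with a 244:836
class imbalance an unstratified split can starve a fold of positives.
Metrics are AUC (midrank over ties), sensitivity, specificity, accuracy
and MCC at a probability threshold of 0.5, with percentile 95% confidence
intervals from 1000 seeded stratified bootstrap resamples.  On 1080
records a 70% split takes round(0.7 * 1080) = 756 training and 324 test
records -- the arithmetic consequence of the fraction, which is what
`split_dataset()` implements.

Boruta follows the original algorithm: per iteration, every feature gains
a shuffled shadow copy, a forest is fitted, a z-score of each real
feature's importance against the shadow importances is recorded, and a hit
is counted when the feature beats the best shadow.  A two-sided binomial
test against p = 0.5 with Bonferroni correction (alpha = 0.05 over the
feature count) decides confirmed/rejected after 100 iterations by
default; undecided features stay tentative.

Structural-class prediction reports the class of the global
minimum-energy model with ties to the lower class id, and its evaluation
emits both the exact-match count and per-class one-vs-all accuracy
together with per-class recall, because "one vs all accuracy" is ambiguous
for classes with few true members.

## What the synthetic generator does and does not emulate

`generate_peptides()` reproduces the *statistical shape* of experimental
hexapeptide collections: a 244:836 positive:negative imbalance and a
composition bias of positives toward high beta-propensity hydrophobic
residues (V, I, F, L, Y, T), implemented as an exponential tilt
`exp(+/- effect_size * propensity)` of the residue distribution.  At
`effect_size = 0` the two classes are draws from the same distribution; at
the default 1.0 the composition contrast is strong enough that the full
pipeline separates the classes well.  The generator does **not** imitate
real sequence motifs, positional patterns, or experimental label noise --
a pipeline that passes the synthetic recovery tests is shown to propagate
composition signal faithfully through threading, energies and
classification, not to reproduce published benchmark performance on
experimental databases, which would require the external data themselves.

## Numerical choices and degenerate inputs

* Coordinates are PDB fixed-column with three decimals; structure
  round-trips are exact at that precision.
* Alternate locations other than blank/'A' are dropped on read; waters,
  ions and ligands are removed by `strip_nonprotein()`, which errors on an
  all-hetero input and is idempotent.
* Sheet assignment of imported crystals projects chain centroids onto
  principal axes and cuts at the largest relative gap; a degenerate
  (single-sheet or collinear) arrangement has no dominant gap and raises an
  error rather than guessing.
* Lennard-Jones distances are clamped below 0.2 Angstrom so scores stay
  finite on pathological input; the r^-12 branch amplifies coordinate
  round-off, so rigid-motion invariance holds to about 1e-6 in relative
  terms rather than machine precision.
* Constant features z-score to zero (with a warning) instead of dividing
  by zero.
* A query whose length differs from 6 triggers template construction at
  that length (4-10 supported), which is how pentapeptide queries are
  handled.

## Problem sizes

The shipped tests and the acceptance script exercise the pipeline end to
end at 400 synthetic peptides (70 decoys each, one CPU, a few minutes),
with 50-iteration Boruta runs and 200-1000 bootstrap resamples -- sizes
chosen so a full validation cycle stays interactive on a laptop while every
statistical check retains power.  The same code paths scale linearly in
the number of sequences.

## Known limitations

* The reduced side-chain representation cannot resolve rotamer-level
  packing; class discrimination rests on backbone symmetry and centroid
  packing only.
* The energy terms are analogs with documented constants, not calibrated
  force-field reproductions; absolute magnitudes are meaningful only
  relative to one another within this package.
* The default pair potential is trained on seven idealized structures;
  it is deliberately self-contained, and users with access to curated
  zipper crystals should retrain it.
* Class assignment for real peptides is intrinsically hard (structural
  polymorphism, scarce annotated crystals); the package reports the
  minimum-energy class as a hypothesis, not a determination.
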