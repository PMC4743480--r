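---
title: "Methods: classification structure-property models for Pgp-interacting compounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classification structure-property models for Pgp-interacting compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

P-glycoprotein (Pgp) is an ATP-binding-cassette efflux transporter that
pumps structurally diverse compounds out of cells. Whether a drug
candidate inhibits Pgp, is transported by it, or neither, shapes its
pharmacokinetics and its potential for drug-drug interactions, so both
endpoints are screened early in discovery. Experimental assays for these
endpoints disagree often enough that computational classifiers built on
interpretable molecular descriptors are a useful complement. `pgpcspr`
implements such a classification structure-property relationship (CSPR)
workflow as two independent binary tasks — inhibitor vs non-inhibitor and
substrate vs non-substrate — with the emphasis on models a medicinal
chemist can read: decision trees whose splits are physical thresholds
(e.g. an acceptor-count or molecular-weight cutoff), backed by
neural-network and support-vector baselines.

The pipeline runs in four stages: (1) dataset curation, (2) descriptor
computation and collinearity pruning, (3) imbalance correction by fuzzy
C-means (FCM) cluster selection, (4) model building and four-metric
validation.

# Curation

Input records are (SMILES, class label) pairs with optional identifiers.
Rules are applied in a fixed order, and every removal is logged with its
reason:

1. **unparseable** — the SMILES does not parse;
2. **overweight** — average-mass molecular weight above 1000 Da
   (configurable); very heavy compounds sit outside the applicability
   domain of small-molecule descriptors;
3. **duplicate** — same canonical SMILES under the same label; the first
   occurrence in input order is kept, which makes a run deterministic for
   a fixed input file (the census is invariant to input order, the kept
   representative is not);
4. **overlapping** — the same canonical SMILES under two distinct labels
   is discarded under *every* label, including cross-task conflicts
   (inhibitor + substrate). Conflicting annotations are treated as
   unresolvable rather than adjudicated.

Canonicalization is delegated to Open Babel and applied as-is: no
tautomer or charge normalization, and multi-fragment (salt) SMILES are
kept verbatim but flagged, since stripping counter-ions would silently
change descriptor values. The census reports one count per endpoint class
plus the total, so inconsistent upstream counts remain detectable instead
of being silently reconciled.

# Descriptors

Seven interpretable 2D descriptors are computed per compound:

| descriptor | definition | units |
|---|---|---|
| MW | average-atomic-mass molecular weight, implicit H included | Da |
| RBN | single acyclic bonds between two non-terminal heavy atoms, amide C–N excluded | count |
| nCIC | cyclomatic number of the heavy-atom graph | count |
| nHDon | hydrogen atoms bonded to N or O | count |
| nHAcc | N, O and F atoms | count |
| ALogP | atomic-contribution octanol-water partition coefficient | — |
| TPSA | Ertl fragment-contribution polar surface area | Å² |

The integer descriptors follow the classical atom-count conventions of
descriptor packages in this field; in particular nHAcc is a plain
N/O/F-atom count, which is what makes integer split thresholds such as
"nHAcc > 4" meaningful in the extracted rules. RBN, nCIC, nHDon and
nHAcc are computed in-package from the explicit-hydrogen molecular graph;
MW, ALogP and TPSA come from Open Babel's atomic-contribution
implementations. For ALogP this is the Wildman–Crippen (1999)
parameterisation of the Ghose–Crippen contribution scheme; the test
suite cross-checks it against an independent implementation (RDKit) of
the same scheme and the two agree to well under 0.01 log unit on
carbon/oxygen frameworks and aromatic nitrogens, while amine/amide N–H
atom typing is a known divergence point between the two
parameterisations — the fixtures document this rather than hide it.

Six quantum-chemical descriptors (mean absolute partial charge, total
energy, dipole moment, HOMO, LUMO, HOMO–LUMO gap) are supported as an
*ingest-only* block merged by compound id from an external
electronic-structure calculation. No quantum chemistry is run
internally; if the gap column is absent it is computed as LUMO − HOMO,
and if present it must agree with that difference within 10⁻³ eV.

# Feature selection

The Pearson intercorrelation matrix is computed over all rows of the
combined (positive + negative) table, and features are pruned greedily:
scanning columns left to right, each surviving column removes every later
column with |r| at or above the cutoff (default 0.7). The absolute value
is used because an anti-correlated feature carries the same information
as a correlated one. The greedy left-to-right rule is a deterministic
refinement of "one of the pair is discarded": which member survives is
defined by column order, never by row order. Constant columns get zero
correlations (with a warning) rather than NaN, and missing values are an
error — the descriptor stage guarantees completeness, so a missing value
upstream is a bug, not something to pairwise-delete around.

# Imbalance correction by FCM cluster selection

Both Pgp tasks are imbalanced toward the positive class (ratios of about
1.5:1 and 7.6:1). The pipeline undersamples the positive class by
clustering it and keeping the best-behaved cluster:

1. `k = max(2, ceiling(n_pos / n_neg))` clusters, so each cluster is
   comparable in size to the negative class. The ratio-based rule
   reproduces plausible selected-cluster sizes for both task geometries
   (k = 2 at 1341:913, k = 8 at 197:26).
2. FCM is run on z-scored features with fuzzifier m = 2, tolerance 10⁻⁶
   on the objective change, 300-iteration cap, and 5 random restarts
   keeping the lowest final objective. FCM is initialization-sensitive;
   restarts from a seeded random membership matrix are the standard
   remedy. A point coincident with a center takes membership 1 there
   (the update-rule limit).
3. Each crisp cluster is joined with all negatives, a decision tree is
   trained on the union and scored by stratified 10-fold cross-validated
   MCC (leave-one-out when a cluster has fewer than 10 members). MCC is
   the selection metric because it is the one statistic of the four that
   is balanced under class imbalance; ties fall back to accuracy, then
   cluster size, then the lower cluster id. Cross-validated rather than
   training performance is used so that a cluster of mislabelled
   look-alikes cannot win by being easy to memorize.

The selected cluster plus all negatives form the balanced table. This is
undersampling only; no synthetic oversampling is provided.

# Models

**Decision tree** (authored in this package): binary numeric splits,
candidate thresholds at midpoints between adjacent distinct sorted values
where the class composition changes, scored by information gain ratio.
Ties break toward the lower column index, then the lower threshold, and
values equal to a threshold go left (so "greater than the cutoff" is
always the right branch, matching how the extracted rules read). Growth
stops at purity or when a child would drop below `min_leaf` (default 2);
zero-gain splits are permitted during growth — this is what lets the
inducer solve XOR-like interactions — and are subsequently collapsed by
pessimistic-error pruning at confidence 0.25 (the customary C4.5
setting; the upper error bound is the binomial upper confidence limit,
`U(0, N) = 1 - CF^(1/N)` in the zero-error case). Each leaf yields one
if-then rule; the rule list is mutually exclusive, exhaustive, and
round-trips through its text rendering.

**MLP and SVM** delegate to `nnet` and `e1071` behind the same
train/predict contract, with hyperparameters chosen by 10-fold
cross-validated MCC over a configurable grid. The MLP grid uses one
hidden layer with sizes {(features + classes)/2, features}, 500 epochs,
and weight decay {0.3, 0.1} — decay is the regularization knob of the
BFGS-trained `nnet`, standing in for the learning-rate axis that
online-backpropagation implementations expose. The SVM grid covers RBF
(C ∈ {0.1, 1, 10, 100} × γ ∈ {0.01, 0.1, 1}) and linear kernels. Both
standardize features; the tree does not, since its splits are
scale-invariant.

# Validation

Four statistics are computed from the pooled confusion matrix: accuracy,
sensitivity and specificity as percentages, and MCC. A zero factor in
the MCC denominator defines MCC = 0; an empty positive or negative
margin makes sensitivity or specificity undefined (reported missing with
a warning, not silently zeroed). Cross-validation uses stratified folds
and pools predictions into a single confusion matrix before computing
metrics — well-defined even when single folds are tiny, unlike per-fold
averaging.

The external split holds out 15 % per class. Plain random splits can
under-represent the tails of the chemical space, so the split is
PCA-guided: per class, features are z-scored, projected on the first
principal component, PC1 is binned into up to 10 equal-frequency strata,
and the test quota is sampled uniformly within each stratum (largest
remainder allocation keeps sizes exact: per class
`|train| = floor(0.85 n + 0.5)`). Classes with fewer than 7 rows fall
back to a plain seeded split, logged. This stratified-PC1 procedure is a
documented stand-in for "PCA-based random sampling", which is commonly
named but rarely specified; it preserves the intent (representative
coverage) and exact 85/15 sizes under one fixed rounding rule.

# Synthetic data

The generator emulates the statistical structure the pipeline assumes so
every stage is testable without any external download. Design choices,
fixed once:

* **delta** is the per-feature difference between class means in
  pooled-SD units, applied to every base feature. delta = 0 is the null
  case (no signal); delta = 3 is strong separation. Note a side effect
  faithful to real descriptor tables: strong per-feature class
  separation induces between-feature correlation (≈ δ²/4 / (δ²/4 + 1),
  i.e. ~0.69 at δ = 3), so collinearity-pruning behaviour should be
  studied at moderate delta where planted pairs are the only
  collinearity.
* **Planted collinear pairs** are exact blends
  `y = r·x_std + sqrt(1 − r²)·ε`, appended as the last columns; the
  ground-truth sidecar names them, so tests can assert that exactly the
  planted later columns are pruned.
* **Column scales** mimic descriptor ranges (an MW-like column, four
  integer count-like columns rounded and clipped at zero, the rest
  standardized), keeping the integer-type invariants of real descriptor
  vectors exercisable.
* **Imbalanced scenarios** place negatives at the origin and positive
  subpopulation s at s·delta per feature, so subpopulations are
  geometrically separated from the negatives and from each other; a
  subpopulation's label-noise rows are drawn at the origin (the negative
  distribution) while keeping the positive label. Exactly one
  subpopulation must be noise-free — it is the recoverable ground truth.
  The default weights (0.45 clean, 0.55 with 30 % label noise) make the
  clean subpopulation about 45 % of the positives, the selected-cluster
  fraction observed in the motivating inhibitor task (603 of 1341).
* All randomness flows from the spec seed through an isolated generator;
  nothing touches or depends on the caller's global RNG state.

What the generator does **not** emulate: real descriptor joint
distributions (they are Gaussian surrogates), discreteness artifacts of
chemistry, activity cliffs, or assay noise structure. Green tests
therefore demonstrate algorithmic correctness under the stated
statistical assumptions, not predictive performance on real Pgp data.

# Problem sizes and numerical conventions used by the test suite

The suite exercises the full inhibitor-task class geometry (1341:913) for
cluster selection, 500+ small instances (≤ 12 rows) for the
exhaustive-oracle tree check, 100 seeded tables for pruning recovery,
and 20 seeds each for the recovery-rate and null-MCC properties; these
sizes keep the full suite in the minutes range on a single core while
leaving each property statistically meaningful. Other conventions worth
knowing: correlation pruning applies to |r| with ≥ as the removal
comparison; FCM convergence is judged on |ΔJ|; the tree's tie tolerance
on gain ratio is 10⁻¹⁰; report JSON carries full-precision numbers while
rendered metric tables use fixed three decimals.

# Limitations

* Quantum descriptors are never computed; analyses involving them
  require an external electronic-structure engine.
* ALogP follows the Wildman–Crippen revision, not the original 1989
  Ghose–Crippen table, and amine/amide hydrogen typing differs between
  independent implementations of the family.
* The duplicate-retention rule keeps the first occurrence; two files
  with the same rows in different order keep different representatives
  (same census).
* Performance numbers on real Pgp datasets depend on the source data and
  are not reproduced by the synthetic conditions here.
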