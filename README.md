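# pgpcspr

Interpretable classification structure–property relationship (CSPR)
models for P-glycoprotein-interacting compounds.

P-glycoprotein (Pgp) is an efflux transporter central to multidrug
resistance and drug pharmacokinetics; screening compounds for Pgp
inhibition and transport is a standard early-ADMET task. `pgpcspr` is
aimed at cheminformaticians who want the whole workflow — from raw
SMILES lists to validated, human-readable classifiers — as tested R
functions:

* **Curation** — SMILES canonicalization, a 1000 Da molecular-weight
  filter, duplicate removal, and discarding of compounds annotated under
  more than one class, with a full removal log and per-class census.
* **Descriptors** — seven interpretable 2D descriptors (MW, RBN, nCIC,
  nHDon, nHAcc, ALogP, TPSA) computed from the molecular graph, plus an
  ingest-only block of six quantum-chemical descriptors merged by id.
* **Feature selection** — Pearson intercorrelation matrix and greedy
  removal of collinear descriptors at |r| ≥ 0.7.
* **Imbalance correction** — fuzzy C-means clustering of the majority
  class with `k = max(2, ceil(n_pos/n_neg))`; each cluster is scored by
  a cross-validated decision tree and the best-MCC cluster becomes the
  representative positive set.
* **Models** — a gain-ratio (C4.5-family) decision-tree inducer with
  pessimistic-error pruning and if-then rule extraction, written here,
  plus MLP (`nnet`) and SVM (`e1071`) learners behind one
  train/predict contract with seeded grid search.
* **Validation** — accuracy, sensitivity, specificity (%) and the
  Matthews correlation coefficient

  MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

  computed from pooled confusion matrices under stratified 10-fold
  cross-validation and a PCA-stratified 85/15 external split.
* **Synthetic data** — a seeded generator for descriptor-like tables
  with tunable class separation, planted collinear pairs and
  label-noise subpopulations, so the entire pipeline is testable with
  no external database.

## Worked example

Curate a small labelled compound list and compute descriptors:

```r
library(pgpcspr)

recs <- molecule_records(
  smiles = c("CCO", "OCC", "c1ccccc1", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"),
  labels = c("inhibitor", "inhibitor", "inhibitor", "non_inhibitor",
             "inhibitor"),
  ids    = paste0("m", 1:5))
cur <- curate(recs)
print(cur)
#> curated_dataset: 2 kept, 3 removed (MW limit 1000 Da)
#>     inhibitor non_inhibitor     substrate non_substrate         total
#>             2             0             0             0             2
#>   duplicate overlapping
#>           1           2
```

`OCC` is the same molecule as `CCO` under the same label (one removed as
a duplicate), and benzene appears as both inhibitor and non-inhibitor
(both copies discarded as overlapping). Descriptors for the two
survivors (ethanol and aspirin):

```r
ft <- build_feature_table(cur, positive = "inhibitor")
round(as.data.frame(ft)[, -(1:2)], 3)
#>        MW RBN nCIC nHDon nHAcc  ALogP  TPSA
#> 1  46.068   0    0     1     1 -0.001 20.23
#> 2 180.157   3    1     1     4  1.310 63.60
```

Balance a synthetic imbalanced task (1341 positives vs 913 negatives,
one label-consistent and one 30 %-label-noise subpopulation) and
cross-validate a tree on the balanced table:

```r
sc  <- generate_imbalanced_scenario(synthetic_spec(seed = 1))
sel <- select_representative_cluster(sc$positives, sc$negatives,
                                     fcm_config(seed = 1))
sel$evaluations
#>   cluster_id size accuracy sensitivity specificity       mcc      cv selected
#> 1          1  663 98.35025    98.19005    98.46659 0.9661706 10-fold     TRUE
#> 2          2  678 77.37272    60.91445    89.59474 0.5357653 10-fold    FALSE

kfold_cv(sel$balanced, learner_config("tree", seed = 1), k = 10, seed = 1)
#> accuracy 98.350 %  sensitivity 98.190 %  specificity 98.467 %  MCC 0.966
```

Cluster 1 is essentially the label-consistent subpopulation: models
built on it classify positives and negatives almost perfectly, while the
noisy cluster drags sensitivity down to 61 % — which is exactly why the
pipeline selects clusters by cross-validated MCC.

The whole pipeline (curation → descriptors → selection → balancing →
split → models → metrics) runs from one seeded config with
`run_pipeline(pipeline_config(...))`, or from a shell via the thin
wrapper `inst/scripts/pgpcspr` (subcommands `curate`, `describe`,
`select-features`, `balance`, `train`, `validate`, `simulate`,
`run-all`).

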