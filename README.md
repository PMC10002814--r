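# csfstrat

Stratifying asymptomatic Alzheimer's disease from CSF biomarker panels.

Alzheimer's disease (AD) pathology accumulates for one to two decades before
cognitive symptoms appear. Cognitively normal individuals whose cerebrospinal
fluid (CSF) already shows an AD-like biomarker profile — here called
**AsymAD**, operationalized as a tTau:Aβ42 ratio above a mixture-model-derived
cutoff — are the natural target population for prevention trials, but they are
heterogeneous: some will progress soon, many never will. `csfstrat` implements
an analysis pipeline that (i) derives biomarker cutoffs and gates a cohort
into CN/BM− (cognitively normal, biomarker-negative), AsymAD, and AD groups,
(ii) selects a compact peptide panel separating CN/BM− from AD, (iii) uses
that panel to place each AsymAD case on the Control↔AD continuum and
pseudo-label it *Control-like* or *AD-like*, and (iv) finds an independent
compact peptide set predictive of those subgroups. It is aimed at researchers
working with targeted CSF proteomics (SRM) panels alongside the classical
Elecsys analytes (Aβ42, tTau, pTau-181).

## Methods at a glance

- **Mixture-model cutoff** — a two-component Gaussian mixture
  `w₁·N(μ₁,σ₁²) + w₂·N(μ₂,σ₂²)` is fitted to an analyte ratio by EM
  (multiple restarts, variance floor); the decision cutoff is the
  equal-posterior point between the component means (the Bayes boundary of
  the fitted mixture). Ashman's D = |μ₁−μ₂| / √((σ₁²+σ₂²)/2) < 2 flags
  unimodal fits, which yield no cutoff. Gating is strict:
  positive ⇔ tTau:Aβ42 > cutoff (default 0.24).
- **Dual-classifier RFE** — recursive feature elimination (drop the feature
  with the smallest |coefficient|, refit, repeat) run independently under a
  linear SVM (C = 1) and L2 logistic regression, each stopped at 14 peptides;
  the reported panel is the intersection of the two selections. Selection and
  training use a stratified 80% split; all metrics (accuracy, precision,
  recall, ROC-AUC, confusion matrix) come from the untouched 20%.
- **Permutation null** — the panel's held-out metrics are compared with
  B (default 100,000) random same-size panels evaluated identically;
  empirical p = (1 + #{null ≥ observed}) / (B + 1).
- **t-SNE + KNN pseudo-labelling** — the panel's standardized log abundances
  for all subjects are embedded to 2-D by t-SNE; each AsymAD case takes the
  majority label of its k = 5 nearest CN/BM−/AD reference neighbours.
  Because t-SNE is seed-dependent, the embedding + vote is repeated
  (default 100×) with derived seeds; the fraction of AD votes is the
  assignment probability, with an explicit uncertainty band (0.4–0.6).
- **JMI selection** — greedy forward selection of 5 peptides under the joint
  mutual information criterion: the first feature maximizes I(X;Y), later
  candidates maximize Σ_{s∈S} I(X_cand, X_s; Y) over the selected set S,
  on equal-frequency discretized (5-bin) abundances; evaluated by held-out
  accuracy and 6-fold cross-validated ROC-AUC.
- **Cohort statistics** — median (quantile-0.5) regression of cognitive
  scores on standardized CSF analytes with seeded bootstrap inference,
  logistic regression on median-dichotomized sparse scores,
  Benjamini–Hochberg FDR (q = 0.20), Kendall tau-b peptide–cognition
  ranking, Youden-index ROC cutoffs, and matched-group tests (paired
  t / Wilcoxon signed-rank / McNemar–Bowker / Fisher exact).

Because real subject-level cohorts of this kind are not redistributable, the
package ships a synthetic-cohort generator (`cohort_spec()` /
`generate_cohort()`) with known ground truth — planted informative peptides,
a latent Control→AD position `u` for every AsymAD case, per-group APOE ε4
allele frequencies, and tau-linked visuospatial decline — so every stage can
be tested for recovery of what was planted.

## Worked example

```r
library(csfstrat)

cohort <- generate_cohort(cohort_spec(seed = 1))
labels <- gate_subjects(cohort$subjects)   # tTau:Abeta42 > 0.24
table(labels)
#>     AD AsymAD CN/BM-
#>    134    134    134

ref <- which(labels %in% c("CN/BM-", "AD"))
sel <- select_panel(cohort$peptides[ref, ], labels[ref], positive = "AD")
sel
#> Dual-RFE panel selection (stop size 14 per classifier)
#>   train/test: 214 / 54 subjects
#>   intersection panel (11 peptides): PEP003, PEP011, PEP019, PEP028, PEP036,
#>     PEP044, PEP053, PEP062, PEP070, PEP072, PEP075
#>   held-out: accuracy 0.981, precision 0.964, recall 1.000, AUC 1.000

qry <- which(labels == "AsymAD")
strat <- stability_stratify(cohort$peptides, sel$panel, ref, labels[ref],
                            qry, repeats = 20, ad_label = "AD", seed = 1)
strat
#> Stability stratification: 134 query subjects, 20 repeats, k = 5
#>   Control-like 73 | uncertain 6 | AD-like 55 (band 0.40-0.60)
```

The panel contains all 8 peptides the generator planted (`PEP003 … PEP062`)
plus three passengers; held-out AUC 1.000 reflects the planted 2-SD shifts.
The stratification splits the 134 AsymAD cases into Control-like and AD-like
subgroups with 6 cases left uncertain across embedding repeats. A JMI
selection on the non-uncertain subgroups then picks a compact predictive
subset:

```r
keep <- strat$assignments$final_label != "uncertain"
idx <- strat$assignments$query[keep]
jmi_select(log(cohort$peptides[idx, ]), strat$assignments$final_label[keep])
#> JMI forward selection (5 equal-frequency bins)
#>   1. PEP062       score 0.1564 nats
#>   2. PEP053       score 0.3688 nats
#>   ...
```

`run_pipeline(pipeline_config(...))` chains all six stages (synthesize/load →
gate → select → stratify → JMI → cohort statistics) and writes per-stage CSV/
JSON outputs plus a manifest recording every parameter and derived seed.

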