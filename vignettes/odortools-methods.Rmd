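---
title: "Methods: predicting aroma contribution and odor thresholds of volatiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting aroma contribution and odor thresholds of volatiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Untargeted volatilomics of a crop sample yields hundreds of detected
volatiles, but perception is governed by two properties most of them lack
annotations for: the **odor detection threshold** (ODT, the minimum
concentration at which the compound is reliably perceived in a stated
matrix) and the **aroma contribution** (whether the compound pushes the
overall aroma in a pleasant or unpleasant direction). Together they give the
odor activity value, OAV = concentration / threshold: a compound with
OAV > 1 is likely perceptually relevant even at low abundance. Measuring
either property by sensory panel is slow and costly, so odortools predicts
both from molecular structure and supplies the panel-side estimator used to
check predictions experimentally.

## Data model and curation

Compounds enter as names and/or SMILES. Names are resolved against a local
lookup table (never a web service), SMILES are canonicalized through
OpenBabel, and records are deduplicated by canonical SMILES with descriptor
union and threshold pooling. Stereochemistry present in the input is
retained (menthyl acetate is chiral; two spellings of the same achiral
molecule still collapse to one record).

Free-text odor descriptors are curated in three data-driven steps, all
encoded in an editable YAML configuration rather than code:

1. **synonym consolidation** (fruit, fruity → fruity),
2. **category mapping and merging** of sparse categories into broad groups
   (Dairy/Buttery into Sweet/Vanilla/Caramel; Rancid/Sweaty/Animalic and
   Chemical/Solvent/Plastic into Off-flavor),
3. **priority resolution**: when a compound's descriptors span several
   categories, the category earliest in a fixed priority order wins
   (Fruity outranks Green/Herbal), making the assignment a function of the
   descriptor *set*, not its order.

Contribution labels are a total function of the final category. The
packaged polarity map marks Fruity, Citrus, Floral, Sweet/Vanilla/Caramel,
Nutty/Roasted and Woody/Spicy positive, and Green/Herbal, Earthy/Musty,
Sulfurous, Off-flavor and Odorless negative. Two of these defaults deserve
comment. *Green/Herbal is negative* because the package's own worked
sensory example (menthyl acetate, described overwhelmingly as grassy) is a
negative contributor; users who target leafy-fresh product profiles can
flip one YAML line. *Odorless* is only ever assigned from an explicit
descriptor; an empty descriptor set leaves the record unlabeled and
excluded from training, because absence of annotation is not evidence of
absence of odor.

Thresholds are harmonized to mg/L and collapsed per compound by the
**median** of literature observations (robust to the order-of-magnitude
scatter typical of threshold compilations); a mean policy is available for
emulating averaged-duplicate workflows. The modeling target is
`y = -log10(t mg/L)`, so potent odorants sit high on the scale and the
target distribution over a diverse corpus is approximately normal.
Non-positive threshold entries are removed before collapsing.

## Featurization

Three fingerprint schemes are supported — ECFP4 and ECFP6 (circular
fingerprints of diameter 4 and 6, i.e. radius 2 and 3, folded to 1024
presence bits) and the 167 MACCS keys — each concatenated with a
physicochemical 4-vector: molecular weight, Crippen-type logP, topological
polar surface area and molar refractivity. Fingerprints and descriptors are
computed with OpenBabel, which emits 4096-bit ECFPs; these are OR-folded to
1024 bits (bit *i* maps to *i* mod 1024). Counts are folded to binary
presence, hydrogens are implicit, and featurization is a pure function of
the canonical molecule. The physchem block is standardized *inside* the
model pipeline using training-set statistics only; fingerprint bits are
never scaled.

For the graph family, molecules become heavy-atom graphs with one-hot
element, degree and aromaticity node features; the physchem vector is
concatenated at the readout rather than broadcast to nodes, which keeps
node features purely structural.

## Scaffold-aware splitting

Random splits overestimate generalization because structural analogues fall
on both sides. The package groups compounds by Bemis-Murcko scaffold (ring
systems plus linkers after iteratively pruning terminal atoms; acyclic
molecules share the empty scaffold) and assigns whole groups: groups are
visited largest first (ties broken by key), filling the training set up to
`(1 - f) N`; the first group that would overflow, and all groups after it,
go to validation. Rare scaffolds therefore land in validation — the harder,
more honest test — and the assignment is deterministic under row
permutation. The achieved validation fraction deviates from the target by
at most `(largest group - 1)/N`. All acyclic volatiles (esters, aldehydes,
alcohols — a large share of any flavor corpus) move as one indivisible
group; this coarseness is deliberate and surfaced in the split output so
users can see when the acyclic block dominates.

## Model harness

Four families are available: random forest (ranger), gradient-boosted trees
(xgboost), a two-hidden-layer multilayer perceptron, and a two-layer graph
convolutional network with mean pooling; the latter two are compact
implementations in base R matrix operations (Adam, ReLU, dropout, early
stopping on an inner 10% split). Hyperparameters are drawn uniformly from
fixed per-family domains (e.g. GBDT: 300/600/900 trees, depth 4/6/8,
learning rate 0.03/0.05/0.1, subsample 0.7/0.9/1.0, column subsample
0.6/0.8/1.0, L2 0/1/3) and scored by 5-fold cross-validation **on the
training set only**: stratified folds and fold-mean macro-F1 for
classification, plain folds and fold-mean R-squared with RMSE tie-break for
regression. The default of 30 draws per scheme-family pair balances search
coverage against desk-scale runtime and is configurable.

Class imbalance — positive contributors vastly outnumber negative ones in
descriptor corpora — is handled twice: the training majority class is
downsampled to at most 5000 instances (never the validation set), and
remaining skew is absorbed by inverse-frequency sample weights
`w_c = N/(K N_c)`, whose mean over samples is 1. Downsampling applies to
classification only; threshold corpora are small (hundreds of compounds)
and are never downsampled.

Validation reports are ranked lexicographically by macro-F1, then accuracy,
then macro-precision, then macro-recall (stable under full ties). The
binary decision cutoff is a probability of 0.5. The sklearn-style RF
controls `min_samples_split`/`min_samples_leaf` map to ranger's
`min.node.size`/`min.bucket`, the closest available semantics.

## Evaluation and conformal intervals

The classification bundle reports macro/weighted F1, accuracy,
macro-precision/recall, ROC-AUC (rank statistic), average precision (step
integration of the PR curve, so a constant score recovers the prevalence
baseline), Brier score, a 10-equal-width-bin calibration curve (empty bins
omitted) and row-normalized confusion matrices. Regression reports
R-squared and RMSE plus RMSE stratified by tertiles of the *true*
validation values (boundaries at the 1/3 and 2/3 quantiles, conservative
"higher" interpolation, upper boundary inclusive — points exactly at q2
belong to Mid).

Prediction uncertainty uses a residual-based split conformal band: the
half-width `q` is the empirical 95th-percentile (again the conservative
order statistic, `sorted[ceiling(0.95 n)]`) of absolute calibration
residuals, giving a multiplicative interval `[10^-(y+q), 10^-(y-q)]` mg/L
after back-transformation. The proper protocol — calibration and
evaluation residuals disjoint — is the default; computing coverage on the
same residuals that set `q` is supported as an explicit emulation mode
because published workflows sometimes report it, but it is flagged and
optimistic by roughly `1/n`.

## Sensory panel estimator

The panel side implements an ascending-series method of limits (modified
ASTM E679: single-bottle yes/no detection instead of 3-AFC, so the
geometric-mean best-estimate-threshold machinery of E679 deliberately does
not apply). The group threshold is the lowest tested nonzero concentration
at which at least 50% of the panel detects (at least 10 of 20); if the rule
is never met the estimate is right-censored above the top concentration.

Uncertainty comes from a non-parametric bootstrap over panelists: resample
the 20 assessors with replacement 10,000 times, recompute the group
threshold per replicate, and read the 2.5th/97.5th percentiles off the
ordered replicate values — the smallest replicate value whose empirical CDF
reaches the tail probability, i.e. lower-value assignment at probability
ties on the discrete dilution grid. Censored replicates sort above the
maximum tested concentration, and a bound landing there is reported as
"> max". Published tables give only marginal detection counts; per-panelist
profiles are reconstructed under the monotone assumption (a panelist who
detects at some concentration detects at all higher ones), which is exactly
the unique profile set consistent with non-decreasing counts. This
assumption is flagged in every estimate that uses it, since a raw detection
matrix could in principle be non-monotone.

## Synthetic data: what it emulates, what it does not

Every stage is testable offline through seeded generators:

* **Molecules** are built by template substitution — seven ring scaffolds
  (benzene, furan, thiophene, pyridine, cyclohexane, cyclopentane, a
  lactone) and three acyclic cores (ester, aldehyde, alcohol) crossed with
  small substituents — guaranteeing chemical validity, controllable
  scaffold multiplicity and a realistic acyclic contingent.
* **Labels** threshold a linear structure score (logP, MW, TPSA) at the
  quantile matching a target prevalence of 0.93 positive, the imbalance
  regime of real contribution corpora; flip noise degrades the signal
  continuously down to coin-flipping.
* **Thresholds** follow `y = beta . (1, MW, logP, TPSA, MR) + N(0, 0.4)`,
  giving means near 1.9 and SD near 1.2 on the -log10 mg/L scale — a few
  orders of magnitude of threshold variation, approximately normal. With
  the noise at 0 the target is an exact function of structure and serves as
  a parameter-recovery oracle (the GBDT regressor reaches held-out
  R-squared above 0.99 at n = 800).
* **Panels** draw each panelist's log-threshold from
  `N(log10 T, 1/slope)`, the cumulative-normal psychometric model with
  default slope 2 per log10 unit — monotone profiles by construction. The
  estimator never sees this model; it applies only the 50% rule.

Passing tests on these generators demonstrates the *machinery* — leak-free
splitting, calibrated metrics, conformal validity, bootstrap correctness —
not chemical realism: synthetic labels are far more linearly recoverable
than real odor perception, real threshold data carry matrix and
protocol heterogeneity the linear rule lacks, and the scaffold library is a
toy compared with a real corpus. Results on synthetic corpora are upper
bounds on the ease of the task, never evidence about real-data accuracy.

## Numerical choices and edge cases

* Quantiles (conformal `q`, tertile boundaries, bootstrap CI bounds) use
  the conservative empirical order statistic throughout, documented at each
  call site and configurable where it matters.
* Canonicalization failures are per-record data errors, never batch
  failures; every exclusion lands in a logged manifest.
* A single-atom molecule is a valid 1-node, 0-edge graph.
* Fewer than two scaffold groups, or a largest group exceeding the training
  budget, abort the split with explicit messages.
* Model artifacts round-trip bit-exactly through disk (xgboost boosters are
  serialized as raw bytes inside the artifact).
* Ties in ranking fall back to input order, making every ranking stable
  and reruns byte-identical.

## Problem sizes

The shipped tests and acceptance checks run at deliberately modest sizes —
corpora of 110-800 synthetic molecules, 10,000 bootstrap replicates,
20-seed Monte-Carlo loops — chosen so the full suite completes in a few
minutes on one CPU while still exercising every code path at the
statistical regime it targets (e.g. 800 molecules is enough for the
noiseless recovery bound; 10,000 replicates pins the discrete bootstrap
CI categories far from the 2.5/97.5 boundaries).

## Known limitations

* Name resolution is a local table; compounds outside it must be given as
  SMILES.
* The acyclic scaffold group is indivisible, so corpora dominated by
  acyclic volatiles have coarse split granularity.
* The multi-class category head is functional but inherits the residual
  imbalance of descriptor corpora; the binary contribution head is the
  recommended screening endpoint.
* Water-matrix thresholds transfer to real juice matrices only
  approximately; matrix effects are out of scope.
* The GCN family is a minimal reference implementation intended for
  methodological completeness, not a tuned deep-learning stack.
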