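---
title: "Predicting isoform-level function by multiple-instance learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting isoform-level function by multiple-instance learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomil)
```

## The problem and the model

Functional annotation databases such as the Gene Ontology label *genes*,
but transcription produces *isoforms*, and a gene's annotated function is
typically carried out by only some of its alternatively spliced products.
isomil treats this as a multiple-instance learning (MIL) problem over
isoform-level expression profiles:

* a **bag** is a gene; its **instances** are the gene's isoforms, each
  represented by a vector of log2 expression values across a panel of
  heterogeneous RNA-seq experiments;
* the **bag label** $y_i$ is observed: 1 if the gene is annotated to the
  function under study (after propagating annotations up the ontology's
  `is_a` hierarchy), 0 otherwise;
* the **instance labels** $y_{ij}$ are hidden, constrained so that every
  positive gene contains at least one functional "witness" isoform while
  no isoform of a negative gene is functional.

A linear soft-margin SVM plays the instance classifier. The joint problem —
maximize the margin over both the hyperplane and the admissible hidden
labelings — is a mixed-integer program, so it is approximated by the usual
alternating heuristic: fix the labels and solve the quadratic program; fix
the hyperplane and relabel the positive-bag instances from their decision
scores; repeat until the labeling reaches a fixed point or revisits an
earlier state (cycle detection). Two update families are implemented:

* **mi-SVM**: every isoform of a positive gene is relabeled POS/NEG by
  comparing its score against a threshold derived from the
  negative-instance score distribution — its mode, its 75th percentile
  (the default, `"p75"`), or its maximum, in increasing order of
  strictness — with an additional `"zero"` variant that cuts at the
  decision boundary itself (the generic "maximize the objective locally"
  update). If no isoform clears the threshold, the top-scoring isoform is
  forced positive, preserving the at-least-one-witness constraint; ties
  break to the lexicographically smallest isoform id for reproducibility.
* **MI-SVM**: exactly one witness (the argmax-scoring isoform, or a
  seeded-uniform draw under the random-witness baseline) is kept positive
  per positive gene and the remaining isoforms become NEUTRAL, excluded
  from the margin.

At the end, genes are scored by the maximum over their isoforms, under the
assumption that at least one isoform realizes an annotated function.

## Numerical choices inside the classifier

Three choices stabilize the alternating heuristic at the problem sizes a
single workstation handles (thousands of instances, ~100 expression
features); all are package design decisions, switchable through
`mil_config()`:

* **Column standardization** (always on). Missing expression is recorded
  as a sentinel of −15 on the log2 scale; without standardization those
  cells dominate the feature geometry and the quadratic solver converges
  poorly.
* **Profile centering** (`profile_centering`, default `TRUE`). Each
  instance is centered on its own mean over non-sentinel cells, so
  discrimination rests on the *pattern* of expression across conditions —
  the co-expression signal the method is built on — rather than on
  absolute abundance. Without it, the learned weight vector has a nonzero
  net sum, and each isoform's baseline abundance leaks into its score as a
  nuisance term.
* **Cross-fitted update scores** (`update_scoring = "crossfit"`, default).
  The dual solution scores every training instance with a term
  $\alpha_i K(x_i, x_i)$ contributed by its *own* current label. At these
  problem sizes that term is comparable to the spread of the negative
  scores, so in-sample update scoring locks in whatever labels the
  iteration started from — including the deliberately wrong all-positive
  initialization. The default update therefore scores each instance with
  fold models (gene-partitioned, 3 folds) that never saw the instance's
  gene. Fold models have incomparable decision-value scales, so each
  fold's scores are centered on that fold's own threshold and the update
  cuts at zero; the fold partition rotates every iteration and the update
  uses the running mean of the centered scores (excluding the
  first-iteration models, which are trained on the fully imputed labels),
  so both model noise and fold-assignment luck average out. If the
  labeling is still moving after `crossfit_iterations` (default 15)
  updates, the run falls back to literal in-sample updating, which
  reaches an exact fixed point quickly. `update_scoring = "insample"`
  reproduces the textbook loop.

Two further defaults depart from obvious alternatives, deliberately:

* **Class weighting is off.** At initialization roughly half of the
  positive-instance labels are wrong by construction. Up-weighting that
  small, label-noisy class (inverse-frequency weighting would give it
  ~20× weight) amplifies exactly the labels the iteration is supposed to
  correct; in our synthetic benchmarks it collapses witness specificity.
  `class_weighting = TRUE` restores inverse-frequency weighting.
* **The soft-margin cost is fixed at C = 1.** A per-term tuner
  (`tune_regularization()`, 3-fold inner CV on gene-level AUC over a small
  grid) is provided, but the default run does not invoke it: on
  standardized, profile-centered features the results are stable across
  an order of magnitude in C, and fixing it keeps every pipeline stage
  deterministic and cheap.

## Preprocessing contract

The expression table enters as FPKM from an upstream quantifier.
Experiments with fewer than 10 million reads or under 50% mapped reads are
removed (boundary values are kept); genes detected — any isoform with
FPKM > 0 — in fewer than half of the surviving experiments are dropped
with their isoforms; remaining values are log2-transformed with zero and
missing cells floored at the −15 sentinel. Zero FPKM is treated as
missing because quantifier output cannot distinguish "absent" from
"unobserved". The matrix carries an explicit space flag (`fpkm` / `log2`)
so a second transform is refused rather than silently applied.

## Gold standards, evaluation designs

Per-term gene standards are built by propagating annotations through
`is_a` edges (`part_of` optional, off by default; all evidence codes are
accepted), taking annotated genes as positives and the rest of the gene
universe as negatives. Terms are kept when their positive set falls in the
inclusive 20–300 window, and can be grouped into size quantiles (ties at
boundaries break by term id).

Performance estimation is always partitioned **by gene**, never by
isoform, so isoforms of one gene cannot straddle a train/test split. The
implemented designs mirror the standard repertoire: stratified k-fold
cross-validation (5-fold headline, 2-fold where test positives would
otherwise run out), a multi- versus single-isoform comparison in which
negatives are seeded-downsampled until both sub-problems share one
positive:negative ratio (hence one baseline precision), expression-level
tertiles (gene expression = mean of non-sentinel isoform cells;
sentinel-only genes sink to the low group), and a homolog-aware two-way
split that assigns whole homolog groups (largest first, seeded ties) to
the smaller side so homologous genes never inform each other's test
scores. Metrics: ROC AUC via the Mann–Whitney statistic (ties count ½),
AUPRC under the average-precision convention (rectangular, not
trapezoidal — do not mix the two when comparing), and precision at a
target recall using the smallest score-threshold set that achieves it,
with `ceiling` semantics for the required positive count. Cross-validated
reports pool held-out scores over folds; per-fold aggregation is available
from `crossval_scores()` directly.

## Final predictions: bagging, calibration, fold change

Final isoform scores come from the 0.632 bootstrap: genes are drawn with
replacement (all isoforms of a gene travel together), the MIL model is fit
on the drawn genes (each bootstrap round trains on the unique genes of the
draw — duplicating a gene would only duplicate hinge terms), out-of-bag
isoforms are scored, and after 30 rounds each isoform keeps the median of
its out-of-bag scores. Isoforms that were never out-of-bag — rare but
possible — are scored by one supplementary round that holds their genes
out, and flagged. Decision scores are mapped to probabilities by a
Platt-style sigmoid fitted on the final full-data labeling (a monotone
map, so rankings are unchanged), and each probability is reported also as
a fold change over the term's background prior, positives divided by the
gene-universe size. Isoforms of one gene routinely receive different
probabilities — that per-isoform resolution is the method's point.

## What the synthetic generator does and does not emulate

`generate_term_dataset()` plants ground truth so every stage is testable
offline: positive genes carry one witness isoform (or a configured
fraction) whose log2 profile is shifted by `effect_size` (default 2) in a
fixed random subset of `signature_dim` experiments (default 30 of 120);
all other isoforms are baseline noise with per-isoform baseline means
drawn from a Normal(3, 2) to mimic abundance heterogeneity; 5% of cells
are masked to the sentinel; defaults put 50 positive genes among 2050
(≈2.4% prevalence, the regime of mid-sized ontology terms scaled down),
with an isoform-count distribution massing 0.6 on single-isoform genes as
in annotated transcriptomes.

Two deliberate simplifications matter when reading test results. First,
non-witness isoforms of positive genes are statistically *exchangeable*
with negative-gene isoforms. Real non-functional isoforms share promoters
and partial sequence with their functional siblings and are thus easier
to confuse — so synthetic witness-specificity numbers are, if anything,
optimistic in structure but also bounded: under the p75 update a quarter
of exchangeable non-witnesses always sit above the threshold, capping
balanced witness-recovery accuracy at ≈0.87 even for a perfect
classifier. Second, cells go missing completely at random, whereas real
missingness tracks low expression; random masking of signature cells is
the main residual source of missed witnesses. Passing tests therefore
demonstrate that the machinery recovers planted structure under honest
noise, not that real-tissue accuracy reaches any particular level.

Problem sizes in the test-suite and acceptance runs were chosen as the
generator defaults for the headline checks (2050 genes × 120 experiments)
and reduced analogues (≈600–800 genes) for the bootstrap-agreement and
formulation-comparison checks, keeping a full run in minutes on one core.

## Known limitations

* The heuristic optimizes a non-convex objective; only on enumerably
  small problems is closeness to the global optimum verified (the
  local-objective `"zero"` update lands within 5% of the enumerated
  optimum on ≈98 of 100 random tiny problems; the distribution-threshold
  updates intentionally trade objective optimality for label recall).
* Linear kernel only; the expression panel is assumed informative enough
  that co-expression is linearly separable in standardized space.
* Calibration borrows the final full-data labeling; when a term's
  labeling is unstable, probabilities (not rankings) should be read with
  care.
* `part_of` propagation, homolog groups and per-round re-tuning of C are
  available but off by default; none is exercised by the headline runs.
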