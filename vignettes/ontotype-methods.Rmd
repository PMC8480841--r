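---
title: "Ontology-guided association: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-guided association: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the representation

Conventional single-variant association struggles when many rare variants
converge on the same cellular machinery: each variant is seen in too few
individuals to reach significance, yet their joint effect on the pathway is
strong. `ontotyper` addresses this by changing the feature representation.
Non-synonymous variants (missense and nonsense) are collapsed onto genes with
an OR gate — a gene is "mutated" in a strain if it carries at least one
qualifying variant — and gene indicators are then aggregated over a gene
ontology: for every term (biological system) the feature is the *count of
mutated genes* in that term's propagated gene set. The resulting strains ×
terms matrix of non-negative integers is the **ontotype**. The encoding is
deliberately parameter-free: no weights, no normalization by term size (a
`normalize` flag exists but is off by default), so the monotone structure of
the hierarchy is preserved exactly — a parent's count always dominates each
child's, and the root counts every mutated gene known to the ontology.

## Ontology handling

Hierarchies come from OBO files (both `is_a` and `part_of` edges are used,
and treated identically, because the aggregation semantics — gene membership
in a system — do not distinguish relation types), from GAF 2.x annotation
files (rows whose qualifier contains `NOT` are skipped; no evidence-code
filtering), or from a generic `parent/child/type` edge-list that accommodates
data-driven hierarchies. After annotation propagation, two kinds of terms
are pruned: terms with no annotated genes, and terms whose propagated gene
set is identical to that of at least one child. The second rule deserves a
note: "redundant with respect to its children" could also be read as "equal
to the union of the children". We remove a parent when it equals *one*
child's set because such a parent carries no information beyond a strictly
more specific term; a parent equal only to the union of several distinct
children still encodes a real grouping and is kept. Pruning rewires each
removed term's parents to its children, so propagated sets of all retained
terms — including the root — are unchanged. Multiple ontology branches (the
three GO namespaces, or a data-driven hierarchy) are joined under one
artificial root so every strain has a single connected feature hierarchy.

Gene identifiers are matched verbatim and case-sensitively; harmonizing
symbol vs. ORF naming across files is the caller's responsibility.

## Genotype encoding

Genotypes are presence/absence: any call containing a non-reference allele
scores 1, which treats heterozygous calls in (rare) diploid data the same as
homozygous alternate — the representation asks only "does this strain carry
the variant". Missing genotypes score 0 by default, with a reported count; a
`drop_variant` policy is available when missingness is substantial.
Multi-allelic sites are decomposed into one column per alternate allele, and
variant IDs are synthesized as `chrom:pos:ref>alt` when the VCF ID field is
`.`, which keeps columns joinable across files.

## Models and cross-validation

All predictors are scored identically: seeded 5-fold cross-validation
(shuffle, contiguous split, remainder strains to the earliest folds), held-out
coefficient of determination per fold, mean over folds. Backends:

* **Random forest** (`ranger`): 1000 trees by default, bootstrap sampling,
  out-of-bag permutation importance. At the simulation scales used in the
  test-suite we run 50–200 trees with `min.node.size` 20–50 and a reduced
  `mtry`; these choices trade a little tree depth for many more
  permutation-null refits and do not change which features dominate.
* **Mixed random forest**: `y = f(X) + g + e` with `g ~ N(0, sigma2_g K)`
  for a kinship matrix `K`. Fitting alternates a forest on `y - g_hat` with
  REML variance components and BLUP of `g` on the forest *out-of-bag*
  residual (using in-bag fits here would let the forest absorb the genetic
  structure it is supposed to cede to `g`). Convergence: relative change of
  `sigma2_g` below `1e-4`, at most 20 iterations, `g_hat = 0` start.
  Held-out strains receive `f(X_new)` plus the kinship projection of `g`.
  Which SNV set feeds the kinship is a free choice; the default is the
  additive GRM of the same SNV set the model is trained on.
* **GBLUP**: `g_hat = K (K + delta I)^{-1} (y - ybar)` on the standardized
  genotype GRM; `delta = sigma2_e / sigma2_g` is REML-estimated when not
  given. This is algebraically ridge regression on standardized genotypes
  with penalty `m * delta`, and the test-suite checks that identity to 1e-6.
* **Ridge / lasso** (`glmnet`): penalty chosen by an inner seeded 3-fold
  cross-validation on the training split over `glmnet`'s log-spaced path.
* **MLP** (optional): three sigmoid hidden layers (1000/400/100 by default)
  with a linear output, trained by Adam on standardized data. Its training
  variance is high at cohort sizes of a few hundred, so it is exercised by a
  smoke test only and excluded from the scientific acceptance checks.

Every backend is deterministic given (inputs, config, seed): all stream
seeds (folds, forests, permutations, scrambles, random gene sets) are
derived from the single user seed plus a stage label.

## Feature importance, consensus and empirical FDR

Importance is out-of-bag permutation importance (mean decrease in MSE). The
null distribution per feature comes from refitting the model on `R`
response-permutations (default `R = 100`); the empirical P value is
`(1 + #{null >= observed}) / (1 + R)`, which is bounded below by `1/(R+1)`
and never zero. A feature is **consensus-selected** when its P value is
below `alpha = 0.01` in *all five* folds — note with `R = 100` this requires
beating every null replicate in every fold. The empirical FDR reruns the
identical pipeline (same folds, same permutation count) on a scrambled
feature matrix and reports `n_null / n_observed`. Scrambling permutes each
feature column independently across strains, destroying both
feature–phenotype and feature–feature structure while preserving marginals;
a `rows` mode (joint strain-label permutation) preserves feature–feature
correlation instead. Rerunning the permutation nulls on the scrambled matrix
(rather than reusing the real-data thresholds) is the conservative reading
of the procedure. Degenerate counts: `0/0` reports 0, and a nonzero null
count with zero observed selections reports 1 with a warning.

In the null-calibration acceptance check the per-fold threshold is
deliberately lax (`alpha = 0.6`) — at the operating `alpha = 0.01` a fully
null run selects nothing on either matrix and the ratio is degenerate at
`0/0`; the lax threshold makes both counts non-zero so the statistic's
behavior (ratio near or above one on null data) is actually observable.

## Burden validation, relationship matrices, heritability

A flagged system is validated directly on the gene matrix: strains are
binned by the number of mutated genes in the system, bins thinner than
`min_group_size = 5` strains are merged into the nearest lower bin (Tukey's
HSD needs filled groups; the floor is our choice, boxplot conventions do not
state one), and the phenotype is compared across bins with one-way ANOVA
plus Tukey HSD. The reference distribution repeats the binning for 1000
random gene sets of the same size drawn from genes *outside* the system.

The additive GRM is `K = Z Z'/m` on unit-variance standardized SNV columns
(monomorphic columns dropped); the epistatic relationship matrix is its
Hadamard square, positive semi-definite by the Schur product theorem.
Variance components of `y = mu + g_a + g_i + e` are estimated by restricted
maximum likelihood, optimized by L-BFGS-B on log variances from three
starting points (balanced, genetic-dominant, residual-dominant — the
restricted likelihood surface can have local optima when `K` is close to the
identity). Narrow-sense heritability is reported as the additive share
`h2 = sigma2_a / (sigma2_a + sigma2_i + sigma2_e)`; a two-variance ratio
with the epistatic term folded into the "environmental" denominator would be
the other defensible reading, and the three-component form is used here
because it keeps the additive and epistatic contributions separately
inspectable. "Variance explained" by a gene set is the in-sample OLS
coefficient of determination of the trait on the genes' binary indicators
(pseudoinverse for collinear indicators), which is monotone non-decreasing
in the gene set by construction.

REML h2 estimates from marker-based GRMs carry substantial sampling
variability: when `K` is nearly the identity the additive and residual
components are weakly identified, and even at `n = 500` strains and
`m = 1000` markers the estimator's spread around a true value of 0.5 is of
order 0.1. The acceptance checks use exactly that scale.

## What the synthetic data emulates — and what it does not

The generator mimics a species-wide panel of natural haploid isolates:

* **Population structure**: ancestral allele frequencies Uniform(0.05, 0.5);
  subpopulation frequencies drawn from the Balding–Nichols Beta distribution
  with drift parameter `differentiation` (default 0.1, moderate
  species-level divergence; 0.35 is used in the confounding stress test);
  haploid Bernoulli calls per strain.
* **Gene mapping**: each SNV assigned uniformly to one of `n_genes` genes;
  ~90% missense / 10% nonsense labels.
* **Hierarchy**: a layered rooted DAG (`branching` children per term down to
  `depth`, occasional second parents), genes attached to the deepest terms.
* **Phenotype**: planted per-system burden effects (default one system,
  negative sign — deleterious burden), a small polygenic background on 10%
  of genes (a tenth of the planted effect size, giving heritability tests a
  nonzero floor), optional subpopulation offsets, and Gaussian noise scaled
  so the realized genetic variance fraction matches `target_h2`.

Deliberately *not* emulated: linkage disequilibrium and recombination maps,
clonal pedigree structure, diploidy/heterozygosity, variant-severity
differences, and measurement artifacts of colony-size phenotyping. Passing
tests on this generator therefore demonstrate the statistical machinery —
propagation, selection calibration, structure correction, variance
partitioning — not robustness to the full messiness of real panels.

Default study conditions used by the acceptance checks: planted-system
recovery at `n = 500` strains, 1000 SNVs over 200 genes, an ~85-term pruned
ontology, the planted system explaining just under half the phenotypic
variance; FDR behavior at `n = 100–300`; heritability recovery at `n = 500`,
`m = 1000`; structure confounding with subpopulation offset variance three
times the genetic signal variance. These sizes were chosen once as realistic
desk-scale analogues of a ~1000-strain panel and are fixed in the test code.

## Numerical conventions and degenerate inputs

* Held-out R^2 uses the held-out fold's own mean in `SS_tot`; a constant
  phenotype is an error (R^2 undefined), and a constant response inside a
  backend yields constant predictions with zero variance components.
* Kinship matrices must be symmetric PSD within `-1e-8` (relative)
  eigenvalue tolerance; `K + delta I` with `delta = 0` and singular `K`
  raises an error advising a positive `delta`.
* Ties in consensus ordering break lexicographically after mean importance.
* Burden bins: merging proceeds from the thinnest high bin downward; bin 0
  merges upward. Fewer than two usable bins is an error, not a p-value.
* Empty gene sets, unknown genes/terms, cyclic hierarchies, sample-less
  VCFs, and effect filters that eliminate every variant are hard errors;
  unknown-term annotation rows and missing genotypes are warnings with
  counts.

## Known limitations

Only non-synonymous SNVs feed the representation: regulatory and structural
variation, copy number, and synonymous effects are invisible. The OR gate
saturates for genes with many frequent variants — in dense-variant regimes
nearly every strain has the gene "mutated" and the gene contributes little
signal (and little SNV-additive variance, which is why GRM-based h2 on
OR-collapsed simulations can be low even when burden effects are strong).
Counts ignore severity; a quantitative weighting is a natural extension.
Dense `n x n` REML limits heritability estimation to cohorts of a few
thousand strains.
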