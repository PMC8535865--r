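---
title: "Detecting SNP-SNP interactions for chronic DILI risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting SNP-SNP interactions for chronic DILI risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilisnp)
```

# The problem

Chronic drug-induced liver injury (DILI) — injury that does not resolve
biochemically within six months — affects a minority of DILI patients, and
individual SNPs carry little power to predict it. The working hypothesis of
this package is epistasis: combinations of genotypes at two or three loci can
be associated with chronicity even when each locus alone is not, or only
weakly so. `dilisnp` implements three families of interaction detectors, an
odds-ratio/Fisher-exact association layer over multilocus genotype
groupings, a selection filter requiring an interaction to beat its own
constituent SNPs, and a CART risk model over the pooled SNPs — together with
synthetic-data generators that emulate the study conditions under which such
a workflow can be validated.

Data model: a `genotype_data` object holds a samples-by-SNPs matrix of
two-letter genotype categories (heterozygotes canonicalised alphabetically,
so `TC` and `CT` are one category), a binary phenotype aligned to the sample
order (1 = case/chronic), and a per-SNP (major, minor) allele pair defining
the additive 0/1/2 coding. The analysis modules require complete genotypes;
`drop_incomplete_samples()` is the supported preparation step, since the
handling of missing calls in the motivating cohort is not documented and we
prefer an explicit, auditable rule over silent imputation.

# The detectors

## Multifactor dimensionality reduction

For a SNP subset S of size n, the n-locus genotype table is reduced to one
dimension by labelling each multilocus cell *high-risk* when its
case/control ratio is at least a threshold T, with ties going to high-risk,
cells containing cases but no controls labelled high-risk, and cells never
observed in training labelled low-risk. T defaults to the training fold's
case/control ratio: on a balanced simulation this reduces to the classical
T = 1, while on an imbalanced cohort (33 chronic vs 238 acute) a fixed T = 1
would label almost nothing high-risk. The reduction turns S into a binary
classifier whose misclassification error is measured by stratified
cross-validation (10 folds by default, the canonical MDR setting; the fold
assignment is seeded and stratified by class). For each order n the subset
minimising the average training classification error is retained, and the
final model minimises the average prediction (testing) error across the
per-order winners, with ties broken by higher cross-validation consistency,
then smaller order, then lexicographic SNP ids. High/low labelling uses
integer cross-products (cases·controls_train vs controls·cases_train), so
threshold comparisons are exact rather than floating-point.

The search is exhaustive and capped at 5·10⁶ subset evaluations; beyond the
cap `mdr_fit()` demands a marginal pre-filter (`prefilter_top`), which keeps
the top-m SNPs by their best single-genotype-grouping Fisher p. How the
original 872-SNP analysis tamed C(872,3) ≈ 1.1·10⁸ triples is not
documented anywhere we could follow, so the pre-filter is our explicit,
reported answer (the pipeline's MDR detector defaults to m = 20 when the
full search would exceed the cap).

## MARS on genotype predictors

The MARS engine does least-squares regression of the 0/1 phenotype on an
adaptively built basis, f̂ = intercept + Σ Cᵢ·Bᵢ(x), followed by backward
pruning under the generalized cross-validation score

GCV = RSS / (1 − C/N)²,  C = 1 + p·k,

with k the number of basis functions and p the cost per function (default
p = 3 when interactions are allowed, else 2 — the classical MARS costs).
The formula is implemented exactly in this form, without the conventional
1/N prefactor; the factor is constant for a dataset and cannot change model
selection, and printed-formula fidelity makes the scores directly
comparable to the motivating description.

Atoms are genotype-category indicators — each observed category and, for
three-category SNPs, each two-category complement, so that products can
express pooled carrier groups — or, optionally (`basis = "hinge"` /
`"both"`), hinge functions max(0, ±(x−t)) on the additive coding with knots
at the observed codes {0, 1, 2}. Indicators are the default because the
interactions of interest are genotype-level cells ("CC and CC"), which
indicator products represent exactly.

Two deliberate departures from the textbook forward pass:

* **Direct pair candidates.** Besides the classical parent-by-atom
  expansion, the candidate set contains all products of two atoms from
  different SNPs. A pure interaction with little marginal signal gives every
  single-SNP basis function near-zero expected gain, so a strictly greedy
  one-atom-at-a-time pass reaches the pair only through a chance entry;
  direct pair candidates make recovery systematic. On wide datasets the
  pair scan is restricted to atoms of the `pair_scan_top` (default 30) SNPs
  with the smallest marginal Fisher p.
* **`max_terms` default 13.** With N = 250 samples and this rich candidate
  set, a long forward pass (the textbook 20–30 terms) absorbs enough noise
  that chance degree-2 terms can rival a genuine pair; 13 terms (about one
  per twenty observations) is enough for an interacting pair plus marginal
  structure. The forward pass also stops when no candidate improves RSS by
  more than `forward_tol` (relative, default 10⁻³) and always keeps
  C = 1 + p·k below N so the GCV denominator stays positive.

Candidate scoring is incremental: candidate columns are kept orthogonalised
against the current basis (one rank-one downdate per accepted term), so each
forward step costs one matrix-vector sweep rather than a refit per
candidate. Numerically degenerate candidates (residual norm below 10⁻⁸
after projection) are discarded rather than inverted.

`extract_interactions()` reports the distinct SNP sets of degree-2+ terms,
ordered by their contribution (RSS increase when the set's terms are dropped
and the rest refitted), each with the single-genotype cell maximising the
fitted risk. The `mars_detect()` pipeline wrapper selects among these sets
by the association strength (Fisher p) of each set's risk cell rather than
by raw contribution: the pipeline's selection currency is the odds ratio,
and association ranking is markedly more stable when a noise set and the
true set have similar RSS contributions.

## Random Forest + logistic regression

`rf_rank()` grows a 500-tree classification forest (package `randomForest`)
on additive codes and ranks SNPs by mean Gini impurity decrease;
`lr_interaction_scan()` fits logit P(Y=1) = β0 + β1·A + β2·B + β3·A·B by
maximum likelihood for every pair among the top-k SNPs (default k = 5 — the
motivating workflow says only "the first few") and returns the pair with the
smallest Wald p for β3 when it is below α = 0.05. No multiplicity
correction is applied across pairs, matching the workflow's apparent
practice; the consequence, visible in the null simulations of the test
suite, is a family-wise null detection rate of roughly 1 − 0.95¹⁰, which a
user scanning many pairs should keep in mind. Pairs with non-converging or
separated likelihoods (|β3| essentially unbounded) are skipped with a
warning rather than reported with a meaningless Wald p.

# The association layer

`build_table()` turns an all-of genotype grouping (one category or category
set per SNP) into a 2×2 table of exposed/unexposed vs case/control;
`odds_ratio()` is the cross-product ratio (b·c)/(a·d), with the
Haldane–Anscombe +0.5 correction applied and flagged when a cell is zero.
Three confidence-interval constructions are available, and the two-sided
Fisher exact p-value (point-probability rule, via `stats::fisher.test`)
plus the Wald z-test of log OR are always both reported. We verified, row by
row, that the published association table this design reproduces prints
*Wald* p-values and *profile-likelihood* confidence intervals (the ones
`glm`+`confint` produce) although its text names the Fisher exact test:
only two of its eight p-values are consistent with Fisher, while all eight
match the Wald test at printed precision and all eight intervals match
profile likelihood to 2 decimal places (Wald intervals are close but
distinguishable; exact-conditional ones are not close). The package
therefore defaults `ci_method` to `"profile"` and reports both p-values,
leaving the choice explicit rather than silently conflating test names.

# The pipeline

`dili_pipeline()` chains: detectors → `select_improved()` (keep a candidate
iff its combined-genotype OR strictly exceeds the marginal OR of *every*
constituent SNP, where each SNP's marginal grouping is its highest-OR single
genotype — the rule that reconstructs the published per-SNP rows; p-values
are reported but never filter) → `pool_snps()` → CART (`rpart`, Gini
impurity, empirical priors, minimum leaf size 3 and complexity parameter
0.01 — small-leaf settings chosen so that clinically tiny but decisive
nodes, like a six-patient leaf, remain reachable) → stratified 5-fold
cross-validation with per-fold refitting (per-fold refit is the standard
choice where the original evaluation is ambiguous), pooling the confusion
matrix and reporting sensitivity, specificity, accuracy and balanced
accuracy = (sensitivity + specificity)/2 with chronic as the positive
class. The MDR candidate's reported risk cell is its highest-OR high-risk
cell among cells with at least 5 observations (tiny cells give unstable
Haldane-corrected ORs); the RF-LR candidate's is the observed cell
maximising the fitted log-odds. All randomness (fold assignments, forest
seed) derives from one master seed at fixed offsets.

# The synthetic generators

## Two-locus epistasis simulation

`make_epistasis_dataset()` builds 250 samples (125 cases / 125 controls) and
25 SNPs, with a planted interaction between SNP4 and SNP9 whose pooled
minority (carrier) groups contain exactly 52 and 57 samples. Construction is
exact rather than sampled: joint carrier cells (both, only-SNP4, only-SNP9,
neither) have fixed counts (36, 16, 21, 177); within each two-locus cell the
number of cases is a largest-remainder integer allocation of cell-size ×
penetrance pinning the total at exactly 125; heterozygote/minor-homozygote
splits within carriers follow Hardy–Weinberg conditional proportions; the 23
noise SNPs are Hardy–Weinberg draws (MAF uniform on 0.05–0.5) independent of
the phenotype; the sample order is shuffled. Everything is a deterministic
function of the seed.

The default penetrance, at carrier level (1/3, 1/16, 2/21, 110/177) for
(both, only-SNP4, only-SNP9, neither), makes carrying either minority group
alone strongly protective while carrying both lifts risk far above what the
two marginal effects predict. Two design points deserve emphasis:

* *It is not marginal-free.* A strictly no-marginal-effect (checkerboard)
  penetrance is the purest form of epistasis, and the cell-counting and
  spline detectors handle it well — but greedy impurity-based forests are
  essentially blind to it: a variable with zero marginal association never
  wins a split, so the conditional structure that would reveal its partner
  is never exposed. We verified this across pure designs and forest
  hyper-parameters before freezing the defaults. Since the workflow under
  study reports near-perfect recovery by all three methods, its simulated
  dataset cannot have been marginal-free either; our default follows suit.
  Users wanting the pure regime can pass their own penetrance and check it
  with `check_no_marginal_effect()`.
* *The causal loci are correlated by construction* (36 of the 52 SNP4
  carriers also carry SNP9, vs ~12 under independence). This is what makes a
  strong interaction feasible at the prescribed carrier counts; it emulates
  two interacting loci rather than two independent ones.

`permute_observations(data, k, protected)` implements the robustness test:
k sampled rows have their genotypes *re-drawn* from each unprotected
column's empirical distribution. Re-drawing, rather than swapping within the
column, guarantees the intended noise dose at small k (a swap of two equal
values is a no-op); whether the original procedure shuffled or redrew is not
stated, so we chose the variant with a well-defined effect size. Protected
columns (the causal pair) and the phenotype are untouched, so recovery rates
under permutation measure the detectors' resistance to noise in the
*background*, not degradation of the signal itself.

## Anchored DILI-like cohort

`make_cohort_dataset()` builds 271 patients (33 chronic / 238 acute) and 872
SNPs in which five anchored SNPs and three anchored genotype combinations
reproduce their prescribed 2×2 tables *exactly*, for every seed. The
allocator works per phenotype class: designated members of each anchored
combination are laid out first, with the minimal overlaps forced by tight
margins (e.g. the chronic rs3785157 margin forces at least 9 chronic
patients to be jointly exposed at rs6487213, rs5417 and rs3785157); the
remaining per-SNP exposed counts are then filled by a safety-checked greedy
pass, in randomised sample order, that never creates an undesignated member
of any anchored combination; every anchor is verified before the dataset is
returned, and infeasible anchor sets raise an error naming the violated
constraint. One additional default *background* cell — rs6487213 CC ×
rs5417 AA at 26 acute / 9 chronic — pins the joint cell of the two
strongest single SNPs below the anchored interactions; left free, that cell
would sit near within-class independence, where its odds ratio would exceed
the strongest anchored interaction and the fixture's top pairwise signal
would not be the anchored one.

What the cohort fixture does *not* emulate: everything the anchors do not
pin. The joint distribution of anchored with unanchored SNPs, and all
higher-order structure, is random; with 867 unconstrained noise SNPs the
globally strongest pairwise pattern in a given realisation is usually a
chance cell, exactly as it would be in a permuted real dataset. Passing
detector tests on this fixture therefore demonstrate mechanics (exact
anchor reproduction, filter logic, end-to-end plumbing) at the scales where
the anchored signal is identifiable; they do not certify discovery power on
872-SNP data, which depends on joint structure no margins-only synthesis
can supply. The generators also simulate no linkage disequilibrium between
noise SNPs, no population stratification, and no genotyping error.

# Tunable parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `mdr_fit(n_folds)` | 10 | stratified CV folds (canonical MDR setting) |
| `mdr_fit(budget)` | 5·10⁶ | exhaustive-search cap before a pre-filter is required |
| `mars_fit(penalty_p)` | 3 (2 if additive-only) | GCV cost per basis function |
| `mars_fit(max_terms)` | 13 | forward-pass size cap (~N/20 at simulation scale) |
| `mars_fit(forward_tol)` | 10⁻³ | minimum relative RSS gain to continue |
| `rf_rank(n_trees)` | 500 | forest size |
| `rf_lr_detect(top_k)` | 5 | SNPs carried into the logistic scan |
| `lr_interaction_scan(alpha)` | 0.05 | interaction significance level, uncorrected |
| `fit_risk_tree(min_leaf, cp)` | 3, 0.01 | CART growth control |
| `stratified_cv_tree(n_folds)` | 5 | evaluation folds, class-stratified |

# Known limitations

* MDR's final-model selection is a cross-validated comparison and inherits
  its Monte-Carlo noise: on fresh simulation replicates a lucky noise pair
  occasionally out-trains the planted pair (the test suite bounds, rather
  than eliminates, this).
* The Wald p-value degrades under quasi-separation (Hauck–Donner effect);
  the logistic scan skips separated pairs instead of reporting them, which
  means a *perfectly* deterministic interaction cell can be invisible to
  the RF-LR detector while trivially visible to MDR.
* Reported cross-validated tree metrics on the synthetic cohort are not
  comparable to metrics on the real restricted cohort, for the
  identifiability reasons above; the package reports them without asserting
  equality to any external figure.
* The exhaustive MDR search above the budget cap requires marginal
  pre-filtering, which can in principle discard a SNP whose effect is purely
  epistatic; this trade-off is explicit in `prefilter_top`.
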