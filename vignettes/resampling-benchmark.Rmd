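---
title: "Benchmarking resampling methods on controlled imbalanced domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking resampling methods on controlled imbalanced domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebalance)
library(dplyr)
```

## The problem

In imbalanced binary classification the decision boundary of most
learners drifts toward the majority class, and the rare (minority)
class — usually the class of scientific interest — is modeled poorly.
Data-level remedies *resample* the training set: **oversampling** adds
duplicated or synthetic minority rows, **undersampling** deletes
majority rows, and **filtering (hybrid) methods** oversample and then
delete rows that a cleaning rule judges misallocated. Oversampling can
*overgeneralize*: synthetic minority points interpolated between real
ones can land inside majority territory, blurring the boundary — and
this failure mode worsens as the intrinsic complexity of the problem
grows.

`rebalance` packages the three ingredients needed to study this
systematically: (1) a simulator of imbalanced domains with controlled
complexity, imbalance and size; (2) from-scratch implementations of the
classic resampling methods; (3) an evaluation protocol based on the
area under the precision–recall curve (AUPRC) and within-replicate
ranks.

## The generative model

Six features are derived from a 6-variate standard normal with
equicorrelation $\rho = 0.3$: $X_1, X_2, X_3$ stay continuous, and the
remaining three are thresholded into binary factors calibrated so that
$P(X_4 = 0) = 0.3$, $P(X_5 = 0) = 0.2$, $P(X_6 = 0) = 0.15$. A noisy
sigmoid response

$$\eta = \frac{1}{1 + e^{-(1.1X_1 + 0.9X_2 + 0.7X_3 + X_4 + X_5 - X_6 + \varepsilon)}},
\qquad \varepsilon \sim N(0,1),$$

maps each row into $(0,1)$. A **backbone model** partitions $[0,1]$
into $2^c$ equal intervals, each assigned to one class:

* *low* complexity ($c=1$): majority on $[0, 0.5)$, minority on $[0.5, 1]$;
* *medium* ($c=2$): four intervals alternating majority/minority;
* *extreme* ($c=2$): minority pushed to the two outer intervals, so the
  minority class splits into two maximally separated response clusters.

The interval placements for medium and extreme are this package's
documented convention (the interval *count* is what the design fixes);
`domain_spec(layout = "MAJ,MIN,...")` overrides them.

Sample size and imbalance are controlled by per-interval quotas: the
majority interval quota is $((5000/32)\cdot 2^s)/2^c$ rounded to the
nearest integer, and the minority quota divides that base by
$32/2^i$ before rounding. With $s \in \{1,3,5\}$ and
$i \in \{1,3,5\}$ this yields class totals such as 156/10 ($s=1$,
$i=1$; imbalance ratio 15.6) up to 2500/625 ($s=5$, $i=3$), and $i=5$
gives balanced classes. Rounding is half-away-from-zero; at $c=2$ some
bases land exactly on .5 (e.g. 312.5 at $s=3$), so summed class totals
at $c=2$ can differ by one count per interval from the $c=1$ totals —
the design table is exact at $c=1$.

`generate_domain()` fills every interval quota exactly by rejection
sampling (batches of 4096 draws, a documented cap of $10^7$ total
draws), drawing a fresh $\varepsilon$ per row; `generate_test_set()`
reuses the backbone with quotas rescaled by largest-remainder
apportionment to a requested total (default 5000) on an independent
seed stream.

```{r backbone}
build_backbone(domain_spec("extreme", s = 1, i = 1))
d <- generate_domain(domain_spec("low", s = 1, i = 1, seed = 1))
table(d$y)
```

## The resampling suite

All methods use Euclidean distance on the raw feature columns (the
simulated features are on comparable scales; binary features enter as
0/1), neighbor ties break toward the lower row index, and label `1` is
the minority/positive class throughout. For 0/1-coded labels the
positive class never flips mid-pipeline even if cleaning leaves class 0
the rarer one; `encode_features()` recodes arbitrary labels to this
convention. Defaults follow the methods' original descriptions where
the benchmark design is silent: SMOTE $k=5$, borderline-SMOTE
$m=k=5$, ENN $k=3$, All-KNN $k_{max}=3$, NearMiss-3 (3, 3), IPF 9
partitions / majority vote / stop after three consecutive iterations
each removing under 1%. The balancing target is full balance
(minority/majority ratio 1), exposed as `target_ratio`.

Orientation of ENN differs by role, a documented divergence: as an
undersampler it edits the majority class only; inside SMOTE-ENN it
edits both classes (standard hybrid semantics, `edit_class = "all"`).
For SMOTE-TL both members of a Tomek link are removed, while the plain
Tomek undersampler removes only the majority member.

Every method returns a `resample_result` whose dataset carries a
`.source` provenance tag, so hybrid deletions of synthetic points are
countable; `tidy()` returns the data, `glance()` a one-row count
summary.

```{r resample}
glance(apply_resampler(d, "SMOTE-ENN", seed = 2))
```

## Complexity measures

Three measures in $[0,1]$, oriented so higher = more complex: **F3**
(minimum over features of the fraction of rows inside the per-feature
class-overlap interval), **N2** ($r/(1+r)$ where $r$ is the
intra-class over inter-class nearest-neighbor distance sum — the
$[0,1]$ normalization satisfies the measures' documented range), and
**C2** ($1 - 1/\mathrm{IR_m}$ with the multi-class imbalance index
$\mathrm{IR_m}$). The benchmark design names these measures without
formulas; the definitions here follow the complexity-measure literature
conventions and are pinned by unit tests (e.g. 156/10 class counts give
C2 = 0.8723). `stratify()` provides the tertile and top/bottom-quartile
groupings used to split real datasets into complex and non-complex
cohorts (inclusive type-7 quantiles; ties keep all tied members).

## Evaluation protocol

`auprc()` is non-interpolated average precision with tied scores
grouped into a single threshold — the conservative convention, avoiding
the optimistic bias of interpolated PR area; with all scores tied it
collapses to the positive prevalence. `auroc()` is the tie-corrected
rank-sum statistic. Within each replicate all method configurations
*including the no-resampling baseline* are ranked by AUPRC (rank 1
best, average ranks for ties) — including the baseline in the pool is a
documented choice where the design is ambiguous — and performance is
reported as rank difference (baseline rank − method rank; positive
means resampling improved the ranking). Across replicates,
`aggregate_ranks()` averages rank differences and flags significance
with a paired two-sided t-test on per-replicate AUPRC differences at
$\alpha = 0.05$, deliberately without multiplicity correction
(matching per-bar significance stars); zero-variance differences are
non-significant unless uniformly non-zero with one sign, which is
flagged with a note.

## The simulation study

`run_simulation_study()` orchestrates: per domain × replicate, generate
a training set, resample with each configured method, tune a decision
tree by stratified 3-fold cross-validated grid search (maximum depth
$\{3, 5, 10, \text{unrestricted}\}$ × minimum leaf $\{1, 5, 10\}$ — the
design fixes 3-fold CV but no grid, so the grid is configurable), and
score on the domain's shared test set. The tree is an unpruned CART
(`cp = 0`): capacity control is left to the tuned depth/leaf
parameters, mirroring decision-tree implementations that grow full
trees by default; rpart's cost-complexity pruning default would
instead leave the rare class unmodeled on the raw data and flatter
every resampler's apparent benefit. Tuning happens per resampled
training set (the alternative — once per original set — is a
documented open point). All seeds derive from the master seed by a
fixed arithmetic scheme, making a study byte-reproducible.

The full published design is 27 domains × 50 replicates with test sets
of 5000. The package's own verification runs a scaled-down slice —
low and extreme complexity at $s = 1$, all three imbalance levels, 10
replicates, test sets of 2000, one fixed seed — the smallest design
that still crosses complexity with imbalance at every level. The
acceptance suite checks the family-level qualitative pattern (rank
differences of undersampling vs oversampling on low-complexity
domains; the filtering family's standing on extreme-complexity
domains) as a seeded statistical property, not published bar heights,
which are figure-only values. Whether the pattern emerges is an
empirical question the test answers at run time; a
correctly-specified learner (logistic regression on this generator)
is indifferent to resampling, so any family ordering is a property of
the tree learner interacting with the domain geometry, and orderings
observed at this scale need not match a larger design.

## The real-data protocol

`run_real_study()` applies the same machinery to a directory of CSVs:
categorical features with fewer than five levels are one-hot encoded
(five or more: ordinal codes), the label is recoded minority-to-1, the
split is 7:3 stratified by class, complexity is profiled on the full
dataset, and every (resampler + baseline) × classifier pair is scored
on the held-out 30%. Per-dataset AUPRC ranks averaged across datasets
give the top-combination tables; strata come from C2 (top quartile =
imbalanced cohort) crossed with F3/N2 (top quartile = complex, bottom
= non-complex). Classifiers are thin adapters over rpart, class,
e1071, randomForest and nnet behind a fit/predict-probability
contract.

## What the simulator does and does not emulate

The generator reproduces the study conditions: correlated mixed-type
features, a noisy monotone response, interval-defined classes, exact
class quotas. Real datasets differ in ways the simulator does not
attempt: feature scales are comparable by construction (hence no
internal standardization; a `standardize` flag would be needed for
heterogeneous real CSVs), features are never missing, the response
noise is homoscedastic Gaussian, and class structure is always
expressible as response intervals. Passing simulation checks therefore
demonstrates correctness of the machinery and the qualitative
complexity/imbalance mechanisms, not performance guarantees on any
particular real dataset.

## Numerical and degenerate-input choices

* Quota rounding: half away from zero; interval boundaries half-open
  with the last interval closed at 1.
* `compute_eta()` clamps to machine epsilon inside $(0,1)$.
* k is capped at (minority count − 1) for SMOTE-family methods;
  minority count < 2 is an error naming the method.
* Borderline-SMOTE with an empty DANGER set warns and returns the
  input unchanged; ADASYN with all-zero hardness falls back to uniform
  allocation.
* ENN vote ties (even k) keep the row; IPF re-draws degenerate
  single-class partitions once (single-class folds fall back to a
  constant-class learner when unavoidable).
* `n2()` returns 0 with a warning on duplicate-only data; `stratify()`
  warns and returns one stratum on constant input.
* IHT estimates out-of-fold probabilities with the tree adapter by
  default; folds that lose a class predict the training prevalence.

## Known limitations

Ten filtering variants the benchmark tabulates are defined only by
citation (DSRBF, TRIM-SMOTE, SMOTE-RSB\*, NRSBoundary-SMOTE, NEATER,
SMOTE-FRST-2T, NRAS, SMOTE-PSO, AMSCO) and are out of scope; SVM-SMOTE
and k-means-SMOTE ship as optional extras (`include_optional = TRUE`)
excluded from the default study set. All k-NN machinery materializes
full distance matrices, which is exact and fast at the study's scales
(≤ a few thousand rows) but not intended for very large datasets.
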