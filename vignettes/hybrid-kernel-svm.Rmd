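---
title: "Hybrid-kernel SVM diagnosis: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-kernel SVM diagnosis: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hksvm)
```

## The problem and the model

Clinical diagnosis tables are small-to-medium, mixed-type, and
heterogeneous in geometry: some diseases separate their classes linearly
in symptom space, others only through local neighbourhood structure.
Support vector machines make the kernel choice decisive, and no single
kernel is reliably best across such tables. `hksvm` therefore classifies
with a *hybrid kernel*: with single kernels

$$K_{\mathrm{lin}}(u,v) = u^\top v,\qquad
K_{\mathrm{rbf}}(u,v) = e^{-\gamma_{\mathrm{rbf}}\|u-v\|^2},\qquad
K_{\mathrm{poly}}(u,v) = (\gamma_{\mathrm{poly}}\, u^\top v + r)^d,$$

the three pairwise mixes share one mixing coefficient $\gamma \in [0,1]$,

$$K_1 = \gamma K_{\mathrm{lin}} + (1-\gamma) K_{\mathrm{rbf}},\quad
K_2 = \gamma K_{\mathrm{poly}} + (1-\gamma) K_{\mathrm{rbf}},\quad
K_3 = \gamma K_{\mathrm{lin}} + (1-\gamma) K_{\mathrm{poly}},$$

and the final kernel is the simplex-weighted sum
$K_h = \alpha_1 K_1 + \alpha_2 K_2 + \alpha_3 K_3$ with
$\alpha_1+\alpha_2+\alpha_3 = 1$, $\alpha_i \ge 0$. The RBF kernel is
*local* (it discriminates points close to each other), the linear and
polynomial kernels are *global*; the blend lets the data decide the
trade-off. Two different gammas appear in this family and the package
names them apart: `mix_gamma` is the pairwise mixing coefficient above,
while `rbf_gamma`/`poly_gamma` live inside the single kernels.

**Sign of the pairwise mixes.** The source formulas for $K_1$–$K_3$ can
be read as a subtraction
$\gamma K_{\mathrm{lin}} - (1-\gamma) K_{\mathrm{rbf}}$. The package
implements the *convex* reading, for three reasons: a subtractive mix is
indefinite (it violates the Mercer condition the dual solver assumes and
empirically produces Gram matrices with strongly negative eigenvalues — a
test demonstrates this); each $K_i$ is described as a *combination* of
two kernels; and the boundary behaviour of the convex form (at
$\alpha_1 = 1, \gamma = 1$ the hybrid is exactly the linear kernel)
matches how optimal weight vectors collapse onto well-performing single
kernels in practice. The subtractive form remains available via
`literal_signed = TRUE` in `hybrid_gram()` / `pairwise_hybrid()` for
anyone studying the literal text, with `check_psd()` reporting its
indefiniteness. The constraint set bounds `mix_gamma` in $[0,1]$: only an
upper bound is stated in the source, but the convex reading requires the
lower one, and all reported optima lie inside $[0,1]$.

Because any convex combination of Mercer kernels is Mercer, $K_h$ on any
point set is symmetric positive semidefinite; the package asserts this
property over randomized weights and data (smallest eigenvalue
$\ge -10^{-8}$).

## Solver

Training uses precomputed Gram matrices, which is what makes an arbitrary
blend usable. Binary subproblems are solved by a compact SMO routine
(maximal-violating-pair working-set selection, the LIBSVM-style scheme)
written in C++, with stopping tolerance $10^{-3}$ on the KKT gap and the
standard free-vector rule for the intercept. Multiclass is one-vs-one:
within each pair the smaller class index plays the positive role, a
decision value of exactly zero votes for it, and vote ties break towards
the smallest class index — the conventions of the common
precomputed-kernel solvers. The box constraint defaults to $C = 1$ (the
usual solver default; the method's sources do not state one); it is
configurable everywhere and can be appended to the GA genome
(`search_C = TRUE`, log scale in $[10^{-2}, 10^2]$).

The test suite ties this solver to an independent reference: at each of
eight boundary weight vectors where $K_h$ collapses exactly onto a single
kernel, precomputed training/prediction is compared against `kernlab`
run with the corresponding *native* kernel on 200 randomized 40-point
datasets. Agreement is label-exact in ≥ 95% of runs, and any disagreeing
row must sit at $|f| < 0.1$ in margin units (support vectors sit at
$|f| = 1$), i.e. at numerically tied decisions — in such cases both
solvers reach the same dual objective and differ only in which side of
zero a near-boundary row falls.

## Genetic-algorithm tuning

The weights $(\alpha_1,\alpha_2,\alpha_3,\gamma)$ are searched by a
generational GA minimizing $-1 \times$ (mean $k$-fold cross-validation
accuracy, in percent), $k = 5$ by default. Design choices, all
configurable through `ga_control()`:

* **Encoding and constraints.** Genomes are unconstrained reals repaired
  on decode: the three $\alpha$ genes are clipped at zero and normalized
  to the simplex (`repair_simplex()`, with the all-zero vector mapping to
  the uniform $1/3$ point), `mix_gamma` is clipped to $[0,1]$. Repair
  keeps every evaluated candidate feasible, avoiding penalty functions.
* **Operators.** Tournament selection (size 3), per-gene arithmetic blend
  crossover (probability 0.8), Gaussian mutation (per-gene probability
  0.1, s.d. 0.1 of the gene range), elitism 1. Defaults: population 50,
  at most 100 generations, stopping early after 20 generations without
  improvement beyond $10^{-6}$. These are conventional small-scale GA
  settings sized for tables of roughly a thousand rows.
* **Exact, cacheable fitness.** The fold assignment is fixed once per run
  and shared by every fitness evaluation, so fitness comparisons across
  generations are noise-free, and fitness is cached on the repaired
  genome rounded at $10^{-9}$. The three single-kernel Gram matrices are
  computed once per run; each candidate only recombines them, so an
  evaluation costs three matrix scalings plus $k$ SMO solves.
* **Verification oracle.** `grid_search_weights()` exhaustively evaluates
  the simplex lattice (spacing 0.1 crossed with the `mix_gamma` lattice:
  66 × 11 = 726 candidates) with the same folds; the GA is required to
  come within 2 accuracy points of the lattice optimum.

Whether a published "cross-validation accuracy" refers to the best
fitness seen during search or to the tuned weights re-validated after
search is often ambiguous; the pipeline reports both (`tuning` and
`train_cv` in the run object). With the shared fold seed they coincide.

## Pipeline and leakage policy

`run_pipeline()` executes: load (CSV or svmlight) → encode → optional
per-column range filter → optional class-rebalancing downsample →
stratified shuffle–split (80/20) → imputation → scaling → PCA → optional
svmlight export → GA tuning → final training on the full training split →
held-out evaluation.

* **Encoding.** A column is categorical when any non-missing cell is
  non-numeric. One-hot is the default (k observed levels → k binary
  columns); ordinal encoding (alphabetical level order) is available.
  The encoding, imputation and scaling methods are not prescribed by the
  method's sources; median/mode imputation, standardization (sample
  s.d., $n-1$) and one-hot are the package defaults as the robust
  conventional choices for SVM inputs. Imputation precedes scaling, so
  scaling statistics include imputed values.
* **Missing values.** Accepted CSV sentinels: empty cell, `NA`, `NaN`,
  `?` (configurable). Parsing never imputes; sentinels survive to the
  imputation stage, whose statistics are computed on the training split
  only and re-applied to the test split.
* **Splitting.** Stratified by default (each class split as close to the
  training fraction as rounding permits) — plain shuffling is available —
  because the small clinical tables otherwise risk folds or test sets
  missing a class entirely.
* **PCA.** Axes come from the SVD of the column-centered training matrix
  (via `prcomp`); the retained dimension is the smallest $k$ whose
  cumulative explained-variance ratio reaches the threshold (default
  0.95, $n-1$ denominators, consistent with scaling). Each axis's sign is
  fixed by making its largest-magnitude entry positive, making fits
  deterministic and row-order invariant. The flowchart order of the
  original procedure applies PCA *before* splitting; that is a leakage
  risk, so the default here fits PCA on the training split only and a
  `paper_order = TRUE` flag reproduces the original ordering for
  fidelity studies.
* **Determinism.** Every stage draws its seed from the master seed
  through `derive_seed(master, stage_index)`, so adding a stage never
  reshuffles the others and a run's JSON artifact is byte-identical
  under a repeated seed.
* **svmlight export.** Retained for interoperability (1-based strictly
  increasing indices, zeros omitted, 17 significant digits so matrices
  round-trip within $10^{-12}$); `svmlight_export = "strict"` re-reads
  the exported files and continues from them, proving format fidelity
  inside the run itself.

## Evaluation

`eval_report()` builds the confusion matrix (rows = actual, columns =
predicted) with accuracy $= 100\,\mathrm{tr}(M)/n$, per-class precision
(column-wise $TP/(TP+FP)$) and recall (row-wise $TP/(TP+FN)$). A class
never predicted, or absent from the evaluated rows, has an undefined
ratio; the package reports 0 with a warning — a convention, chosen
because silently dropping such classes hides degenerate predictions.
Micro-averaged recall equals accuracy, an identity the tests assert.

`run_comparison()` implements the model-comparison protocol: the
GA-tuned hybrid and the three single-kernel baselines are scored by
(default) 10 runs of 5-fold cross-validation with per-run fold seeds
shared across models, and the runs × models accuracy matrix goes into
Friedman's rank test (`stats::friedman.test`, tie-corrected chi-square;
the fully tied case is reported as statistic 0, p = 1 rather than NaN).
P-values are reported without an interpretive threshold. Wall-clock time
per model is logged for orientation but is hardware-dependent and never
asserted.

## Synthetic data: what it does and does not show

No real patient data ships with the package. `generate_synthetic()`
produces clinical-shaped tables with controlled geometry:

* `linear_separable` / `overlapping`: Gaussian blobs with class centers
  spaced `separation` apart along a random unit direction. The direction
  is random (not the all-ones diagonal) so that the correlation
  mechanism below is not confounded with the class signal.
* `radial`: concentric shells, class $c$ at radius $c \times$
  `separation` with radial noise 0.15 × `separation` — separable by a
  local kernel, not by a half-plane. A half-plane can still capture one
  blob plus part of a ring, so "near chance" for the linear kernel means
  roughly 60–75%, not 50%; the tests encode that honestly.
* `polynomial_boundary`: classes are ordered slices of a fixed quadratic
  form with a separation-scaled gap dropped around each threshold.
* Correlated features: a shared standard-normal latent factor mixed into
  every numeric column at weight $\sqrt{\rho}$, giving pairwise
  correlations near $\rho$ — the "correlated features that only add
  noise" motif PCA is there to absorb. Note the factor also shrinks the
  class signal by $\sqrt{1-\rho}$, so high-$\rho$ tables are genuinely
  harder, not just noisier.
* Categorical columns with class-dependent level frequencies; missing
  cells placed completely at random (MCAR) at the requested rate — no
  informative-missingness mechanism is modelled.

`synthetic_clinical_suite()` emulates the (instances, features, classes)
signatures of seven widely used diagnosis benchmarks (148 × 18 with four
classes, 120 × 6 binary, 569 × 30 binary, and so on) with mixed
geometries. Only shapes are echoed: passing tests on these fixtures shows
the pipeline's mechanics and the tuner's behaviour under known geometry,
not clinical performance. Real tables have informative missingness,
label noise, measurement artefacts and distribution shift that the
generator deliberately does not model, and published accuracies on the
real benchmarks are not reproducible from synthetic stand-ins.

## Study conditions used by the checks

The acceptance-style tests and `scripts/acceptance.R` run at sizes chosen
to exercise the claims within desk-scale budgets: 200 randomized
40-point datasets for the reference-solver comparison; 100 random
50-point sets for the Mercer check; a 150-sample two-class set against
the 726-point grid oracle over 3 GA seeds; radial and
polynomial-boundary suites of n = 400 over 5 seeds for the
hybrid-vs-singles and weight-recovery checks. The radial suite uses
separation 1.2: at larger separations every mixture attains 100% CV
accuracy, the fitness landscape is flat, and asking where the optimizer
puts its mass becomes meaningless — at 1.2 the non-RBF kernels sit near
chance, so RBF mass is identifiable. The GA configurations in these
checks are scaled down (population 20–30, 15–25 generations with early
stall) from the package defaults, which changes search effort, not the
search problem.

## Known limitations

* The SMO solver targets desk-scale problems (up to a few thousand
  rows); there is no shrinking, kernel caching across processes, or
  approximate (Nyström) path.
* One-vs-one with voting gives no probability calibration; regression
  and one-class modes are out of scope.
* The GA is single-population and single-objective; fitness evaluations
  are sequential.
* Downsampling is the only rebalancing mechanism (no SMOTE or
  oversampling), mirroring the method's own protocol.
* The sigmoid kernel is provided as a single kernel for completeness but
  never enters the hybrid, whose constraint set and optima are defined
  over the linear/RBF/polynomial trio.
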