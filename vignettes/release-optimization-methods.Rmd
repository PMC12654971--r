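---
title: "Modeling and optimizing sustained-release formulations with releaseopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and optimizing sustained-release formulations with releaseopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`releaseopt` implements a complete workflow for optimizing multi-component
sustained-release tablet formulations from mixture-design dissolution data:
polynomial release modeling with sparse term selection, repeated-measures
estimation by quadratic inference functions, penalty-constrained
multi-objective search of the composition space, and entropy-weighted
TOPSIS ranking of the pooled candidates. This vignette explains the models,
the tunable parameters, and the numerical and design choices behind each
stage.

## The data and the modeling problem

A mixture-design dissolution study measures, for each of $n$ trial
formulations, the cumulative drug release percentage $Y_t$ at a set of time
points (here 2, 8 and 24 h — the initial, intermediate and terminal release
phases). Each formulation is described by $q$ excipient percentages
$X_1,\dots,X_q$ that must sum to a fixed total (82.8 % w/w in the packaged
glipizide study: HPMC K4M, HPMC K100LV, MgO, lactose, anhydrous CaHPO$_4$).
Two features shape the statistics:

* **The constant-sum constraint.** The design region is a box-bounded slice
  of a simplex, so component effects are not separately identifiable in the
  classical sense, and optimization must respect $\sum_i X_i = 82.8$.
  Printed data carry rounding error: with five components reported to one
  decimal, a row sum can be off by up to 0.25 percentage points, which is
  the default tolerance of `validate_constant_sum()` (machine-exact sums
  are demanded of generated data). The packaged 25-run study indeed
  contains rows summing to 82.6–82.9.
* **Repeated measures.** The three release values of one formulation are
  serially dependent. On the packaged study the rank correlations between
  time points are $-0.23$ ($Y_2,Y_8$), $-0.62$ ($Y_2,Y_{24}$) and $0.69$
  ($Y_8,Y_{24}$) — `release_correlations()` computes either Pearson or
  Spearman versions — which motivates an autoregressive working-correlation
  structure in the fit.

## Candidate terms: the q-component centered polynomial

`term_basis()` enumerates main effects, all product interactions up to a
chosen order, component-by-time interactions, linear and quadratic time,
and an intercept — 39 candidate terms for $q = 5$ at full order. Labels
are canonical index strings (`X24` = $X_2 X_4$, `X3t` = $X_3 t$, `t2` =
$t^2$). Raw (Scheffé-type) products are the default; an optional centered
variant shifts component columns by their training means before products
are formed, with the offsets stored for prediction-time reuse. Both modes
share one code path, and an intercept is retained even though classical
Scheffé mixture models drop it, because the reference model family
includes one.

## Sparse term screening

With 38 non-intercept candidates and 75 pooled observations the model is
badly overparameterized, so terms are screened by penalized least squares
(`cv_select()`): cyclic coordinate descent on standardized columns under a
LASSO, SCAD ($a = 3.7$) or MCP ($\gamma = 3$) penalty, a 100-point
log-spaced $\lambda$ path down to $10^{-3}\lambda_{\max}$, and $k$-fold
cross-validation with ties resolved toward the sparser model. The inner
descent loop is compiled (C++) because the non-convex penalties on highly
collinear interaction columns need thousands of sweeps to reach the
$10^{-7}$ coefficient tolerance.

Two choices deserve comment:

* **Fold construction.** By default folds partition *formulations*, never
  individual time rows, so the three serially-correlated measurements of
  one formulation can never straddle the train/validation split. Row-level
  folds (the convention of generic penalized-regression CV on pooled data)
  are available via `fold_by = "row"`; they are systematically more
  optimistic because the two in-fold time points of a held-out row leak
  cluster information. On the packaged study this difference is material:
  leakage-free folds retain only the time terms for the non-convex
  penalties, while row folds retain 15–20 terms. The CV error curve is
  nearly flat across that whole range — composition effects are weak
  relative to noise at $n = 25$ — so the selected support is genuinely
  fold-dependent, and only the sparsity *ordering*
  $|\mathrm{MCP}| \le |\mathrm{SCAD}| \le |\mathrm{LASSO}|$ is stable.
* **Support cap.** `max_terms` restricts the admissible path points. Its
  purpose is downstream: a quadratic-inference fit with $K$ basis matrices
  imposes $K(p+1)$ moment conditions whose empirical covariance is
  estimated from only $N$ cluster scores. Stress tests on the packaged
  study show clean fits while the moment count stays at or below about two
  thirds of $N$ and severe distortion as it approaches $N$; the pipeline
  therefore caps supports at $\lfloor 2N/3K \rfloor - 1$ terms.

## Quadratic inference function estimation

`fit_qif()` estimates the selected linear release model on the
repeated-measures data. For cluster $i$ with design $X_i$ and responses
$y_i$, the inverse working correlation is expanded in basis matrices $M_k$
(identity plus the tridiagonal AR(1) pair from `ar1_basis()`; an
exchangeable pair is available for sensitivity), giving stacked extended
scores $g_i(\beta) = \{X_i^\top M_k (y_i - X_i\beta)\}_k$. The estimator
minimizes $Q_N(\beta) = N \bar g^\top C^{-1} \bar g$ with
$C = \tfrac1N \sum_i g_i g_i^\top$; for this linear, identity-link case the
minimizer is computed by iterated two-step GMM (start at OLS, rebuild $C$,
solve the weighted normal equations, iterate to $10^{-8}$). Columns are
internally rescaled to unit RMS — the estimator is exactly invariant to
this, and the raw polynomial columns span seven orders of magnitude — and a
singular $C$ falls back to a Moore–Penrose pseudoinverse after a $10^{-10}$
ridge jitter, with a warning. With the identity-only basis the estimate
reduces exactly to OLS, a property the tests exercise.

Inference uses the GMM sandwich $(G^\top C^{-1} G)^{-1}/N$;
`inference_table()` reports Wald $z$ statistics. `information_criteria()`
defines $\mathrm{AIC} = Q_N + 2p$ and $\mathrm{BIC} = Q_N + p\ln n_{obs}$,
a convention fixed so that $\mathrm{BIC} - \mathrm{AIC} = p(\ln n_{obs} -
2)$ — on the packaged study with $p = 11$ and $n_{obs} = 75$ this gap is
25.492, matching the gap between the study's published values. The
absolute base term is configurable (`base = "gaussian"` uses a $-2$
log-likelihood) because $Q_N$ bases are only comparable between models with
the same moment structure: a model containing no composition terms has an
identical design in every cluster, which lets the mean score be zeroed
exactly ($Q_N = 0$) — an artifact of the shared design, not evidence of
fit, and one reason the pipeline does not choose its optimization model by
$Q$-based criteria alone (see below).

## From model to objectives

`predict_release()` evaluates the fitted polynomial at any (composition,
time); `build_objectives()` converts it into three objectives to minimize,
$Q_k(x) = -\hat Y(x, t_k) + \sigma P(x)$, with the quadratic exterior
penalty $P(x) = (\sum_i x_i - 82.8)^2$ and $\sigma = 1000$. The quadratic
$\varphi$ keeps the objectives differentiable, and at $\sigma = 1000$ a
constant-sum violation of 0.05 already costs 2.5 release points, far more
than any release difference of comparable scale, so optimizer output stays
within 0.05 of the slice in practice. $\sigma$ is fixed — no escalation
schedule — because a single value suffices at this scale.

A second, optional penalty charges violations of the pharmacopoeia release
intervals ($Y_2 \in [15,25]$, $Y_8 \in [55,65]$, $Y_{24} \in [80,110]$)
inside the search. This matters because the three objectives are
*concordant* on fitted release models — compositions that dissolve faster
do so at every time point — so the unconstrained within-box optimum
overshoots the upper caps and an archive gathered around it contains no
feasible point at all. Steering the search with the interval penalty keeps
final archives feasible; the post-hoc `pharmacopoeia_filter()` is still
applied at pooling. (That the published candidate set tops out at
$Y_8 = 64.983$, a hair under the 65 cap, shows the cap acting as an active
constraint during the original searches too.) The base objective contract
— `Q_k = -Yhat` exactly on the feasible slice — holds when no limits are
attached.

## Multi-objective search

Three metaheuristics search the box-bounded composition space, sharing the
Pareto machinery (`nondominated_sort()`, `crowding_distance()`,
`das_dennis()`):

* **NSGA-III** (`run_nsga3()`): binary tournament on front rank,
  single-point crossover interpreted as a tail swap on the real-coded
  5-vector (probability 0.8), per-gene uniform-reset mutation (0.05), and
  environmental selection by non-dominated sorting with ideal-point
  normalization and Das–Dennis reference-direction niching ($p = 13$
  divisions, 105 directions for a population of 100 — the standard sizing
  rule).
* **MOGWO** (`run_mogwo()`): an external archive of non-dominated
  solutions on an adaptive hypercube grid (10 divisions per objective,
  inflation $\alpha = 0.1$); wolves move toward three leaders drawn by
  roulette over inverse cell density raised to $\beta = 5$; an over-full
  archive (cap 100, matching the population) evicts from crowded cells
  with pressure $\gamma = 2$.
* **NSWOA** (`run_nswoa()`): whale operators — shrinking encirclement with
  coefficient $a$ decaying linearly $2 \to 0$, logarithmic-spiral
  bubble-net with $b = 1$, random-leader exploration, branch probability
  0.5 — followed by elitist non-dominated sorting with crowding-distance
  truncation; progress is reported every `ishow = 10` generations.

All runs use population 100 over 200 generations, clip bound violations,
are bitwise-reproducible under a fixed seed, and record per-generation
best-so-far and population-mean scalarized fitness. The scalarization
$-(Q_1+Q_2+Q_3)$ is a reporting convention for the evolution curves, not
part of selection. On the packaged study the curves gain the bulk of
their improvement in the first generations (the penalty terms collapse
fast), but small best-so-far gains — on the order of 1 % of the fitness
level, from polishing the constant-sum and release-window penalty
boundaries — continue to arrive late in many runs. This is intrinsic to
the operator set: tail-swap crossover recombines existing coordinate
values and uniform-reset mutation is the only source of new ones, so fine
refinement proceeds by fresh random draws rather than by continuous
contraction. A strict plateau criterion (no improvement beyond 0.1
fitness units after generation 50) therefore fails for a majority of
runs of all three algorithms, and the shipped checks assert monotonicity
plus a late-gain bound relative to the fitness level instead.

Each algorithm is run 15 times independently (run $r$ of algorithm $k$
seeded as `seed + 1000k + r`); `pool_candidates()` filters each final
archive to the pharmacopoeia window and distills one representative per
run by equal-weight TOPSIS (vector normalization, zero negative ideal) —
the original study does not state its per-run distillation, and this
choice is deterministic and mirrors the final ranking stage. The pooled
table has 45 rows, printed to three decimals.

## Entropy-weight TOPSIS ranking

`entropy_weights()` and `topsis()` implement the final evaluation. The
release criteria are first min–max rescaled to $[0,1]$ per column; entropy
weights follow from column-sum probabilities,
$e_j = -\tfrac{1}{\ln n}\sum_i P_{ij}\ln P_{ij}$,
$w_j = (1-e_j)/\sum_k (1-e_k)$; TOPSIS vector-normalizes the rescaled
matrix, weights it, and scores each alternative by closeness
$C = D^-/(D^+ + D^-)$ to the ideal points. Min–max preprocessing makes the
column minima zero, so the negative ideal is exactly the zero vector — the
all-benefit convention. This dialect was fixed by reconciliation against
the study's published ranking table, which it reproduces essentially
exactly (all 15 printed ranks, $C$, $D^\pm$ to three decimals, and
$Y_8$ carrying the largest weight); the plainer dialect that skips the
min–max step is available via `preprocess = "none"` but assigns the
largest weight to $Y_2$ and ranks a different candidate first, so it
cannot be the published computation. Ties in $C$ break toward the earlier
row for reproducibility.

## The pipeline

`run_pipeline()` chains the stages: data (packaged study, CSV, or the
synthetic generator), term basis, screening with each penalty family,
QIF fits of every variant plus the unscreened model (which on the packaged
study is rank-deficient — 31 composition columns cannot exceed rank 25 on
25 formulations — and is reported as unfittable), an information-criterion
table, objective construction with in-search limits, the 45-run optimizer
suite, pooling, ranking, and a comparison of the winner against the
original formulation (absolute change and percent rate of change per
component and per time point). The release model used for optimization is
the best composition-dependent variant by BIC: on the packaged study the
non-convex penalties retain only time terms, and a model with no
composition terms — whatever its prediction error — has nothing to say
about formulation. The master seed makes the whole bundle a pure function
of (data, config, seed).

## The synthetic generator

`simulate_mixture_study()` emulates the study design for testing and
calibration: compositions are drawn uniformly in the component box
(defaults: the observed ranges of the packaged study), projected onto the
constant-sum hyperplane by an equal shift, and rejected if the projection
leaves the box; responses are a sparse ground-truth polynomial (default:
the published 11-term model) plus stationary AR(1) Gaussian noise across
time points (defaults $\sigma = 2$ release points, $\rho = 0.5$ — a
moderate serial dependence consistent with the observed correlation
structure; study size 25). What the generator does *not* emulate: real
dissolution noise is heteroscedastic and bounded (release cannot exceed
~110 %), component effects enter through an unknown transformation rather
than exactly through raw products, and real designs are D-optimal rather
than uniform-on-a-slice. Passing recovery tests on synthetic data
therefore validate the estimators' algebra and their sampling behavior
under the assumed model, not the adequacy of that model for any real
formulation.

## Numerical choices and degenerate inputs

* Coordinate descent converges on a $10^{-7}$ maximum coefficient change
  (standardized scale) with a 10,000-sweep budget; non-convergence warns
  rather than fails. Constant columns are absorbed into the unpenalized
  intercept.
* The QIF iteration stops on a $10^{-8}$ coefficient change; rank-deficient
  post-selection designs raise immediately.
* Correlation of a constant response column, entropy weights of an
  all-constant criterion matrix, and TOPSIS on a zero-norm column all
  raise rather than return NaN.
* Zero-noise simulation reproduces the ground-truth polynomial exactly and
  regression residuals of the true model are numerically zero, which the
  tests assert.
* Degenerate (zero-range) objectives contribute zero crowding distance;
  duplicated archive members are deduplicated at $10^{-10}$ resolution.

## Problem sizes used in the shipped checks

The packaged checks run the full reference workflow at its native size
(25 formulations, 39 candidate terms, 15 runs x 3 algorithms x 200
generations x population 100). Property checks use deliberately smaller
synthetic studies (16–500 formulations, 200 replicate fits for the
recovery study, 300 bootstrap resamples) — sizes chosen so the whole suite
exercises every code path in a few minutes while keeping Monte-Carlo
standard errors small enough for 2-sigma assertions.

## Known limitations

* The published model coefficients cannot be reproduced from the published
  data: plugging the printed compositions into the printed equation does
  not recover the printed predictions, indicating an unstated variable
  transformation in the original analysis. The package therefore refits
  rather than hard-codes, and treats the published candidate table as the
  fixture for the ranking stages.
* Selected supports on a 25-formulation study are fold-dependent; only
  order properties are stable.
* The exterior penalty handles one equality constraint; general nonlinear
  constraints beyond the release intervals are out of scope, as are
  pH-dependent mechanistic release models and experiment-design generation.
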