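---
title: "Designing and analysing mixture-amount experiments with mixamount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing mixture-amount experiments with mixamount}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixamount)
```

## The problem

A mixture experiment varies the *composition* of a blend: the proportions
`x_1, ..., x_q` of its components are non-negative and sum to one, so the
design region is a simplex and a polynomial in the proportions cannot contain
an intercept (it is confounded with the blending constraint). A
mixture-amount experiment additionally varies the *total amount* of the blend
applied, so that both "what the mixture is" and "how much of it there is" act
on the response.

The motivating application is a diet study on tephritid fruit-fly
development: five phenolic compounds found in apple —
(+)-catechin (`Ca`), phloridzin (`Ph`), rutin (`Ru`), chlorogenic acid
(`ChA`) and *p*-coumaric acid (`pCoA`) — are blended in varying proportions
and added to artificial diet at total concentrations between 75 and
225 mg/100 g. The lower bound is the rounded sum of the mean per-compound
contents measured in resistant apple cultivars; the upper bound is three
times that. Dish-level responses (larval weight in mg, development times in
days, and percentages derived from 30 larvae per dish) are analysed by
ordinary least squares on dish means.

## The model

The package fits crossed Scheffé polynomials. With coded amount
`A in [-1, +1]`,

* linear mixture: `sum_i beta_i x_i`,
* quadratic mixture adds `sum_{i<j} beta_ij x_i x_j`,
* crossing with an amount polynomial of order `d` multiplies every mixture
  term by `A^a`, `a = 0, ..., d`.

For `q = 5` components the full quadratic-by-quadratic crossing has
`(5 + 10) * 3 = 45` terms; `enumerate_terms()` generates the set in a fixed
lexicographic order so every matrix and report is bit-for-bit reproducible.
A pure component's predicted response at mid amount equals its blending
coefficient — which is how printed coefficient tables can be checked directly
against `predict_surface()`.

Amount coefficients are interpreted on the *coded* scale. The reference
coefficient sets shipped in `reference_study_config()` carry `[Conc]` terms
whose magnitudes are consistent with coded units, and all internal
computation codes the amount before evaluating terms; `code_amount()` /
`decode_amount()` convert both ways.

## Design construction

`build_study_design()` chains five steps, each independently usable:

1. **Candidates** (`generate_candidates()`): simplex vertices, binary 50:50
   edge midpoints, the overall centroid and axial check blends, crossed with
   the coded amount levels {-1, 0, +1}. For five components this yields 63
   candidates.
2. **D-optimal model points** (`select_d_optimal()`): Fedorov point exchange
   maximizing `det(X'X)` — random QR-guided starts, the best single swap per
   iteration, stop at a relative improvement below 1e-10, at least ten
   multi-starts keeping the best. The model-point set is kept duplicate-free:
   replication is a separate design role here, and a duplicate-free set is
   what an exhaustive subset-enumeration oracle checks. All determinant and
   inverse computations go through QR so that near-singular candidate sets
   are detected by rank, not by a determinant underflow.
3. **Lack-of-fit points** (`augment_lack_of_fit()`): greedy maximin distance
   in coded space (proportions plus coded amount). The criterion is a
   standard distance-based augmentation; the class of points is part of the
   design contract, the selection rule is ours.
4. **Replicates** (`augment_replicates()`): the highest-leverage distinct
   points are duplicated (ties broken by a seeded shuffle). Leverage-guided
   replication puts pure-error information where the model variance is
   largest.
5. **Center points and blocks**: `add_center_points()` appends copies of the
   equal-proportion centroid at mid amount; `assign_blocks()` balances block
   sizes to within one run and spreads copies of the same point across
   blocks.

The canonical build (45 model + 5 lack-of-fit + 45 replicate + 5 center runs
in 5 blocks) reserves the centroid-at-mid-amount point for the center role by
excluding it from the model/lack-of-fit candidate pool, so the design always
has 51 distinct points.

### Degrees-of-freedom accounting

`df_partition()` uses the mixture convention: block df `n_b - 1`; model df
`t - 1` for `t` terms (the blending constraint absorbs one df); lack-of-fit
df `(#distinct points) - t`; and pure-error df the *residual remainder*
`(N - 1) - block - model - lof`. The remainder convention matters: the naive
within-replicate count `sum(n_i - 1)` is 49 for the canonical design, but
block effects consume four replicate df, and the remainder definition
reproduces the published partition 4 / 44 / 6 / 45 exactly.

## Fitting and ANOVA

`fit_rsm()` solves the no-intercept least-squares problem with fixed block
effects in sum-to-zero coding, via QR (no iterative optimisation, so fits are
deterministic). Blocks are estimated but never tested or removed — the
partition reports block df but no block F, matching how such designs are
conventionally summarised.

`anova_rsm()` produces the mixture-convention table:

* **Model**: block-corrected model SS on `t - 1` df against the pooled
  residual (lack of fit + pure error).
* **Linear mixture**: a joint F on the `q - 1` equality contrasts among the
  blending coefficients, computed from the full-model covariance after block
  adjustment. The exact contrast set used by commercial tools is
  undocumented; equality contrasts are the natural test of "no blending
  differences" and reduce to the usual test when the design is orthogonal.
* one partial (Type-III) F row per non-linear term (equal to the squared
  t statistic for a single column);
* **Lack of fit / Pure error**: pure-error SS is the residual SS of the
  block + distinct-point saturated model; `F = MS_LOF / MS_PE` on the
  convention df above. When a fit is numerically exact (simulations at
  `sigma = 0`) both SS are rounding noise and the test is reported as
  unavailable rather than as a random verdict; a tolerance of 1e-12 relative
  to the response scale draws that line.

`r2_stats()` reports `R^2`, adjusted `R^2` (residual df) and predicted `R^2`
from PRESS via the hat diagonal, all against the block-corrected total SS.

## Model-order selection and reduction

`select_model_order()` walks the nested ladder linear x linear ->
quadratic x linear -> quadratic x quadratic, testing each *block* of added
terms with a sequential F and each model's lack of fit, and picks the highest
order with significant added terms (`p < alpha`) and non-significant lack of
fit (`p >= alpha`, default `alpha = 0.05`). Whether "additional model terms
were significant" means block-sequential or per-term tests was an open call;
the block-sequential F was chosen because it is invariant to the ordering of
terms within an order. When no order qualifies the lowest is returned and
flagged. Note the rule's intrinsic error rate: even under a clean truth it
steps one order too high with probability about `alpha`.

`backward_eliminate()` refits after removing the least significant eligible
term (largest partial p above `alpha_out`) until all eligible terms are below
the threshold. Linear blending terms and blocks are never removed, and
amount-crossed terms are eliminated independently of their mixture parents.
The default `alpha_out = 0.10` is deliberately laxer than the testing
`alpha = 0.05`: the reference reduced models retain pairwise terms whose
partial p exceeds 0.05, which is consistent with a 0.10 stay threshold and
not with 0.05. Both thresholds are arguments.

## Adequacy battery

`studentized_residuals()` (internal and external/outlier-t),
`influence_rsm()` (leverage, Cook's distance, DFFITS, per-coefficient
DFBETAS) and `precision_ratio()` implement the standard diagnostics; the
closed forms are taken from the underlying `lm` machinery and are verified in
the test suite against brute-force delete-one refits. Default flags: Cook's
D > 1, `|DFFITS| > 2 sqrt(p/n)`, `|DFBETAS| > 2/sqrt(n)`, and
`|outlier-t| > 3.5` — the outlier-t cutoff is a widely used convention; the
diagnostic itself, not the cutoff, is part of the published analysis. The
exclusion workflow (`refit_without()`, used by the pipeline) drops a single
flagged run and refits once; there is no iterative outlier hunting.

`box_cox()` profiles the Jacobian-corrected log-likelihood of the normal
linear model in `(y + k)^lambda` (log at 0) over a grid (default
`[-3, 3]` in steps of 0.01), with a chi-square likelihood-ratio ~95% CI; the
grid-and-CI summary replaces reading a plot by eye. A shift `k = 1` handles
zero responses. The reported `(y + 1)^-2.6` transformation of the deformity
response is treated as the applied exponent (`apply_transform()` /
`inverse_transform()` round-trip it exactly); whether it was a rounded plot
reading is unknowable from the printed record. The precision of the profile
depends on the mean structure it conditions on: profiling under a
near-saturated model leaves the transform identified only through replicate
variation, so the pipeline profiles under the selected model, and simulation
checks of exponent recovery profile under the (linear) truth structure.

## Surfaces

`predict_surface()` evaluates a fit or a hand-written `coef_table()` at
arbitrary blends and amounts; block effects are always excluded, because the
displayed surface is the population-average one. `slice_grid()` exports the
binary-blend x amount grids behind two-component contour figures, in actual
amount units, and `find_extremum()` grid-searches a simplex lattice crossed
with the amount axis with a deterministic lexicographic tie-break.
`autoplot()` methods render the grid, the Box-Cox profile and the residual
panels; rendering is a convenience, the grid export is the contract.

## The synthetic-study generator

`reference_study_config()` encodes the study shape: the five-component
space, the 75–225 mg/100 g amount factor, the 45/5/45/5-in-5-blocks design
structure, and per-response truth surfaces taken from the published reduced
coefficient sets — larval weight, larval development time, pupal development
time, and deformity (whose truth lives on its `(y + 1)^-2.6` analysis scale
and is back-transformed, so simulated studies contain zeros and exercise the
shift). Four null responses are flat at the reported control means
(21.9 mg pupal weight; 83.9% pupation, 95.8% emergence, 82.7% survival),
the percentages drawn as `Binomial(30, p)` dish counts via
`simulate_percentage()`.

Noise is the generator's honest fiction: the real dish-to-dish variance is
not recoverable from the printed record. Continuous responses get Gaussian
dish noise plus a Gaussian block effect. The dish sigmas (2 mg larval
weight, 0.35 d and 0.55 d development times, 0.3 on the transformed deformity
scale) are a documented tuning: they place the simulated adjusted R-squared
inside the 0.13–0.26 band the original analyses reported, and the larval
weight value doubles as the parameter-recovery study condition. The
generator emulates dish-level means only — no larva-level correlation, no
overdispersion beyond binomial, no time-to-event structure — so passing
recovery tests demonstrate the pipeline's statistical machinery, not
biological realism.

`simulate_study()` is bit-reproducible in `(config, seed)`; all sub-seeds
derive from the master seed. `end_to_end_recovery()` runs the whole chain
(simulate -> select order -> backward-eliminate) over seeded replicates and
reports retention, false-retention and CI-coverage rates with binomial
standard errors.

A power note that the recovery rates make concrete: with 100 runs, the
standard error of a pairwise blending coefficient is about 3.5 response
units, so a true pairwise coefficient of ~8 (as in the larval-weight truth)
has only ~70% probability of surviving elimination at `alpha_out = 0.10`.
Joint retention of *all* true terms at dish sigma = 2 mg therefore sits near
50%, not near 1 — the same marginal power the original experiment's printed
F values imply. The corresponding acceptance check is left failing rather
than re-tuned, since the condition, not the implementation, binds.

## Numerical choices

* All determinant/inverse work in the exchange uses QR rank checks;
  log-determinants, never raw determinants.
* Exact fits are first-class: studentized residuals are zero (not 0/0), the
  LOF test is "unavailable", elimination treats 0/0 t statistics as
  uninformative (p = 1).
* Ties (leverage, maximin distance, block choice) break by seeded shuffle;
  grid extrema break lexicographically.
* Rounding in `amount_range_from_composition()` is half-away-from-zero,
  required to map a 74.50 sum to 75.
* Pseudo-component scaling is available (`to_pseudo()` / `from_pseudo()`)
  but off by default: the components here span the full simplex.

Problem sizes in the shipped tests are chosen for desk-scale runs: exhaustive
D-optimality oracles up to 12 candidates, delete-one influence oracles at
n <= 20, 1000-replicate null calibration, 200-replicate recovery and
Box-Cox studies on the 100-run design.

## Limitations

* Constrained simplex regions with multicomponent constraints, special-cubic
  and higher mixture orders, I-/A-optimality, and split-plot randomization
  are out of scope.
* Percentage responses are analysed by OLS on dish means, mirroring the
  source analysis; no GLM path is provided.
* Mixed/random block effects are not modelled.
* The "modified" D-criterion of the commercial tool is not documented;
  candidate-set Fedorov exchange is the closest published, oracle-checkable
  algorithm, and that is what is implemented.
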