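# mixamount

Design and analysis of **mixture-amount experiments**: studies in which both
the *composition* of a blend (component proportions `x_1, ..., x_q` summing
to 1) and the *total amount* applied vary. The package was built around a
diet study on tephritid fruit-fly (*Anastrepha ludens*) development in which
five apple phenolics — (+)-catechin (Ca), phloridzin (Ph), rutin (Ru),
chlorogenic acid (ChA) and *p*-coumaric acid (pCoA) — were blended at total
concentrations of 75–225 mg per 100 g of artificial diet, but every piece is
generic: it is aimed at anyone who needs to build a blocked D-optimal
mixture-amount design and push the measured responses through the standard
response-surface analysis.

## The model

The response surface is a crossed Scheffé polynomial in the proportions and
the coded amount `A ∈ [−1, +1]`:

    E[y] = Σ_i β_i x_i  +  Σ_{i<j} β_ij x_i x_j            (mixture part)
         + Σ_i γ_i x_i A + Σ_{i<j} γ_ij x_i x_j A + ...    (amount crossing)

with no intercept (the constraint `Σ x_i = 1` absorbs it), fitted by least
squares with fixed sum-to-zero block effects. A pure component's prediction
at mid amount equals its blending coefficient `β_i`. The analysis follows the
standard response-surface workflow: sequential selection of the polynomial
order, mixture-convention ANOVA with a lack-of-fit / pure-error split,
backward elimination, adequacy diagnostics (outlier-t, Cook's distance,
DFFITS, DFBETAS, Box-Cox transformation profiles, prediction precision), and
surface prediction/export.

A synthetic-study generator (`reference_study_config()`,
`simulate_study()`) reproduces the shape of the motivating experiment — the
100-run, 5-block design and eight dish-level responses with published
reduced-model coefficient sets as truth surfaces — so the whole pipeline is
testable without any raw data.

## Worked example

```r
library(mixamount)

space  <- component_space(c("Ca", "Ph", "Ru", "ChA", "pCoA"))
amount <- amount_factor(75, 225, units = "mg/100g")

# 45 D-optimal model points + 5 lack-of-fit + 45 replicates + 5 centers,
# 5 blocks, built for the full quadratic x quadratic crossed basis
design <- build_study_design(space, amount, seed = 11)
df_partition(design)
#>   block_df model_df lack_of_fit_df pure_error_df total_df
#> 1        4       44              6            45       99

# a synthetic study with the published coefficient sets as truth
study <- simulate_study(reference_study_config(), seed = 11, design = design)

sel <- select_model_order(study, "larval_weight")
sel[, c("mixture_order", "amount_order", "n_terms", "seq_p", "lof_p", "chosen")]
#>   mixture_order amount_order n_terms    seq_p lof_p chosen
#> 1             1            1      10 0.000241 0.254 FALSE
#> 2             2            1      30 0.0169   0.844 TRUE
#> 3             2            2      45 0.597    0.925 FALSE

fit <- backward_eliminate(attr(sel, "chosen_fit"), alpha_out = 0.10)
dplyr::filter(tidy(fit), type != "block")
#>    term       type     estimate std.error statistic  p.value
#>  1 Ca         blending    21.9      0.576     38.0  1.08e-54
#>  2 Ca*[Conc]  amount       1.86     0.655      2.84 5.72e- 3
#>  3 Ca*ChA     mixture    -13.6      3.46      -3.93 1.72e- 4
#>  4 Ph         blending    19.0      0.615     31.0  9.76e-48
#>  5 Ph*[Conc]  amount       1.24     0.665      1.86 6.58e- 2
#>  6 Ph*Ru      mixture     11.8      3.44       3.43 9.36e- 4
#>  7 Ph*ChA     mixture     -6.18     3.43      -1.80 7.54e- 2
#>  8 Ru         blending    19.3      0.579     33.4  2.86e-50
#>  9 ChA        blending    21.8      0.671     32.5  2.20e-49
#> 10 ChA*[Conc] amount      -1.28     0.659     -1.95 5.49e- 2
#> 11 ChA*pCoA   mixture    -10.8      3.44      -3.13 2.38e- 3
#> 12 pCoA       blending    17.5      0.573     30.6  2.75e-47

glance(fit)[, c("r.squared", "adj.r.squared", "pred.r.squared",
                "p.value", "lof.p.value")]
#>   r.squared adj.r.squared pred.r.squared       p.value lof.p.value
#> 1     0.494         0.428          0.279 0.00000000880       0.946
```

Reading the output: the selection trace steps from linear×linear to
quadratic×linear (the added quadratic block is significant, `p = 0.017`, and
lack of fit is not, `p = 0.84`) and declines quadratic×quadratic. Backward
elimination keeps the five blending coefficients (always retained), and the
surviving interactions recover the simulated truth: the antagonistic blends
`Ca*ChA` (−13.6; truth −10.07) and `ChA*pCoA` (−10.8; truth −12.68), the
synergistic `Ph*Ru` (+11.8; truth +14.47), and the concentration effect
`Ca*[Conc]` (+1.86; truth +1.76). A blending coefficient is the predicted
response of the pure component: pure catechin diets give ~22 mg larvae, and
negative pairwise terms mean those blends depress larval weight below the
linear blend of the pure components.

Surface export and diagnostics:

```r
predict_surface(fit, data.frame(Ca = 0, Ph = 0, Ru = 0, ChA = 0.5,
                                pCoA = 0.5, amount = 150))
slice_grid(fit, c("ChA", "pCoA"))       # long-format grid; autoplot() draws it
influence_rsm(fit)                      # per-run leverage/Cook/DFFITS/DFBETAS
box_cox(design, study$larval_weight)    # transformation profile
run_pipeline(study)                     # the whole chain for every response
```

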