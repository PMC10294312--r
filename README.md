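# bocprev

Decision-analytic modelling of breast and ovarian cancer prevention in
women with BRCA1/2 mutations.

Carriers of pathogenic BRCA1/2 variants face lifetime breast cancer risks
of 60–90% and ovarian cancer risks of 20–40%, and must weigh intensified
surveillance (IS) against risk-reducing surgery — prophylactic bilateral
mastectomy (PBM) and/or salpingo-oophorectomy (PBSO) — performed at
different ages. `bocprev` is for health-economic modellers and HTA
analysts who need a tested, scriptable implementation of this evaluation:
a deterministic annual-cycle Markov cohort model of the two-cancer
natural history with a full cost-effectiveness layer.

## The model in brief

A cohort starts well at age 30 and moves annually through 96 states:
undetected stage-specific cancer (breast pT1–pT4, ovarian FIGO I–IV),
detected cancer in ten-year survival tunnels, survivor, and three
absorbing death states. Annual stage-1 onset probabilities $p_c(a)$
(decade-band endpoints, linearly interpolated) compete from the well
state on the rate scale; prevention strategies act through relative
risks on onset (PBM: RR 0.070 for breast; PBSO: 0.500 breast / 0.038
ovarian; both: 0.039 breast), a one-time surgery cost and one-cycle
disutility, and halved surveillance cost after PBM. Tunnel survival uses
the constant-rate transform $S_5^{1/5}$ of stage-specific five-year
survival; background mortality is the female all-cause life table minus
breast/ovarian mortality on the rate scale. Outcomes per strategy are
(un)discounted LY, QALY and lifetime 2022-€ cost; strategies are
compared through efficiency frontiers (strong + extended dominance) with
stepwise ICER/ICUR against a 90,000 €/LY-or-QALY willingness-to-pay.
Companion modules calibrate the natural history to incidence and
stage-distribution targets and run one-way deterministic sensitivity
analyses. Because the official DESTATIS/RKI mortality series are not
redistributable, the package ships synthetic Gompertz–Makeham
equivalents anchored to published German female mortality levels
(`inst/extdata/*_synthetic.csv`).

## Worked example

```r
library(bocprev)

params   <- default_parameters()      # Tables of the base case + synthetic life table
analysis <- run_base_case(params)     # all 16 strategies, frontiers, increments

subset(analysis$outcomes, strategy_id %in% c(1, 8, 11, 12),
       select = c(strategy_id, label, ly, qaly, cost_disc))
#>    strategy_id                  label       ly     qaly cost_disc
#> 1            1     Standard care (IS) 48.17158 41.13666  28776.45
#> 8            8       PBM + PBSO at 30 54.42060 49.60092  21627.56
#> 11          11 PBM at 30 + PBSO at 35 54.10089 49.34996  21477.44
#> 12          12 PBM at 30 + PBSO at 40 53.77455 49.01933  21382.67

analysis$frontier_ly$chain
#>   id   effect     cost step_icer cost_effective
#> 1 12 26.73249 21382.67        NA           TRUE
#> 2 11 26.85370 21477.44   781.874           TRUE
#> 3  8 26.98414 21627.56  1150.817           TRUE
```

Reading this: every surgery strategy costs less than surveillance alone
(IS keeps full-price screening for life and still pays for the most
cancers). Simultaneous PBM+PBSO at 30 (strategy 8) maximises life
expectancy — 6.25 undiscounted life-years gained over standard care —
while the serial schedules with PBM at 30 and PBSO at 35/40 (strategies
11/12) trail it closely at slightly lower cost; strategy 12 is the
least-costly non-dominated point and anchors both frontiers. The
stepwise ICERs along the frontier (782 and 1,151 €/LY here) are far
below the 90,000 € willingness-to-pay. The standard-care model validates
against published carrier risks: 72% breast, 21% ovarian, 94% either
cancer by age 70 (published: 68%, 21%, 90%).

```r
tr <- run_cohort(get_strategy(1), params)
100 * cumulative_risk_by_age(tr, "breast", 70)   # 72.1
100 * cumulative_risk_by_age(tr, "ovarian", 70)  # 21.4
```

Calibration and sensitivity analysis:

```r
targets <- make_calibration_targets(params, noise_sd = 0)  # or read_calibration_targets()
fit     <- calibrate_model(targets, init = params)
dsa     <- run_dsa(dsa_spec("discount_rate"), params)
```

See `vignette("prevention-model")` for the model's assumptions, the
calibration design and known limitations — in particular why
single-surgery strategies behave differently here than in published
evaluations (mutually exclusive cancer pathways funnel prevented risk
into the other cancer).

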