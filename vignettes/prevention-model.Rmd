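---
title: "A Markov cohort model of breast and ovarian cancer prevention in BRCA1/2 carriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of breast and ovarian cancer prevention in BRCA1/2 carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bocprev)
```

## The decision problem

Women carrying pathogenic BRCA1/2 variants face high lifetime risks of
breast and ovarian cancer and must choose between intensified surveillance
(IS) and risk-reducing surgery — prophylactic bilateral mastectomy (PBM)
and/or prophylactic bilateral salpingo-oophorectomy (PBSO) — at different
ages. `bocprev` implements a deterministic annual-cycle Markov cohort
model of the joint natural history of the two cancers from age 30 to age
100 and evaluates sixteen prevention strategies on life years (LY),
quality-adjusted life years (QALY) and lifetime cost from a health-system
perspective, with efficiency-frontier cost-effectiveness analysis,
natural-history calibration, and one-way deterministic sensitivity
analysis.

## The state-transition model

The cohort starts with unit mass in the *well* state. Each cancer
pathway comprises four undetected stages (breast pT1–pT4, ovarian FIGO
I–IV), four detected stages split into ten *tunnel* years since
diagnosis, a survivor state (reached only after tunnel year 10), and a
cancer-death state; a shared other-cause death state completes the 96
states. The three death states are absorbing. The cancers are mutually
exclusive: onset competes only from the well state and a woman on one
pathway can no longer develop the other cancer (see *Limitations*).

Within a one-year cycle, events compose in a fixed order:

1. **Other-cause death.** Well and undetected states die with the
   cancer-adjusted background probability $q_\mathrm{other}$; survivor
   states use the unadjusted all-cause probability $q_\mathrm{all}$
   (survivors face general-population mortality); tunnel states are
   exempt because their registry-based survival already includes all
   causes of death (avoiding double counting).
2. **Tunnel survival.** Detected stage $s$ in year $y$ survives with
   probability $s(s, y)$; failures move to cancer death, year-10
   survivors to the survivor state.
3. **Detection, then progression.** Undetected mass is first detected
   with the stage-specific probability and enters tunnel year 1; the
   remainder progresses one stage. Detection-first composition also
   resolves rows whose printed detection and progression probabilities
   sum above 1 (undetected FIGO III: 0.72 + 0.99).
4. **Onset.** Well mass develops stage-1 cancer. The two annual onset
   probabilities $p_b, p_o$ (linearly interpolated inside their decade
   bands and multiplied by the strategy's current relative risks) compete
   on the rate scale: with $h_c = -\log(1 - \mathrm{RR}_c p_c)$, total
   onset is $1 - e^{-(h_b + h_o)}$, split in proportion to $h_b : h_o$.

The engine is fully deterministic; reruns are bit-identical.

## Parameters

All inputs live in a single validated container (`boc_params`), loadable
from a flat key–value CSV; `default_parameters()` loads the packaged
base case.

* **Onset schedules** — annual probabilities at the first and last
  integer age of each decade band, ages 20–99, per cancer. Interpolation
  is linear within a band and bands may be discontinuous at boundaries,
  the simplest faithful reading of banded endpoint data.
* **Progression / detection** — stage-to-stage and
  undetected-to-detected annual probabilities; terminal stages do not
  progress.
* **Survival** — five-year disease-specific survival per diagnosed stage
  (breast 99.3/87.6/59.5/26.2%; ovarian 87.1/70.4/35.0/15.5%) converted
  to the constant annual tunnel survival $S_5^{1/5}$ for years 1–10.
  Year-specific annual survival is published only as year-1 to year-10
  ranges; per-year values are not recoverable, so the constant-rate
  transform is the default and a configuration hook (`surv.*` keys, or
  `survival_vector_from_range()` for log-linear interpolation of a
  range) accepts full year-specific vectors.
* **Effect measures** — relative risks on onset after surgery: PBM 0.070
  (breast), PBSO 0.500 (breast) and 0.038 (ovarian), PBM+PBSO 0.039
  (breast). The combined breast RR uses the published joint estimate,
  not the product of the single-surgery values. PBM leaves ovarian risk
  unchanged.
* **Utilities** — well 0.92; diagnosed stage utilities in tunnel year 1;
  clinical remission 0.83 in tunnel years 2–10 and survivor states;
  undetected stages default to the detected-stage values (the
  approximation used for unpublished undetected-state utilities) and are
  overridable. During a surgery cycle the utility of well/undetected
  occupants is rescaled by $u_\mathrm{surgery}/u_\mathrm{well}$ and
  reverts the next year. Note the published PBSO surgery-cycle utility
  (0.95) *exceeds* the well utility (0.92), so a lone PBSO cycle is a
  small utility gain; this drives the QALY attractiveness of serial
  surgery.
* **Costs (2022 €)** — annual surveillance 608 € (halved after PBM, as
  breast MRI is dropped); one-time surgery costs (PBM 9,032, PBSO 3,099,
  both 12,131); one-time initial-treatment costs at diagnosis by cancer,
  severity class (breast pT1–3 vs metastatic; ovarian FIGO I–II vs
  III–IV) and surgery history; annual follow-up costs for 10 (breast)
  and 5 (ovarian) years after diagnosis; ovarian tunnel years 6–10 and
  survivor states pay surveillance only; a one-time palliative cost
  (12,103 €) at every cancer death. Surgery history at diagnosis is
  deterministic in a cohort model (a surgery scheduled at age $s$ applies
  to everyone still well or undetected at $s$), so history-specific
  costs need no extra states except a two-way split of the survivor
  states by PBM history for surveillance costing.
* **Background mortality** — a female all-cause life table adjusted by
  removing age-specific breast+ovarian mortality on the rate scale,
  $q_\mathrm{other} = 1 - \exp(-(h_\mathrm{all} - h_\mathrm{cancer}))$,
  rather than naive probability subtraction.
* **Analysis** — 3% annual discounting of costs and effects, anchored at
  the age-30 evaluation start; willingness-to-pay 90,000 €/LY or QALY;
  ages 30–100, one-year cycles, no half-cycle correction, rewards
  credited to the state occupied at cycle start, event costs (surgery,
  initial treatment, palliative care) to the cycle in which they fire.
  Mass still alive at age 100 receives its final cycle and is then
  truncated (negligible at these mortality levels).

## Strategies

`strategy_catalog()` returns the sixteen schedules: standard care (IS
only), PBM alone at 30/35/40, PBSO alone at 30/35/40, simultaneous
PBM+PBSO at 30/35/40, and six serial combinations, including the one
PBSO-first schedule (PBSO 35, PBM 40). Relative risks apply from the
surgery cycle onward; both surgeries at the same age fire as one
combined event. Surgeries apply only to mass still in well or undetected
states — women already diagnosed do not undergo prophylactic surgery,
and a diagnosis cancels the remaining scheduled surgery for the other
cancer (an explicit assumption; the source guidance is silent).

```{r catalog}
run_base <- run_base_case(default_parameters())
run_base$frontier_ly$chain
```

## Cost-effectiveness analysis

Strategies are compared as (effect, cost) points — discounted for
ratios, undiscounted for effectiveness reporting — on both the LY and
QALY scales. `efficiency_frontier()` removes strongly dominated points
(weak dominance; identical duplicates resolve to the lower strategy id)
and applies extended dominance until stepwise ICERs are strictly
increasing, which yields the lower-left convex hull. Every excluded
strategy carries a certificate (the dominating strategy, or the mixing
pair). The frontier is verified in the test suite against a brute-force
convex-combination oracle on 1,000 random 16-point clouds.

## Calibration

Disease-progression parameters are calibrated to age-band diagnosis
incidence and stage distribution at detection under standard care.
Published inputs do not include the original calibration protocol, so
the module is a documented generic design:

* **Objective** — weighted sum of squared errors, weights defaulting to
  inverse squared target magnitude (relative error).
* **Parameterisation** — one multiplicative scale per onset decade band
  (both endpoints move together) and one scale each per cancer for the
  progression and detection vectors. Finer structure is not identifiable
  from these targets: a band contributes one incidence target but two
  endpoint probabilities, and three free stage fractions cannot pin
  seven progression/detection values. Users with richer targets can
  supply them via `read_calibration_targets()`.
* **Hierarchy** — stage A fits onset scales to incidence by damped
  proportional fitting (each band's scale is multiplied by its
  target/predicted ratio), which converges in a few passes because a
  band's incidence responds mostly to its own onset level; a pure
  simplex search here crawls along the strongly coupled
  onset–detection ridge and was replaced after proving impractically
  slow. Stage B fits progression and detection scales by Nelder–Mead on
  the log scale against the full objective. Stages alternate (default 12
  rounds) until the improvement falls below tolerance; stage A retains
  the best visited scale set, so the outer objective history is
  non-increasing. Everything is deterministic given the initial
  parameter set.
* **Recovery experiment** — `make_calibration_targets()` generates
  targets from known parameters (optionally with seeded relative noise).
  The test suite perturbs onset bands by ±30% and progression/detection
  downward by up to 30% — boundary values (undetected pT4 detection
  1.00, FIGO III→IV progression 0.99) make upward multiplicative
  perturbations unrecoverable by construction — and requires recovery
  within 5% relative; in practice the fit returns well under 1%.

## Sensitivity analysis

`run_dsa()` varies one parameter group at a time: all utilities ×0.8–1.2,
all effect RRs ×0.8–1.2 (clipped at 1), all costs ×0.5–2, discount rate
1–10%. The joint-group reading (one common multiplier per group) is an
assumption; a per-parameter tornado can be built by calling
`apply_scenario()` on hand-modified parameter sets. Each scenario re-runs
all strategies and both frontiers and flags changes in frontier
membership and strategy rank order against the base case.

## The synthetic mortality inputs

The official German female life table and cancer-mortality series are
not redistributable here, so the packaged fixtures
(`*_synthetic.csv`) are generated by `make_life_table()`: a
Gompertz–Makeham all-cause hazard fitted once to published German female
period-mortality anchors (q35 ≈ 4·10⁻⁴, q50 ≈ 2·10⁻³, q70 ≈ 1.15·10⁻²,
q90 ≈ 0.135; life expectancy at 30 ≈ 53 years), and a piecewise-linear
breast+ovarian share of all-cause mortality peaking near 24% in midlife.
The generator reproduces the *level and shape* of the real series but
not their cohort effects, vintage revisions, or the exact official
values; results that hinge on fine mortality detail (notably stepwise
ICERs, which are ratios of small differences) therefore carry that
uncertainty, while cumulative risks and life-year totals are robust to
it. All fixtures load through the same readers as user data.

## Numerical choices

* Mass balance is enforced every cycle (|row sum − 1| < 10⁻¹⁰; any
  negative mass is an error, not a warning).
* Onset competition uses exact rate-scale splitting (`log1p`/`expm1`),
  so tiny probabilities do not lose precision.
* The frontier walk uses exact comparisons; equal-effect ties are
  removed by weak dominance with the lower-id tie-break before ICERs are
  formed, so no division by zero can occur.
* Problem sizes: 96 states × 71 annual cycles per run; 16 strategies per
  analysis; the packaged test suite verifies the frontier on 1,000
  random point clouds and runs one full calibration recovery.

## Limitations

* **Mutual exclusivity funnels risk.** Because onset competes only from
  the well state, suppressing one cancer's onset keeps mass at risk of
  the other: under PBM alone, lifetime ovarian incidence nearly trebles
  and life expectancy *falls* relative to standard care, whereas the
  published evaluation reports every surgery strategy as beneficial.
  The published natural-history validation risks (breast 68%, ovarian
  21%, combined 90% by age 70) *are* reproduced, so this is a structural
  consequence of the exclusive-competition design interacting with the
  large calibrated late-life onset probabilities, not a parameter error.
  Conclusions about single-surgery strategies should not be read off
  this implementation; combined-surgery strategies, which suppress both
  onsets, match the published pattern well. For the same reason,
  life-year monotonicity in a single RR holds only on a single-pathway
  configuration, and the test suite checks it there.
* **Survivor mortality** uses the unadjusted all-cause life table
  (general-population mortality for survivors); whether lifelong
  surveillance continues in the survivor state is assumed, not sourced.
* **No recurrence states, no BRCA1/BRCA2 split, no probabilistic
  sensitivity analysis, no uptake/adherence modelling** — all outside
  the model's scope by design.
* **Discount anchor.** Discounting is anchored at the age-30 evaluation
  start. Published absolute discounted costs appear to be anchored three
  decades earlier (they match ours after multiplying by 1.03⁻³⁰);
  ICERs are anchor-invariant, absolute discounted totals are not.
* Passing tests demonstrate internal consistency, analytic correctness
  of the engine and frontier, and reproduction of the published
  qualitative structure under a synthetic life table; they do not
  demonstrate forecast accuracy for real German mutation carriers.
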