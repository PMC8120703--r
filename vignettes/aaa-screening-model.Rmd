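---
title: "A Markov cohort model for one-time AAA ultrasound screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for one-time AAA ultrasound screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaascreen)
```

## The decision problem

An abdominal aortic aneurysm (AAA) — an aortic diameter above 3 cm — is
usually asymptomatic until it ruptures, and rupture is fatal for most
patients who do not reach emergency repair. A one-time ultrasound screen of
men at age 65 detects aneurysms early, puts small and medium ones under
surveillance, and routes large ones (> 5.5 cm) to elective repair, which has
far lower 30-day mortality than emergency repair after rupture. The question
the package answers is economic: per invited man, how much does the
screening program cost, how many quality-adjusted life-years (QALYs) does it
buy, and is the incremental cost-effectiveness ratio (ICER) acceptable at a
given willingness to pay?

`aaascreen` implements this as a Markov cohort model of two identical
cohorts of 65-year-old men — one invited to a single screen, one not —
followed in 3-month cycles over a lifetime horizon, from the payer's
perspective, with all inputs specific to the Iranian health system (costs in
US$ at the official exchange rate, optionally re-expressed in
purchasing-power-parity dollars).

## Model structure

The cohort occupies eleven mutually exclusive statuses: no AAA; undetected
small / medium / large AAA; detected small / medium / large AAA; post-EVAR
and post-OSR (the two repair procedures — endovascular and open surgical
repair); death from AAA; and death from other causes. Internally the
detected-large status is split into an *operable* track, which proceeds to
elective repair, and an *inoperable* track, contraindicated for surgery,
which keeps the untreated rupture rate; reporting aggregates the two so the
published eleven statuses are recoverable (`aggregate_states()`).

Within each cycle, events resolve in a fixed order:

1. **Other-cause death** (from the life table, converted to the cycle
   length) applies first, as a competing risk.
2. **Rupture**, at the state-specific 3-monthly rate. A fraction of
   ruptures (36.8% at the point estimate) reaches emergency surgery, which
   splits EVAR/OSR (5% / 95%) and then applies 30-day mortality; everyone
   else dies of the rupture in-cycle. Thirty-day deaths are attributed to
   AAA death within the surgery cycle, since 30 days is shorter than one
   cycle.
3. **Opportunistic detection** moves undetected survivors to the matching
   detected state (1.14% per cycle). An undetected large aneurysm detected
   opportunistically enters the operable/inoperable split immediately.
4. **Growth** advances small to medium and medium to large, on the
   detected and undetected tracks alike; growth into the detected-large
   status applies the operable/inoperable split (91.8% / 8.2%).
5. **Elective repair** applies to the detected-large operable state: its
   occupants — having survived steps 1–2 — undergo repair during the cycle
   (EVAR/OSR 80% / 20%, then 30-day mortality), leaving for a
   post-operative state or AAA death.

The published description gives no within-cycle ordering; this one is fixed,
documented here, and exercised by an independent micro-simulation oracle in
the test suite that implements the same sequence with per-walker draws. The
operable/inoperable split is applied once, on *entry* to the detected-large
status: a per-cycle re-draw would let the 8.2% contraindicated fraction
drain into surgery, contradicting the dedicated rupture rate that status
carries.

The strategies share identical dynamics; they differ only in the initial
distribution (attendees' aneurysms start detected — 75% attendance at the
point estimate) and in the one-time screening cost. Opportunistic detection
operates in both arms.

## Payoffs, discounting, half-cycle correction

Surveillance of detected small ($9.79) and medium ($19.58) aneurysms is a
per-cycle state cost. Screening ($39.17 per attendee), repairs (EVAR
$12,433, OSR $6,442, the same price electively or in emergency) and
reoperations are event costs attached to flows. Reoperation applies for two
years after EVAR (6.3%/year) and one year after OSR (3.9%/year), affects
cost only, and is accumulated by convolving post-operative inflows with
other-cause survival across the eligibility window.

Utilities are EQ-5D age-band values (0.83 / 0.81 / 0.79 / 0.74 for 65–69 /
70–74 / 75–79 / 80+) with a permanent −0.02 disutility in the post-operative
states. QALYs and life-years accrue on half-cycle-corrected occupancy — the
trapezoid of successive cycle-boundary occupancies, i.e. transitions are
assumed to happen mid-cycle — while one-off event costs are dated to their
cycle without correction (the screen occurs at t = 0 by construction).
Discounting compounds the 3% annual rate per cycle,
$(1+r)^{-t/4}$ for cycle $t$.

The horizon runs from 65 to a terminal age of 100, where the life table
forces $q = 1$ and one closing cycle absorbs all survivors; with 3-month
cycles that is 141 transitions. The terminal cap loses a negligible tail
(survival to 100 is under 2% on the bundled table) and keeps the matrices
finite.

## Parameters and derived distributions

All inputs live in one configuration (`aaa_parameters()`, or YAML via
`read_parameters()`); each uncertain parameter is a
`{point, low, high, family}` block. Ranges are interpreted as central 95%
intervals — the source material never states what its ranges mean, and this
is the standard convention in cost-effectiveness modelling — so
$\sigma = (\text{high} - \text{low})/(2 \times 1.96)$, and hyperparameters
follow by method of moments: beta from $(\mu, \sigma)$ on the unit interval,
gamma with shape $(\mu/\sigma)^2$, normal directly. The three aneurysm size
proportions (0.789 / 0.12 / 0.091) are drawn jointly from a Dirichlet whose
concentration is the proportions scaled by an effective sample size,
defaulting to 100 since no dispersion is published for them. Utilities and
the post-operative disutility are published without ranges and stay fixed in
the probabilistic analysis. The discount rate is a special case: fixed in
the probabilistic analysis but varied 0–6% in the one-way analysis, so a
`fixed` family here means "not sampled" and may still carry a range.

Probabilities published per year (the reoperation rows, the life table) are
converted to the cycle length by `annual_to_cycle_probability()`,
$1 - (1-p)^{1/4}$; the growth, rupture and detection probabilities are
already 3-monthly and are used as printed.

## Mortality input

Age-specific other-cause mortality is the one externally sourced input. The
package reads single-year or abridged (5-year) `age,qx` tables
(`read_life_table()`) and generates synthetic Gompertz–Makeham tables
(`synth_life_table()`), $q_x = 1 - \exp(-(\lambda + a e^{bx}))$. The bundled
default (`iran_male_life_table()`) is such a synthetic table — Makeham level
0.001, scale 3.06901e-5, rate 0.1 per year — calibrated once so that male
life expectancy at 65 equals 15.0 years, in line with published Iranian
values; the national table behind the original analysis is not
redistributable, so this is a labelled stand-in, and absolute per-strategy
results carry that uncertainty (incremental results much less so).

## What the analyses produce

`aaa_cea()` runs both cohorts and returns per-strategy discounted cost,
QALYs and life-years plus the incremental comparison with standard
dominance handling; ICERs are only reported on the trade-off quadrants.
`run_dsa()` re-runs the whole pipeline at each ranged parameter's low and
high (one parameter at a time) and ranks the absolute ICER spread for a
tornado diagram, ties broken alphabetically. `run_psa()` draws all uncertain
parameters independently (except the jointly-Dirichlet size mix — no
correlation structure is published), runs both strategies under each shared
draw, and `ceac()` converts the draws into a cost-effectiveness
acceptability curve using strict net-monetary-benefit positivity
($\lambda \Delta Q - \Delta C > 0$; ties count as not cost-effective). Each
PSA draw gets its own RNG substream derived from the mandatory seed, so a
failed draw cannot shift its successors.

```{r base-case}
fit <- aaa_cea()
fit
```

```{r dsa, eval = FALSE}
dsa <- run_dsa()           # ~30 s: two full runs per ranged parameter
plot(dsa, base_icer = fit$incremental$icer_qaly)

psa <- run_psa(n = 1000, seed = 1)   # ~3 min
plot(ceac(psa))
```

## Numerical conventions and degenerate inputs

Transition-matrix rows are validated to sum to 1 within 1e-12 and cohort
mass is checked every cycle at the same tolerance. Probabilistic draws that
violate the parameter invariants (a negative normal cost draw, say) are
rejected and redrawn, up to 100 attempts. Structural zeros in the Dirichlet
stay exactly zero. A zero-prevalence, zero-incidence cohort collapses to
pure life-table survival and costs exactly the screening fee (screening
arm) or nothing (comparator) — both are asserted in the tests. Degenerate
ranges (low = point = high) yield point masses and zero one-way spread.

## Problem sizes used in the tests

The bundled checks run the full 141-cycle cohort model (fractions of a
second per run), a 1000-draw probabilistic analysis, and micro-simulation
cross-checks with 1e5–2e5 walkers over 40 cycles compared at 3 Monte-Carlo
standard errors — sizes chosen to make Monte-Carlo noise small relative to
the tolerances being asserted.

## Limitations

The synthetic mortality fixture reproduces a life-expectancy level, not the
age-shape of the true national table; absolute costs and QALYs per strategy
are sensitive to that shape. The model screens once at 65 (incident
aneurysms are never re-screened), has no female cohort, prices both repair
settings identically, bundles complication costs into procedure costs, and
attaches no mortality or state change to reoperation. PSA draws are
independent across parameters, which understates joint uncertainty if the
underlying evidence is correlated. The acceptability curve's location is
tied to the base-case ICER, so at thresholds near that value the curve is
sensitive to every structural convention listed above.
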