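# aaascreen

Cost-effectiveness analysis of a one-time, population-based ultrasound
screening program for abdominal aortic aneurysm (AAA) in 65-year-old men,
compared with no screening, built for health-economics analysts evaluating
screening policy in settings — such as Iran — where local costs and
willingness-to-pay thresholds differ sharply from the Western settings in
which AAA screening was originally shown to be cost-effective.

## The model

A Markov cohort model follows two identical cohorts of men from age 65 over
3-month cycles to a lifetime horizon. The cohort occupies eleven mutually
exclusive health statuses: no AAA; undetected and detected small
(3–4.4 cm), medium (4.4–5.4 cm) and large (> 5.5 cm) aneurysms;
post-endovascular (post-EVAR) and post-open (post-OSR) repair; death from
AAA; and death from other causes. Aneurysms grow small → medium → large,
may rupture at size-specific rates (rupture is fatal unless emergency
repair succeeds), and may be detected by the one-time screen or
opportunistically; detected large aneurysms go to elective repair unless
contraindicated. Costs (payer perspective, US$) and EQ-5D-weighted
life-years accrue per cycle with half-cycle correction and are discounted
at 3%/year:

- per strategy *s*: discounted cost C_s, QALYs Q_s, life-years L_s;
- incremental cost-effectiveness ratios
  ICER = (C_screen − C_none) / (Q_screen − Q_none), and per life-year
  analogously;
- one-way deterministic sensitivity analysis over every parameter range,
  ranked by ICER spread (tornado);
- probabilistic sensitivity analysis with distributions derived by method
  of moments from each point estimate and 95% range (beta / gamma / normal,
  joint Dirichlet for the size mix), summarised as a cost-effectiveness
  acceptability curve, P(λ·ΔQ − ΔC > 0) over willingness-to-pay λ.

All published model inputs ship as the default parameter set
(`aaa_parameters()`, or `inst/extdata/aaa_params.yaml`); age-specific
other-cause mortality comes from a life-table file, with a bundled
synthetic Gompertz–Makeham table calibrated to Iranian male life
expectancy at 65 (15.0 years) standing in for the non-redistributable
national table.

## Worked example

```r
library(aaascreen)
fit <- aaa_cea()          # bundled parameters + bundled life table
fit
#> One-time AAA ultrasound screening vs no screening
#>   no screening: cost $  295.06  QALY  9.1708  LY 11.4208
#>   screening:    cost $  433.40  QALY  9.1991  LY 11.4593
#>   incremental:  cost $  138.34  QALY  0.0283  LY  0.0385
#>   ICER: $4885 per QALY, $3589 per LY
```

Read: inviting one man to a single ultrasound costs the payer an extra
$138 over his remaining lifetime and buys 0.0283 quality-adjusted
life-years (about 10 quality-adjusted days), i.e. roughly $4,900 per QALY
gained — below a 1-GDP-per-capita threshold for Iran (~$5,600). In PPP
dollars multiply monetary results by `usd_to_ppp(1)` ≈ 2.633. Sensitivity
and probabilistic analyses:

```r
dsa <- run_dsa()                      # one-way analysis, tornado-ordered
head(dsa[, c("parameter", "icer_low", "icer_high", "spread")])
psa <- run_psa(n = 1000, seed = 1)    # probabilistic analysis
ceac(psa, thresholds = c(6000, 12000))
plot(ceac(psa))
```

The tornado is led by the cost of EVAR, the discount rate, the rupture
rate of undetected large aneurysms, AAA prevalence and the screening test
cost; the acceptability curve rises through ~0.5 near the base-case ICER.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "aaa-cea", package = "aaascreen")` with subcommands
`base-case`, `dsa`, `psa` and `fixtures`.

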