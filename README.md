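# dfucea

Cost-effectiveness modelling of adjunct wound care for diabetic foot ulcers
(DFUs), built as a reusable R package around a six-state monthly Markov
state-transition model.

## The problem

Patients with an uninfected DFU face a chronic, recurrent disease: ulcers
heal and recur, become infected, progress to gangrene, and can end in
amputation or death. The package evaluates adding a topical
macrophage-regulating agent (ON101 cream) to general wound care (GWC)
against GWC alone, from a health-care-sector perspective, for users who
need a transparent, testable, re-runnable version of that analysis: health
economists reproducing or stress-testing the published results, and
modellers reusing the engine on their own model-definition files.

## The model

A cohort starts in the uninfected-ulcer state `uDFU` and moves monthly
between six states — `healed`, `uDFU`, `iDFU`, `gangrene`,
`postamputation`, absorbing `death` — for 60 cycles (5 years). Both arms
share all transition probabilities except healing, which the intervention
improves by an odds ratio (OR 2.30). Discounted (3%/year,
$(1+r)^{-t/12}$ per cycle) outcomes per strategy are

* total cost $C$ (2021 USD): initial-ulcer cost + monthly state costs +
  one-time hospitalization costs on infection/amputation transitions +
  monthly drug cost while treated,
* QALYs $Q = \sum_t d_t \sum_s w_{s,t}\, u_s / 12$ with yearly utilities
  $u_s$,

and the decision statistic is the incremental cost-effectiveness ratio
$\mathrm{ICER} = \Delta C / \Delta Q$ against willingness-to-pay thresholds
of \$32,787 and \$98,361 per QALY. Around the base case the package
provides individual-level microsimulation for event counting, probabilistic
sensitivity analysis with cost-effectiveness acceptability curves, one-way
(tornado) and two-way deterministic sensitivity analyses, break-even
drug-cost search, scenario runs, report bundles, and a structural
calibration harness that resolves ambiguous printed transition rows against
the published outcome profile (see the methods vignette,
`vignettes/dfu-markov-model.Rmd`).

Models are plain YAML files; the shipped default
(`inst/extdata/on101_dfu.yaml`) encodes the published input table verbatim
with the calibration-selected interpretation, and a literal variant ships
alongside.

## Worked example

```r
library(dfucea)

m <- load_paper_parameters()     # checksum-guarded shipped model
bc <- run_base_case(m)
bc
#> <dfu_basecase> on101-dfu-calibrated
#>   GWC          cost     7795  LY 4.5037  QALY 3.6897
#>   ON101+GWC    cost     8260  LY 4.5056  QALY 3.7276
#> <dfu_ce_result> dCost 466, dQALY 0.0379: ICER 12291/QALY
```

Adding the cream costs an extra \$466 per patient over five years and gains
0.0379 QALYs — about \$12,300 per QALY gained, far below the \$32,787
"highly cost-effective" threshold. How robust is that to the drug's price
and efficacy?

```r
break_even_multiplier(m, "cost_saving")$multiplier
#> [1] 0.852356

two_way_threshold(m, c(304, 608, 912))
#>   drug_cost threshold_or    status
#> 1       304     1.284717 threshold
#> 2       608     1.586182 threshold
#> 3       912     1.916357 threshold
```

Below 85% of the base-case price the intervention is outright cost-saving;
at a price of \$912/month it stays cost-effective as long as the healing
odds ratio exceeds about 1.92. Parameter uncertainty is propagated with
`run_psa(m, 10000, seed = 1)` and summarized by `compute_ceac()`; event
counts come from `microsim_compare(m, 10000, seed = 1)`; a complete output
bundle (tables, figures, JSON manifest with all seeds) is written by
`generate_report()`.

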