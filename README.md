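# ehpgap

Tools to assess an **essential health package (EHP)** — the set of
cost-effective interventions a government selects to address its main causes
of disease burden, typically funded through a sector-wide approach (SWAp).
In countries without vital registration, the impact of an EHP cannot be
measured through health outcomes; what *can* be measured is its technical
efficiency: whether the chosen interventions are good value for money, and
whether enough of each service is being delivered to meet estimated need.
`ehpgap` implements that assessment as a tested, reusable pipeline for
health planners and researchers working with burden-of-disease estimates and
routine HMIS (health management information system) data.

## The model

**Burden and need.** Disease burden is measured in disability-adjusted life
years, DALY = YLL + YLD, with continuous time discounting at rate *r*:

    YLL = N · (1 − e^(−rL)) / r        (N deaths, L years of life remaining)
    YLD = I · DW · (1 − e^(−rd)) / r   (I incident cases, disability weight DW, duration d)

Diseases are ranked by DALYs, and each disease's annual incidence is
converted into the cases an intervention must serve per 1000 population:

    need a = 1000 · incidence · required_coverage / population

**Coverage and gap.** HMIS service counts become provision rates
*b* = 1000 · count / denominator, using the denominator population the
service targets (live births, under-5s, over-5s, adults 15+, females 15–45,
or total). The per-intervention **gap ratio** is *b/a*; the **aggregate
gap** across the package is totals-based,

    aggregate gap = Σb / Σa,

which weights interventions by volume and is *not* the mean of the row
ratios (0.68 vs 0.66 on the packaged table). A service is overprovided when
its ratio, rounded to two decimals, exceeds 1.00.

**Cost-effectiveness screen.** Each intervention's published $/DALY value is
classed against a threshold (default $150/DALY, the conventional cutoff for
low-income settings; strictly below = cost-effective; ranges like $3–12 are
judged by their upper bound) and crossed with EHP membership and whether it
targets a top-20-burden disease, yielding the candidate list of
cost-effective interventions not yet in the package.

**Funding.** Per-capita expenditure is compared with the per-capita required
cost of the package: coverage fraction, multi-year mean and percent change,
kept separate by accounting scope (SWAp-partner funding excludes households,
NGOs and non-SWAp donors and is not comparable with national totals).

The package ships plain-CSV transcriptions of the Malawi 2008 assessment
tables (`ehp_fixture()`) and a synthetic-data generator with retained ground
truth (`synthetic_config()`, `simulate_ehp_inputs()`) for end-to-end
validation.

## Worked example

```r
library(ehpgap)

gap <- ehp_fixture("gap")   # the 49-intervention Malawi 2008 gap table
g <- classify_provision(build_gap_table(
  data.frame(intervention = gap$intervention, need_per_1000 = gap$need_a),
  data.frame(intervention = gap$intervention, rate_per_1000 = gap$provision_b)))
g
#> Gap analysis: 49 interventions
#> # A tibble: 49 × 5
#>   intervention      need_a provision_b ratio class
#> 1 Full immunization   58.5        41.9  0.72 underprovided
#> 2 Measles             45.1        39.4  0.87 underprovided
#> 3 ARI in under-5s    140          68.1  0.49 underprovided
#> 4 Malaria - bednets   91.8        91.8  1    met
#> 5 Malaria - under 5  171.        196.   1.14 overprovided
#> # ℹ 44 more rows
#> Total need 1931.6, total provision 1311.3 per 1000; aggregate gap 0.68
```

By 2007/08 the package delivered 1311.3 of the 1931.6 cases per 1000
population it needed to serve — 68% of estimated need. Two malaria treatment
services were overprovided (ratios 1.14 and 1.41); the worst-served
interventions provided under a tenth of need:

```r
flag_severe_gaps(g, 0.10)[, 1:4]
#>   intervention                    need_a provision_b  ratio
#> 1 Prevention of MTC transmission    12.2         0.6 0.0492
#> 2 Newborn Complications              9.8         0.8 0.0816
#> 3 Treatment of Dehydration in U5s  292          25.5 0.0873
```

Funding tells the same story: SWAp-partner expenditure per capita rose 70.9%
over the period ($7.9 → $13.5) but still covered under half of the revised
$28.6 per-capita cost of the package:

```r
funding_summary(ehp_fixture("funding"))
#>   scope          first_year last_year first_expenditure_pc last_expenditure_pc pct_change
#> 1 swap_ehp       2002/03    2007/08                    7.9                13.5       70.9
#> 2 national_total 2005/06    2005/06                   25                  25         NA
```

`run_full_assessment()` orchestrates all stages from a YAML run
configuration and writes `gap.csv`, `ce_classification.csv`,
`funding_summary.csv` and a machine-readable `headline.json`; a thin CLI
wrapper lives at `inst/scripts/ehp-assess.R`.

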