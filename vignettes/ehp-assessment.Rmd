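---
title: "Assessing an essential health package: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing an essential health package: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehpgap)
```

## The assessment problem

An essential health package (EHP) is the set of interventions a government
selects, usually under a sector-wide approach (SWAp), to address its main
causes of disease burden. Where vital registration and morbidity surveys are
absent, outcomes cannot be measured, so the package is assessed on technical
efficiency instead: are the chosen interventions good value for money, and
is enough of each service delivered to meet estimated need? `ehpgap`
implements that assessment in five stages — burden and need, provision
rates, the gap analysis, the cost-effectiveness screen, and funding coverage
— each exposed as plain functions over tibbles so every stage can be run,
inspected and tested in isolation.

## Burden and need

Burden is measured in disability-adjusted life years. Both components use
continuous discounting of a constant stream of healthy years:

$$\mathrm{YLL} = N \frac{1 - e^{-rL}}{r}, \qquad
  \mathrm{YLD} = I \cdot DW \cdot \frac{1 - e^{-rd}}{r},$$

with the undiscounted limits $NL$ and $I \cdot DW \cdot d$ at $r = 0$. The
default discount rate is $r = 0.03$/year, the convention in national
burden-of-disease work; it is a convention here too, not an estimate, and is
exposed as an argument. Uniform age weights are the only implemented form —
the `age_weighting` flag exists so callers state the choice explicitly, and
the non-uniform variant is rejected rather than silently approximated. The
test suite checks both functions against brute-force numerical integration
of $e^{-rt}$ (to six significant figures over $r \in [0, 0.1]$,
$L \in [0, 80]$), an oracle that shares no code with the closed form.

`rank_diseases()` sorts a stratum descending by DALYs with alphabetical
tie-breaking — published tables carry no ties, so any deterministic rule
serves; alphabetical keeps ranking reproducible across platforms. When a
table lists only the leading causes, the stratum total must be supplied so
percentage shares refer to the full burden, not the listed subset.

Need conversion is
$a = 1000 \cdot \text{incidence} \cdot \text{coverage} / \text{population}$,
reported to one decimal place. The packaged Malawi table is internally
consistent with a working population of 13,066,000 (e.g. $1000 \times
1{,}829{,}077 / 140$), slightly below the rounded 13.1-million census
figure; the package records both and uses the former for re-derivation
(`malawi_population_2008`). Rows whose printed need is *not* reproduced by
full-coverage incidence conversion (within 0.5 per 1000, i.e. within
rounding of the printed precision) are labelled `costing_default`: their
need reflects a required-coverage default from a costing exercise, and
`build_need_table()` back-solves and reports the implied coverage rather
than forcing agreement.

## Provision rates and trends

HMIS counts become rates per 1000 of the denominator class the service
targets — live births, under-5s, over-5s, adults 15+, females 15–45, or the
total population. Over-5s fall back to total minus under-5s when not
supplied directly. Two conventions matter for routine data:

* **Missing is not zero.** Blank cells in multi-year provision tables mean
  the series was not yet collected; published zeros are real zeros. Readers
  and generators preserve the distinction, and `build_provision_table()`
  reports unreported intervention-years as `NA`.
* **Round late.** Rates are held unrounded internally and rounded only at
  report time, half away from zero (`round_half_up()`), because base R's
  round-half-to-even turns e.g. 0.625 into 0.62 where reported tables print
  0.63.

## The gap analysis

The per-intervention gap ratio is $b/a$; the aggregate across the package is
**totals-based**, $\sum b / \sum a$. This weights interventions by volume
and is the definition under which the packaged table's total row (1931.6,
1311.3, 0.68) is reproduced; the arithmetic mean of the 49 row ratios is
0.66, and the test suite asserts the two differ so the distinction cannot
silently regress. The aggregate is invariant to row order and to any common
rescaling of needs and provisions.

Classification into over/met/under-provided uses the ratio rounded to two
decimals, so a service at 1.004 (growth monitoring on the packaged table)
counts as exactly met; under this rule exactly the two malaria-treatment
services are overprovided. Interventions present on only one side of the
need–provision join are excluded from the totals and surfaced in an
exclusions attribute with a warning — never silently dropped, never
zero-filled. Names join exactly after whitespace/case normalization, with an
explicit alias map (`ehp_intervention_aliases()`) for the HMIS-versus-EHP
naming variants in the packaged tables.

## The cost-effectiveness screen

An intervention is cost-effective when its $/DALY value is **strictly
below** the threshold (default \$150/DALY, the conventional cutoff for
low-income settings); values at the boundary are not, which is the literal
reading of a "<\$150/DALY" criterion. Published ranges such as \$3–12/DALY
are judged conservatively by their upper bound: both ends must clear the
threshold. Missing estimates are classed `unknown`, never imputed. The
screen crosses the threshold class with EHP membership and a
targets-top-20-disease flag; externally funded interventions (e.g.
donor-funded antiretroviral therapy) carry an `externally_funded` flag that
is reported but deliberately does not alter their class. The full
per-intervention $/DALY table of the original assessment was published only
as supplementary material, so the packaged CE fixture carries the values
quoted in the text; the published 33/12/10 split is therefore exercised
structurally (partition and monotonicity properties, plus recovery of a
known cost-effective share on synthetic tables) rather than reproduced
row-by-row.

## Funding coverage

Coverage is expenditure over required cost, both per capita, dimensionless
and invariant to currency rescaling. Series carry an accounting `scope`
because SWAp-partner expenditure (which excludes households, NGOs and
non-SWAp donors) is not comparable with national totals; `mean_coverage()`
refuses mixed scopes. The packaged funding fixture carries only the
published point values (\$7.9/\$13.5 SWAp expenditure against \$17.3/\$28.6
EHP cost; \$25 national in 2005/06 against the \$34 target, \$38 by 2015);
the original four-year 57% average used yearly values published only as a
figure, so that statistic is computable by the module but not reproducible
from packaged data. The original text also describes a funding gap
"reducing from 44% to 74%", which reads as coverage rising rather than a gap
falling; the ambiguity is noted here and neither number is used in
validation.

## The synthetic-data generator

The generator produces every pipeline input with retained ground truth. Its
defaults are the assessment's own conditions: a 13.07-million population
with the six denominator classes (fractions 0.045 live births, 0.17
under-5, 0.83 over-5, 0.52 adults 15+, 0.22 females 15–45 — demographic
proportions typical of a high-fertility southern-African population), 20
ranked diseases sharing 7.5M DALYs under a jittered power law, 49
interventions with true coverage drawn from 0.05–1.45 (the span of observed
provision-to-need ratios, including over-provision), $/DALY values
log-normal with median \$67 and log-sd 1.3 (placing ≈73% of mass below
\$150, the observed 33-of-45 split among known values) with 10/55 of
estimates missing, and six fiscal years of per-capita funding growing from
\$7.9 at 11.3%/year (reaching \$13.5 in year six).

Service counts are Poisson around
$\text{coverage} \times \text{need} \times \text{denominator}/1000$ —
the minimal counting assumption, since routine-reporting error has no
published error model — switching to negative-binomial (variance
$\mu + \phi\mu^2$) when the `count_noise` dispersion $\phi$ is positive; a
`"none"` option returns the rounded expectation for exact structural
checks. The noise level is a free parameter, not an estimate. Each
generator draws from its own seeded RNG stream, so output is byte-identical
for a fixed seed and independent of call order.

What the generator does **not** emulate: facility-level or patient-level
records, missing reporting months, duplicate reporting, or any systematic
(non-mean-zero) HMIS error. Passing parameter-recovery tests therefore show
the pipeline's arithmetic is faithful under counting noise — not that
real-world HMIS completeness problems are handled.

**Recovery estimator.** Parameter recovery uses the pooled multi-year
estimate — total counts over all years divided by the counts expected at
full coverage — rather than a single year. Poisson error on a coverage
estimate scales as $\sqrt{\text{coverage}/\text{caseload}}$, so for the
smallest-caseload interventions a single year sits at the edge of the ±0.02
tolerance the tests assert, while pooling six years brings every
intervention comfortably within it. The validation sizes are 49
interventions × 6 years for recovery and $n = 10^4$ draws for the
cost-effective-share check (within ±0.02 of the log-normal CDF at the
threshold).

## Degenerate inputs and edge rules

Zero or negative populations, denominators and needs are errors (a gap
ratio with zero need is undefined coverage, not infinity); zero provision
is a valid ratio of 0. A `flag_severe_gaps()` threshold of 0 flags only
services with no provision at all. `top_diseases()` beyond the table size
returns everything with a warning rather than failing. Duplicate
intervention names are errors at every join. All CSVs are UTF-8,
comma-delimited, header mandatory, `.` decimal, with empty fields as
missing values.

## Known limitations

* Coverage is a prerequisite of impact, not a measure of it: nothing here
  assesses quality of care or outcomes.
* The under-15 burden share is stored as published (29%) alongside totals
  (2.1M of 7.5M = 28%) without reconciliation; both are available, neither
  is silently corrected.
* Need rates labelled `costing_default` depend on an external costing
  exercise; the back-solved implied coverage is descriptive, not a
  recommendation.
* The $/DALY inputs are literature values taken as given; no cost or effect
  modelling is performed.
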