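---
title: "Segmenting households with children who have complex needs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting households with children who have complex needs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(householdseg)
```

## The problem and the model

Complex health and social problems cluster in families: adults with
comorbid physical and mental illness, children with chronic conditions or
in state care, poverty, and heavy but fragmented service use tend to occur
together in the same households. Services, however, are organised around
individuals and single sectors. This package implements a household-level
segmentation designed as a case-finding tool for integrated care: it takes
one snapshot year of person-level linked records and flags households with
children whose needs cut across sectors.

A *household* is the set of people sharing a pseudonymised address
identifier. Address groups with more than `max_household_size` (default 10)
residents are excluded wholesale as likely institutions — care homes,
houses of multiple occupation — rather than trimmed, because the intent of
the rule is to remove non-family settings entirely. People with no address
identifier cannot be grouped and are dropped with a logged count; turning
them into singleton households would distort the cost-quantile denominator.

A household with at least one child (aged 0–16 inclusive; adults are 17+)
is **complex** when four criteria hold at the same time:

* **C1** — some adult carries a physical long-term condition code *and*
  some adult carries a mental-condition code. The two adults need not be
  the same person: the operational definition used in the deployed model
  counts household-level co-presence, and the package follows it. A single
  adult with both also qualifies.
* **C2** — some child carries any condition listed for adults (the
  child-problem set defaults to the physical ∪ mental union), or a
  child-in-care marker.
* **C3** — any of seven social-vulnerability sub-flags: homelessness code
  on any member; any member with strictly more than `ae_visits_per_year`
  (5) A&E attendances; substance-abuse code; lone parenthood (exactly one
  adult resident with children); a child in care; residence in the most
  deprived `deprivation_quantile` (20%) of the region; use of at least
  `distinct_services_min` (3) distinct care sectors by the household.
* **C4** — per-capita cost-weighted utilisation in the top
  `1 − spend_quantile` (25%) of all households with children.

The conjunction is deliberately rule-based — a definition practitioners can
audit — not a predictive score.

## Numerical choices

**Top-share quantile.** C4 flags the top *m* = ⌊(1−q)·n⌋ households by
per-capita cost, with every household tied at the m-th value included.
On costs {1,2,3,4} at q = 0.75 exactly the most expensive household is
flagged; when all costs tie, all are flagged. The flagged share is
therefore at most (1−q) plus the tie mass at the threshold, which the
segmentation reports (`spend_tie_mass` attribute). With fewer than four
cohort households at q = 0.75 the quantile is undefined and the
segmentation refuses rather than guessing. The same top-share rule gives
the deprivation cutoff, computed over **all** retained households (the
region), not only those with children; the published definition is
relative ("most deprived 20%"), so no national lookup is needed, and the
region-versus-municipality choice is configurable in principle by running
per municipality.

**Costs.** The original costing mixed heterogeneous sources (condition
management estimates in primary care, national tariffs in secondary care,
reference costs for mental health and community services, published spend
statistics for social care). The algorithmic content — weight contacts,
sum within household, divide by head count — is preserved exactly behind a
configurable sector → unit-cost tariff with optional per-contact overrides.
Currency units are abstract; multiplying all tariffs by *k* scales every
cost by *k* and provably leaves C4 flags unchanged (tested). Per-capita
spend divides by **all** members, children included, with no
equivalisation: none is described for the source model, so none is applied.

**Rounding for printed tables.** The criteria table reproduces the
published presentation: percentages round half-up to whole numbers, keep
one decimal below 2% and two decimals below 0.1%. This rule was chosen
because it reproduces every verifiable published cell (92, 25, 3, 1.7,
0.8, 0.6, 0.03); the published table contains one cell (27 for 27.995%)
that no consistent rounding of its printed counts reproduces.

**Odds ratios.** The unmet-need contrast crosses household type with
any-emergency mental-health attendance within two strata: persons already
known to mental-health services (any mental-condition code or any
non-emergency mental-health sector contact) and persons with no such
history. The estimator is the closed-form 2×2 odds ratio with a Wald
interval, cross-checked against the interaction coefficient of a saturated
Poisson log-linear model — the two must agree to six significant figures.
The source description says "Poisson regression" but reports odds ratios;
computing both routes reconciles the terminology without guessing. Zero
cells abort unless the Haldane–Anscombe 0.5 correction is explicitly
requested; it is never applied silently. Person-level any-attendance odds
are used rather than attendance-rate ratios: the published phrasing
("emergency attendances … 7 times higher, OR = 6.8") is an odds ratio on
people.

## The synthetic generator: what it emulates, and what a green test means

The record-level data behind the deployed model are not distributable, so
the package generates linked populations with the joint structure the
pipeline actually reads:

* **Household structure** — sizes 1–10 from a configurable distribution
  (default mean ≈ 3.3); every household keeps at least one adult; planted
  complex households draw sizes conditional on ≥ 3 (mean ≈ 4.2, mirroring
  the published finding that complex households are larger) and always
  contain a child.
* **Ages** — children uniform on 0–16 (teen-skewed in planted households),
  adults 17–90 with an exponentially decaying profile (mean ≈ 38).
* **Deprivation** — household-level Beta score, mean 0.20 (SD 0.16) for
  ordinary and mean 0.25 for planted households, matching the published
  group means.
* **Conditions** — per-adult (physical, mental) flags from a bivariate
  Bernoulli with configured marginals (defaults 0.20/0.08 ordinary,
  0.45/0.30 planted) and a comorbidity log-odds (default 1.0) via the
  Plackett construction; flagged persons receive a named code with asthma,
  anxiety and depression weighted heaviest, echoing the published
  prevalence profile.
* **Contacts** — per-person, per-sector Poisson counts; planted households'
  rates are multiplied by `sector_rate_multiplier_complex` (default 6);
  children in care draw heavy children's-social-care contact, which makes
  that sector the largest cost share, the qualitative pattern of the
  published cost distribution; mental-health A&E presentations concentrate
  in teenage girls of planted households.

**Planting is asymmetric by design.** Criteria 1–3 are forced
deterministically in planted households (a physical and a mental adult
flag, a child problem, contacts in three sectors); criterion 4 is *never*
planted — the cost multiplier raises planted households' spend, but the
quantile is always computed from the realised cost distribution. Recovery
of the planted labels therefore genuinely tests the costing and ranking
logic, not a circular construction. With the default strong-separation
settings the pipeline recovers planted labels with sensitivity and
specificity ≥ 0.9 (the package's headline self-test).

The unmet-need planting (`plant_unmet_need`) derives each person's stratum
from the generated records themselves, then samples emergency
mental-health events from a two-stratum Bernoulli model with configured
odds ratios (defaults 6.8 no-prior, 2.0 known — the published point
estimates used as *planted truth*, not as reproductions). Pre-existing
emergency contacts with mental-health reasons are relabelled so the
planted odds ratio is exact; the planting uses its own RNG stream (config
seed + 1) so regeneration is reproducible regardless of what ran in
between.

What the generator does **not** emulate: clinical coding noise and
terminology drift, registration churn and mid-year household moves,
mortality, municipality-level deprivation geography, and any dependence
between household size and condition burden beyond the planted contrast.
A green test establishes that the *algorithm* behaves as specified on data
with the stated joint structure — it says nothing about how well the
shipped default taxonomy or tariffs match any real site, and the default
code lists are stand-ins for local clinical code sets, not clinical
artefacts.

## Published-count worked examples

The headline regional numbers (21,527 complex households; 8% of 266,939;
89,631 people; 34% of costs, £362M) derive from a 2.6M-person linked
dataset that cannot be recomputed at desk scale. The package ships the
published aggregate counts (`inst/extdata/`) and recomputes the ratio and
summation cells from them (`worked_example_targets()`); the cost-total and
cost-share figures are not recomputable from printed counts and are not
reported. One published table row (child in care) has an unrecoverable
other/complex split in the available text; its cells are left empty in the
fixture and nothing depends on them.

## Degenerate inputs and edge behaviour

* Missing `household_id` → person dropped, counted in the run log.
* Missing deprivation score → `deprived` sub-flag FALSE, counted.
* Missing tariff for an observed sector → error naming the sector.
* Fewer than four cohort households → quantile-undefined error.
* Zero total spend in a cost-share group → explicit error.
* Empty stratum or zero-margin 2×2 → flagged degenerate, estimate NA.
* Emergency flags outside A&E/inpatient, negative ages, out-of-range
  deprivation scores, unknown sectors or codes → row-level validation
  errors at load time, with row numbers.

## Known limitations

The model inherits the inverse-care-law caveat of its source: it is built
from service-contact data, so households that use no services are
invisible to every criterion except deprivation and lone parenthood. One
address identifier is treated as one household; multi-family addresses are
not disaggregated. The snapshot design evaluates one year; no longitudinal
re-identification is attempted. The unmet-need contrast is unadjusted (no
covariates), matching its source.
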