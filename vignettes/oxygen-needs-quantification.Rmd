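---
title: "Quantifying national medical oxygen needs with oxyplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying national medical oxygen needs with oxyplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyplan)
library(dplyr)
```

## The quantification model

Medical oxygen demand in a health system is driven by hypoxaemia: patients
whose blood oxygen saturation falls below a clinical threshold and who need
supplemental oxygen.  Direct consumption data are rarely available at
national scale, so planners estimate demand from facility structure and
ward-level clinical assumptions.  `oxyplan` implements that model as a
pipeline of small, testable steps.

For a ward type with hypoxaemia prevalence $p$ (fraction of admitted
patients), typical prescribed flow rate $f$ (litres per minute), and
therapy duration $d$ (hours), the gaseous oxygen volume for one typical
hypoxaemic patient is

$$V = 60\,f\,d \quad \text{litres},$$

and the expected annual hypoxaemic caseload of a ward with $b$ beds, annual
bed turnover $t$ (admitted patients per bed per year), and average
occupancy $o$ is

$$N = p\,b\,t\,o \quad \text{patients per year}.$$

The ward's annual need is $V \times N$; a facility sums its wards; facility
types, regions and the country sum their facilities.  Every quantity is an
expectation under a static annual model — there is no seasonality, surge
dynamics, or stochastic admission process.  Consequences that the tests
rely on: demand is *linear* in each of $p$, $b$, $t$, $f$, $d$ separately,
zero in any factor propagates to zero demand, and totals are conserved
under any complete partition of the facilities.

```{r worked}
per_patient_volume(1, 72)                      # neonatal patient, 3 days at 1 L/min
caseload(0.20, 10, 50)                         # 10-bed neonatal ward
ward_annual_need(4320, 100)                    # litres per year
```

### Assumptions and parameters

The shipped assumption registry (`default_ward_assumptions()`) covers nine
ward types with prevalence, flow and duration values of the kind used by
standard oxygen system planning tools; the facility-type registry
(`default_facility_type_params()`) describes a 99-facility national frame
of four hospital categories with their bed totals and annual bed turnover
rates.  Both registries are open vocabularies: analyses may add wards (a
COVID treatment ward, say) or facility types by providing their own rows,
as the CSV schemas in `load_ward_assumptions()` and
`load_facility_type_params()` document.

Parameter conventions, chosen once and used everywhere:

* **Prevalence is a fraction** in $[0,1]$; percentage columns in input
  files are divided by 100 at load time, avoiding unit ambiguity
  downstream.
* **Duration is stored in hours** (the registry's native unit).  Input
  files may give durations in days via an explicit `duration_unit` column
  (`days` are converted by ×24 at parse time); worked planning examples
  habitually mix the two units, so the conversion is explicit rather than
  guessed.
* **Turnover is a facility-type property** applied to all wards of a
  facility, because turnover data are reported per facility category, not
  per ward.  One consequence is that two wards with different turnover
  assumptions must be modelled as facilities of different types.
* **Occupancy enters as an optional multiplier** on the caseload, default
  1.0.  The headline formula omits it; the default reproduces the standard
  worked examples while keeping an occupancy-adjusted analysis one argument
  away.
* **Caseloads stay fractional.**  They are expectations; rounding to whole
  patients would break the exactness of the worked examples and bias
  small-ward totals.
* **Monthly = annual / 12.**  Planning summaries habitually quote monthly
  litres; a flat division is the only convention consistent with an annual
  turnover rate and no seasonality.
* **The headline turnover summary is the unweighted mean** across facility
  types (66.75 for the default frame) — each hospital category counts
  once.  A bed-weighted mean is exposed via
  `mean_turnover(params, weight = "beds")` because the unweighted mean
  over-represents small categories when used as a national rate.

One inconsistency in the default frame is preserved deliberately: the
published bed total for this kind of 99-facility frame is 11 111, while the
four category rows sum to 11 091.  The registry stores the rows; totals are
always computed from rows, and neither number is silently "corrected".

## Gap analysis

`coverage(available, required)` returns the coverage fraction (which may
exceed 1 — a surplus) and the absolute gap clamped at zero.  A zero
requirement met by zero devices is vacuously covered (coverage 1); a
surplus against a zero requirement is flagged with an infinite coverage
sentinel rather than a division error.

Clamping happens **per scope group**: a surplus in one region never offsets
a deficit in another, because maldistribution is itself a finding (one
region can hold more concentrators than it needs while another has 14% of
its requirement).  Clamped gaps are therefore not additive across scopes —
the sum of regional gaps is $\ge$ the national gap — and `gap_report()`
computes all gaps at one declared scope per call.

Cylinder gaps are native volumes.  `cylinder_equivalents()` converts litres
into standard-cylinder counts under three conventions: `exact` (the real
ratio), `procurement` (ceiling — fractions of a cylinder cannot be bought),
and `reporting` (3 significant figures, the convention of headline
summaries: 140 000 000 L at 7500 L/cylinder prints as 18 700).
Device-count requirements (concentrators, oximeters, monitors) are inputs
from planning norms supplied as configuration; the package does not try to
reconstruct norms from litres, except for cylinders where a volume-based
requirement is natural.  `gap_report()` sizes the required cylinder stock
to one month of demand by default (`demand_basis = "monthly"`), a common
stock-holding convention; pass `"annual"` to size against annual volume.

## The indicator set

The monthly reporting stream follows a DHIS-2-style schema: one row per
facility-month with stock movements (litres), device functionality counts,
staffing and patient counts.  The indicator list this module implements
names its indicators but not their formulas, so **every formula here is a
package definition**, recorded in `indicator_catalogue()` (13 indicators —
the source list prints one of them twice) so it can be audited or
overridden:

* Ratio indicators **pool numerators and denominators** across facilities
  within a scope, rather than averaging facility percentages: pooling is
  robust to small denominators and makes the national value the
  report-weighted combination of regional ones.
* Oximeter functionality is device-level (`functional / total` pooled);
  respirator and oxygen-generator indicators are facility-level
  ("has at least one functional") stratified by facility category, with
  the type-to-category mapping a configurable input
  (`default_category_map()`).
* The quarterly stock-out indicator sums a facility's stock-out days over
  the quarter's three months and averages across facilities; facilities
  missing a month are excluded by default (the policy is recorded on the
  result), or counted with zeros via `missing = "zero"`.
* The stock ledger must satisfy
  `opening + received − consumed − lost = closing` within 1 litre.
  `validate_ledger()` reports residuals; it never repairs them, because a
  broken ledger is a data-quality finding.

Zero denominators produce missing values with an explicit reason, never
`NaN`, and all defined percentage indicators lie in $[0, 100]$.

## The synthetic generator

The assessment data such models are normally fitted to are confidential,
so the package ships a generator that emulates their structure.  Its
defaults define the study conditions used throughout the tests:

* a 99-facility frame (4 general, 13 central, 15 regional, 67 district
  hospitals) over 10 anonymous regions `R01`–`R10` with uniform allocation
  weights;
* ward bed shares over the nine default wards (30% general medicine, 18%
  maternity, 15% paediatrics, 10% operating theatre, …) — a plausible
  hospital profile, not an empirical estimate, and explicitly configurable;
* report-stream parameters: 60% of facilities with a hypoxaemia-management
  department, stock-outs at 1.5 events per facility-month, 70%
  oxygen-therapy coverage, 75% therapeutic success, 50% of staff trained.

Bed allocation uses **largest-remainder apportionment** twice — beds to a
type's facilities, then a facility's beds to wards — so facility-type bed
totals are conserved exactly (a testable invariant) while each cell stays
within one bed of its exact quota.  Hypoxaemic patient counts are Poisson
with mean equal to the facility's expected monthly caseload *from the
demand engine*, tying the generator to the quantification model; treatment
counts are binomial thinnings; the stock ledger is built constructively so
its identity holds on 100% of reports.  Everything is seeded:
a fixed seed reproduces rosters, inventories and report panels exactly.

What passing tests on this generator do and do not show: they demonstrate
that the demand arithmetic, roll-ups, gap clamping and indicator pooling
are correct and internally consistent, and that generator parameters are
recovered by the indicator estimators within sampling error (checked at
roughly 600 facility-months, where binomial/Poisson standard errors are
small).  They do not validate the clinical assumption values against any
real country's data, and the generator deliberately makes no attempt to
reproduce real regional distributions of beds or equipment, which are not
published as numbers.

## Numerical and design notes

* Worked-example arithmetic is exact in double precision (products of
  small integers), and the tests assert identity, not tolerance.
* Roll-ups are checked against a brute-force per-(facility, ward) loop at
  relative tolerance $10^{-6}$ on rosters of ≤ 200 facilities.
* One widely circulated worked example of this model prints the per-patient
  volume of a severe-COVID adult ward with a typographic corruption
  ("100 8000 L"); the arithmetic, $10 \times 60 \times 168 = 100\,800$ L,
  is confirmed by its printed annual product $100\,800 \times 125 =
  12\,600\,000$ L, and that is what the package computes.
* CSV outputs carry full precision; only the human-readable `summary.txt`
  rounds, to 3 significant figures, matching the reporting convention of
  the cylinder conversion.
* Degenerate inputs are defined, not accidental: zero-bed wards and
  zero-prevalence wards contribute zero demand; empty facility-type
  registries are valid data but an error for `mean_turnover()`;
  apportioning over all-zero shares is an error.
* Test and example problem sizes (99-facility rosters, 3–6 month panels)
  keep the full suite and the acceptance script fast while leaving
  standard errors small enough for 3-standard-error parameter-recovery
  checks.

## Limitations

The model is a planning expectation, not a forecast: no seasonality,
epidemic surges, referral flows between facilities, or oxygen source
engineering (purity, pressure, PSA plant sizing).  Equipment requirement
norms for non-cylinder devices must be supplied by the analyst.  The
shipped assumption values are defaults to be reviewed against local
clinical practice before any real planning use.
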