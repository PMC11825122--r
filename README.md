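# oxyplan

Tools for quantifying a country's medical oxygen needs from health-facility
data, analysing equipment gaps, and computing a DHIS-2-style set of
hypoxaemia-management indicators from monthly facility reports.  It is
aimed at health-system planners and analysts sizing national oxygen
programmes, and at anyone who needs a tested, reproducible version of the
bed-based oxygen quantification commonly used in oxygen system planning.

## The model

Oxygen demand is built up from ward-level clinical assumptions.  For a ward
with hypoxaemia prevalence *p*, typical flow rate *f* (L/min) and therapy
duration *d* (hours), one typical hypoxaemic patient needs

```
V = f × 60 × d            litres of gaseous oxygen
```

With *b* beds, an annual bed turnover rate *t* (patients per bed per year)
and average occupancy *o* (default 1), the expected annual hypoxaemic
caseload is

```
N = p × b × t × o         patients per year (kept fractional)
```

and the ward's annual need is `V × N` litres.  Facility demand sums its
wards (turnover is a facility-type property); facility-type, regional and
national totals are sums over facilities; monthly figures are annual ÷ 12.
The gap module compares functional equipment with requirements, clamps
shortfalls at zero per scope, and converts cylinder volume gaps into
7500 L cylinder equivalents.  The indicator module computes pooled-ratio
and facility-share indicators from monthly reports and validates the stock
ledger `opening + received − consumed − lost = closing`.

A synthetic generator produces facility rosters (matching a configurable
facility-type frame exactly, via largest-remainder bed apportionment),
equipment inventories and monthly report panels whose ledger identity
holds by construction, so the full pipeline runs without confidential
assessment data.

## Worked example

```r
library(oxyplan)

# one typical neonatal patient: 1 L/min for 3 days
per_patient_volume(1, 72)
#> [1] 4320

# expected caseload: 20% prevalence, 10 beds, turnover 50
caseload(0.20, 10, 50)
#> [1] 100

ward_annual_need(4320, 100)
#> [1] 432000

mean_turnover(default_facility_type_params())
#> [1] 66.75

# a 140-million-litre volume gap in large-cylinder equivalents
cylinder_equivalents(140e6, 7500, "reporting")
#> [1] 18700
```

So a ten-bed neonatal ward is expected to treat 100 hypoxaemic newborns a
year and to need 432 000 L of oxygen annually, and a 140 M L national
volume gap corresponds to about 18 700 large cylinders.

Run the whole pipeline on synthetic data:

```r
res <- run_pipeline(pipeline_config(out_dir = "results/run", seed = 13))
res$rollups[res$rollups$grouping == "national", ]
#> # A tibble: 1 × 5
#>   grouping group_key annual_litres monthly_litres expected_hypoxaemic_patients
#>   <chr>    <chr>             <dbl>          <dbl>                        <dbl>
#> 1 national national    2423300458.     201941705.                      218079.
```

which writes `demand.csv`, `gap.csv`, `indicators.csv`, `ledger.csv` and a
human-readable `summary.txt`.  A thin command-line wrapper with
`synth` / `demand` / `gap` / `indicators` / `all` subcommands is installed
at `inst/cli/oxyplan.R`.

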