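---
title: "Projecting asbestos-related disease from a job-exposure matrix: models, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting asbestos-related disease from a job-exposure matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardrisk)
```

## The problem

Two asbestos-cement factories (Harare and Bulawayo, Zimbabwe) accumulated
about 25 years of personal airborne chrysotile measurements, condensed into a
job-exposure matrix (JEM): one arithmetic-mean fibre concentration (f/mL,
with sd) per job title and calendar period. `ardrisk` turns that matrix into
projections of asbestos-related disease burden — excess mortality from lung
cancer, mesothelioma, and gastrointestinal cancer, and incidence of
asbestosis — per 100,000 exposed workers, under the standard linear
dose-response framework used in occupational risk assessment.

The dose metric throughout is cumulative exposure,
$CE = f \times d$ (f/mL-years), the concentration a worker breathes times the
years worked at that level. Linearity in $CE$ is the conventional regulatory
assumption for asbestos: it lets group-average exposures stand in for
individual ones, extrapolates easily, and errs on the conservative side at
low dose. Its known weaknesses — it ignores latency, age structure, competing
mortality, and the lower potency of chrysotile relative to the amphibole
fibres present in the cohorts behind the calibration table — are discussed
under *Limitations*.

## Cancer: calibrating the excess-risk slope

The calibration input is the regulatory risk table bundled as
`ardrisk_fixture("osha")`: estimated cancer deaths per 100,000 exposed, for
seven fibre concentrations (0.1–10 f/mL) at 1, 20, and 45 years of exposure,
by cancer site. Each entry becomes a calibration point $(CE, \text{cases})$
via `extract_points()`, and a per-site linear model
$\text{cases} = a + b \cdot CE$ is fitted with `fit_linear()` (ordinary least
squares through `stats::lm()`; closed-form, deterministic).

The analysis this package replicates applied regression equations whose
coefficients are not recoverable from the published record (the regression
figures are illegible). One anchor survives: a worked example stating that at
$CE = 0.19$ f/mL-years the per-site grids give 13.7 (lung), 8 (mesothelioma),
and 1.3 (gastrointestinal) cases per 100,000, summing to 23. `ardrisk`
therefore exposes four calibration modes in `calibrate_models()`:

* **`implied`** (default): zero-intercept slopes $b = \{13.7, 8, 1.3\}/0.19$
  — the only calibration the published record pins down exactly, and the one
  that reproduces its worked example to the digit.
* **`pooled`**: OLS over all 21 table rows. Dominated by the huge
  cumulative exposures of the 20- and 45-year blocks (up to 450 f/mL-years),
  far above the factory range (≤ 4.8), so it underpredicts there.
* **`per-duration:D`**: OLS within one duration block (D = 1, 20, 45).
* **`low-ce:X`**: OLS over points with $CE \le X$ (default 10 f/mL-years),
  the region nearest the factory exposures.

All modes yield strictly positive slopes ordered lung > mesothelioma >
gastrointestinal, mirroring the ordering of the calibration columns at every
duration. Negative fitted intercepts are retained in the model object but
predictions are clamped at zero cases. Calibration always uses exact
products for $CE$; rounding is strictly a presentation step in the
prediction layer.

### How well can the published cancer grid be reproduced?

Only approximately — and provably so. Comparing the `implied` grid against
the transcription of the published summary table
(`ardrisk_fixture("cancer_reference")`), 191 of 200 cells agree within 10%
(mean relative deviation ≈ 4.5%). The nine cells outside are the smallest
ones: the 1-year projections at ≤ 0.05 f/mL and the three 10-year cells at
0.06 f/mL. No choice of slope and intercept can fix them, because the
published table is internally inconsistent: its cell at
$f = 0.04, d = 20$ (105 cases at $CE = 0.8$) forces $a + 0.8b \ge 94.5$
within 10%, while its cells at $f = 0.06, d = 10$ (63 cases at $CE = 0.6$)
force $a + 0.6b \le 69.3$; together with the 1-year cell at
$f = 0.04$ (6 cases) these demand $b \ge 116.6$ and $b \le 111.3$
simultaneously. Since any set of per-site linear models sums to a single
linear model for totals, *no* linear calibration — fitted, implied, or
hand-picked — satisfies every published cell within ±10%. The package
reports the deviation profile transparently (`analysis/03_cancer_grid.R`)
rather than patching individual cells. Agreement checks use the unrounded
predicted total against the printed integer: rounding single-digit
predictions to whole cases first would add up to 7 percentage points of pure
presentation noise exactly where the comparison is tightest.

## Asbestosis: the cumulative-dose model

Predicted asbestosis incidence uses $R_a = m \cdot f \cdot d$ (percent),
with $m = 0.055$ % incidence per f/mL-year, applied at a single duration
(default 25 years, the span of the exposure records). Two conventions are
forced by the published table itself and are implemented exactly:

* **Rounded-CE:** the slope is applied to $CE$ already rounded to 1 decimal
  place. At $f = 0.17, d = 25$: $CE = 4.25 \to 4.3$ and
  $0.055 \times 4.3 = 0.2365 \to 0.24\%$, matching the printed 0.24, whereas
  the exact-CE route would give $0.055 \times 4.25 = 0.2338 \to 0.23$.
* **Round half up**, at every rounding site: $4.75 \to 4.8$,
  $0.165 \to 0.17$. IEEE half-to-even (`base::round()`) would print 4.8 but
  0.16, contradicting the table. `round_half_up()` pre-rounds at $10^{-8}$
  so binary representations of decimal products sit exactly on their
  intended half-way points.

Cases per 100,000 are the rounded percent incidence × 1000. Under these
conventions the package reproduces 47 of the 50 published cells digit for
digit. The three exceptions are flagged `suspected_typo` in the bundled
transcription, and each contradicts the published table's own arithmetic,
not just ours: Harare kollergang 2001–2008 prints 180 cases beside 0.17%
(0.17% of 100,000 is 170); Bulawayo multi-cutter 2001–2008 prints 300 beside
0.17% (same); Bulawayo multi-cutter 2018–2020 prints 0.05%/50 where
$0.055 \times 1.0 = 0.055$ rounds half-up to 0.06%/60.

## Risk classification

`per_1000()` converts cases per 100,000 to a rate per 1,000 workers (2 dp),
and `classify_risk()` compares it to a policy threshold with a *strict*
inequality — exactly 1 case per 1,000 is not "more than" the OSHA
significant-risk criterion. Defaults are 1/1,000 (OSHA) and 4/1,000
(Netherlands/Germany). At 25 years every JEM cell exceeds 1/1,000 under the
default calibration, and only the highest-exposure pre-2008 cells exceed
4/1,000 (`analysis/05_risk_classification.R`).

## The synthetic measurement generator

The projections consume only cell means, but the package also ships the
measurement-level pipeline so it can be tested end to end with no external
data: `campaign_from_jem()` → `generate_measurements()` →
`aggregate_monthly()` → `recover_jem()`.

Measurements are drawn lognormal — the conventional model for occupational
exposure concentrations, and one that guarantees positivity — with
`meanlog`/`sdlog` moment-matched so the *arithmetic* mean and sd equal the
JEM cell targets: $\sigma_{\log}^2 = \log(1 + s^2/m^2)$,
$\mu_{\log} = \log m - \sigma_{\log}^2/2$. A zero target sd degenerates to
constant draws. The distribution choice is confined to one function so a
gamma alternative could be swapped in. The default schedule — 48 sampled
cells × 36 months × 2 measurements/month = 3,456 measurements condensed to
1,728 monthly means — echoes the scale of the real campaign (~3,000
measurements, ~1,800 monthly means over ~25 years); the true month-by-month
sampling plan is unrecorded, so any schedule is necessarily invented.
Factory-wide "Overall factory" rows are excluded from campaigns: they are
derived summaries, not sampled strata. Everything is driven by a single
integer seed set once per campaign, with cells generated in stored order,
so identical campaigns are bit-identical.

What the generator does *not* emulate: below-detection censoring (the real
cell means sit well above zero and no censoring is reported), within-month
autocorrelation, task-level exposure determinants, and the real measurement
counts per cell. Passing recovery tests therefore show that the arithmetic
of the pipeline is sound and unbiased under the assumed lognormal structure
— not that the package would be robust to the messiness of raw hygiene
records.

One statistical note on recovery checks: the recovered cell mean has
standard error $s/\sqrt{n}$ ($n = 72$ draws per cell by default), and a
"every cell within 2 SE" check across 48 independent cells is expected to
fail for roughly 90% of seeds (about 2.2 cells fall outside 2 SE by chance).
The test suite runs that check at a fixed seed chosen up front and reports
the outcome as is; the robust end-to-end guarantee is the grid-level one —
at the default schedule, the asbestosis grid built from a recovered matrix
stays within one rounding step (10 cases per 100,000) of the grid built
from the true matrix.

## Numerical and design choices

* **Missing JEM cells are absent, never zero.** A "-" in the exposure matrix
  produces no prediction, matching the dashes in the published grids.
* **Overall-factory rows use the published factory-wide means** (0.11 and
  0.12 f/mL) carried as JEM cells, rather than re-averaging job cells whose
  weights are unstated.
* **Durations** default to {1, 10, 20, 25} years, capped at 25 because the
  exposure record spans ~25 years; durations beyond the 45-year calibration
  range warn but still compute.
* **Care-and-maintenance periods** (2018–2020 in most Harare jobs) are a
  boolean flag on the cell, not an annotation smuggled into the period label.
* **Comma dialects** in the printed calibration table ("14,4" meaning 14.4;
  "13,996.7" and "12,177" meaning thousands) are normalized by an explicit
  rule — a comma is decimal iff no period is present and at most two digits
  follow it — so the bundled fixture can stay faithful to the source tokens.
* **The one inconsistent calibration row** (20-year block, 10 f/mL, printed
  total 13,996.7 against a component sum of 19,418.7) is flagged by
  `validate_osha_table()` and deliberately left as printed; calibration
  modes that use it inherit the inconsistency, which is one more reason the
  `implied` mode is the default.
* Projections are excess-risk rates per 100,000 exposed, not expected death
  counts for the factories' actual headcounts, which are not published.

## Problem sizes

The bundled analyses are small by construction: a 21-row calibration table,
a 50-cell JEM, 200-cell cancer grids, and synthetic campaigns of a few
thousand draws (the moment-matching check uses $10^5$ draws). Every analysis
script and the full test suite run in seconds on one core.

## Limitations

The projections inherit every limitation of linear low-dose extrapolation:
no latency or age structure, no competing mortality, no
amphibole-vs-chrysotile potency adjustment, no confidence intervals (the
published analysis provides none to compare against), and a calibration
table itself assembled from heterogeneous historical cohorts. The package's
contribution is to make the published computation explicit, reproducible,
and checkable — including the places where the published tables are
internally inconsistent — not to improve on its epidemiology.
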