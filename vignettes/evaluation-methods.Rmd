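---
title: "From incubation time series to spatially resolved biodegradation rate constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From incubation time series to spatially resolved biodegradation rate constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverkin)
```

## The problem

River biodegradation screens of micropollutants incubate water-sediment
suspensions (a modified OECD 309 design) spiked with a mixture of trace
organic chemicals, and follow the dissolved-phase peak area of each
compound over about ten days. Three vessel types disentangle the loss
processes: live test vessels (TEST), azide-sterilized sorption controls
with sediment (SC), and an azide-sterilized sediment-free hydrolysis
control (HC). The scientific outputs are first-order biodegradation rate
constants per compound and river segment, corrected for sorption and
ionization speciation, and an attribution of their spatial variability to
environmental factors.

`riverkin` implements that evaluation chain end to end, together with a
synthetic-experiment generator that emulates the study design, so every
stage can be exercised and validated without any laboratory data.

## Kinetic model and estimation

Dissolved-phase dissipation is modelled as first order. For each compound
and segment, all uncensored points (area above the limit of
quantification, LOQ) from the three TEST replicates enter one ordinary
least-squares regression of $\ln(\text{area})$ on time; the observed rate
constant is $k_\text{observed} = -\hat\beta_1$ (unit: day$^{-1}$).
Confidence intervals come from the t distribution of the slope, and the
p-value is one-sided for a negative slope, since dissipation is the only
alternative of interest: a significantly *increasing* signal is flagged
invalid, not "significant". An estimate is **valid** when it rests on at
least `min_points = 5` data points and the slope is significant at
`alpha = 0.05`. Cells with fewer than two uncensored points are
**not available**.

### Sorption-control correction

The SC captures sorption plus abiotic loss. The package estimates the SC
dissipation rate by a log-linear fit of the pooled SC areas and divides
every TEST area by the fitted relative curve
$\hat S(t) = e^{-\hat k_\text{SC} t}$, clamped so $\hat S \le 1$. On exact
exponentials this is identical to subtracting the abiotic rate constant,
and it preserves point-level data for the break test. We deliberately do
*not* divide by the raw per-time SC ratios: those carry the measurement
noise of every individual SC observation into all TEST points sampled at
the same time, producing errors that are correlated within a time point
and invisible to the OLS slope standard error. In simulation that raw
division depressed 95% CI coverage to roughly 0.8, whereas dividing by the
fitted curve — and propagating the variance of $\hat k_\text{SC}$ into the
cell's standard error, since the corrected rate is a difference of two
independent slopes — keeps coverage near its nominal level. The SC
correction is skipped (with a status flag) when every SC point is censored.

### Biphasic kinetics

Some compounds dissipate fast initially and slowly later. A Chow
structural-break F-test of the pooled log-linear regression is evaluated
at every interior scheduled sampling time with at least `m_min = 3`
uncensored points and two distinct times on each side (first segment
$t \le$ break). The largest F wins, earliest time on ties. Because up to
six candidate breaks are scanned, the minimal candidate p-value is
Bonferroni-corrected by the number of candidates before comparison with
`alpha_chow = 0.05`; without that correction the family-wise
false-biphasic rate under a monophasic null is well above the nominal 5%.
When the corrected p falls below the threshold the cell is biphasic and
the reported $k_\text{observed}$ is the initial-segment fit. The candidate
grid, `alpha_chow` and `m_min` are declared package defaults, all
configurable.

## Sorption and speciation corrections

The dissolved fraction is estimated from the controls at $t = 0$:
$f_\text{Dis} = \overline{A}_\text{SC}(0) / \overline{A}_\text{HC}(0)$,
clamped to $(0.01, 1]$ — the floor keeps the correction bounded under
measurement noise, and values above 1 are measurement noise around "no
sorption". Then

$$k = \frac{k_\text{observed}}{f_\text{Dis}}$$

is the rate constant that would be observed if the compound were fully
dissolved. When the HC area at $t = 0$ is censored, $f_\text{Dis}$ is not
estimable; the correction is skipped and flagged.

For ionizable compounds the neutral fraction $f_N$ at the ambient pH
follows Henderson–Hasselbalch speciation: for an acid site
$1/(1+10^{\,\text{pH}-\text{p}K_a})$, for a base site
$1/(1+10^{\,\text{p}K_a-\text{pH}})$, and multiple sites multiply as
independent probabilities (pKa values alone cannot resolve zwitterionic
microstates, so microstate coupling is deliberately not modelled). Under
the assumption that the biodegradation rate is proportional to $f_N$ —
uptake of the neutral species limits degradation — rates are normalized
to a reference pH of 7:

$$k_\text{pH7} = k \cdot \frac{f_N(7)}{f_N(\text{pH}_\text{site})}.$$

This is the only form consistent with rate-proportionality to $f_N$; with
site pH equal to 7 it is the identity. Whether degradation of charged
microforms should also be normalized is not identifiable from pKa data
and is out of scope.

## Gap-filling

Invalid estimates (too few points, or not significant) still carry
information in their confidence intervals. The decision chain replaces an
invalid cell, in order: (1) with the median valid value of the same
compound at the other segments if the cell's 99% CI contains it; (2) else
with the minimum of those valid values if the CI contains it; (3) else
with the global minimum valid value over all compounds and segments.
Containment is closed-interval. "Median" with an even count is the
conventional arithmetic midpoint in linear rate space. The chain operates
on $k_\text{observed}$; corrected values inherit fills through the
corrections applied afterwards (`fill_before_correct = FALSE` reverses
that order, scaling each CI by the cell's correction factor). The chain is
idempotent and never invents values outside the observed valid range.

Cells with no estimate at all are filled — only for the ordination data
set, which tolerates no gaps — with the compound's within-country median,
and only when the within-country stddev of the log10 values is below 0.4,
i.e. where the country's segments agree well enough for the median to be
a defensible stand-in. Compounds enter the spatial comparisons when they
are valid in at least `min_valid = 12` of 18 segments (gap-filled in less
than one third).

## Spatial variability and its attribution

The variability metric is the sample standard deviation of
$\log_{10} k$ across segments; its antilog expresses the spread as a fold
difference (0.46 log units is about a factor of 3 — base 10 is forced by
that conversion, since $e^{0.46} \approx 1.6$ would not match). Per
compound, a one-way ANOVA on replicate-level fits (on $\log_{10} k$ by
default, where replicate noise is approximately homoscedastic; a flag
switches to linear k) tests for differences between segments. Replicate
fits inherit the pooled cell's kinetic class so like is compared with
like. Summaries report per-scope medians across compounds and the
percentage of compounds with a significant segment effect.

The attribution step is redundancy analysis: the segments × compounds
matrix of $\log_{10} k_\text{pH7}$ is regressed on 10 standardized
environmental predictors and the principal axes of the fitted values are
the constrained axes. Concentration-like variables (TOC, TCC, EC, DO,
clay, sand) are log10-transformed; temperature enters as $1/T$ in Kelvin
(Arrhenius-consistent); pH and the geographic coordinates enter
untransformed — coordinates can be negative, so a log transform is not
meaningful for them; silt is dropped because the three particle-size
fractions close to 100% and it is collinear with clay and sand. The
"unbiased" variance explained is the Ezekiel adjustment
$1-(1-R^2)(n-1)/(n-m-1)$. The global test permutes response rows
(unrestricted, 999 permutations, $(b+1)/(B+1)$ p-values, so the smallest
attainable p is 1/1000). Per-variable statistics come from envfit on the
first two constrained axes (configurable). Note that envfit applied to a
variable that is itself among the constraints is mildly anti-conservative
by construction — the axes were chosen to correlate with the constraint
set — which is a known property of this widely used post-hoc test; the
package's null-calibration checks therefore use variables external to the
constraints. The heavy lifting is delegated to vegan (`rda`, `anova.cca`,
`envfit`), the standard tool for constrained ordination; the test suite
cross-checks axis shares against an independent normal-equations plus
eigendecomposition implementation.

## The synthetic-data generator

`generate_experiment()` renders peak-area series under the study design:
10 sampling times over 10 days (0, 2, 5, 9, 18 h, then 1, 2, 4, 7, 10 d),
three TEST, two SC and one HC vessel, 1 µg/L spikes mapping to an area of
$10^6$ at $t = 0$, and an LOQ of $10^3$ area units (a three-decade dynamic
range, matching a calibration span of 1 ng/L to 10 µg/L). Signals are

* TEST: $A_0 f_\text{Dis} e^{-(k_\text{site}+k_\text{abiotic})t}$,
* SC: $A_0 f_\text{Dis} e^{-k_\text{abiotic}t}$,
* HC: $A_0 e^{-k_\text{abiotic}t}$,

each multiplied by mean-preserving lognormal noise with a relative
standard deviation of 0.09, the typical between-sample RSD of
internal-standard peak areas in this assay; a single shared RSD per
compound is used because nothing finer is identifiable from that summary.
Sub-LOQ areas are kept but flagged censored — exclusion belongs to the
fitting stage. Biphasic compounds decay piecewise, continuous at the
break.

Per-site true rates combine three components on the log10 scale: the
compound mean, a TOC-driven component shared across compounds
(`toc_slope` × centered log10 TOC; the default 0.6 makes the Pearson
correlation between per-segment median rates and log10 TOC come out
around 0.7 at the default panel size), and residual site noise whose
variance is set so the *total* between-segment stddev of log10 k equals
`sigma_site = 0.46` (about a factor of 3). For ionizable compounds the
realized rate additionally scales with $f_N(\text{pH}_\text{site})/f_N(7)$,
so normalizing back to pH 7 recovers the compound's intrinsic value — this
is what makes the speciation round-trip testable. The default environment
panel has 18 segments in five countries (13 contaminated, 5 pristine),
site pH uniform over a 1.6-unit band (6.9–8.5), incubation temperature
near 20.5 °C, and lognormal TOC, TCC and EC.

The default compound panel (12 compounds) spans rate constants of roughly
0.03–10 /day — half-lives of hours to weeks, the central range seen in
river screens — with neutral compounds, acids, bases, one zwitterion, two
sorbing bases ($f_\text{Dis} < 0.5$), slow hydrolysis for two compounds
and two biphasic compounds. A companion `monophasic_compound_panel()`
replaces the biphasic members with monophasic ones of similar magnitude;
it is used for parameter-recovery studies, where every cell must have a
well-defined estimand: a biphasic compound whose initial phase is
statistically invisible at some site (e.g. a strongly speciated acid at
low pH) has no unambiguous "true" single-slope value, and that situation
measures break-detection power, which is assessed separately.

### What the generator does and does not emulate

It reproduces the design geometry, censoring, multiplicative measurement
noise, between-segment lognormal variability, a TOC-correlated rate
level, speciation-driven pH dependence, sorption and abiotic loss. It
does **not** simulate chromatographic drift, matrix effects, calibration
curves, inter-laboratory effects, or correlated noise between replicates.
Passing tests therefore demonstrate that the evaluation chain is correct
and well-calibrated under the stated statistical model, not that any
particular field data set satisfies that model.

## Numerical choices and degenerate inputs

* Noiseless series fit exactly; a perfect single line (relative residual
  below $10^{-15}$ of total variation) short-circuits the break test to
  monophasic, avoiding 0/0 F statistics.
* An exact-fit ordination (residual variance numerically zero) reports
  the permutation floor $1/(B+1)$ directly instead of an undefined F.
* $f_\text{Dis}$ clamps: floor 0.01, cap 1. $\hat S(t)$ cap 1
  (equivalently $\hat k_\text{SC} \ge 0$).
* Chow ties break to the earliest candidate; candidate grid restricted to
  scheduled times.
* Analytical duplicates are treated as independent points in the pooled
  regression.
* Time is days everywhere; hour-denominated input columns are converted
  on read.
* All CSV output carries R's full 15-significant-digit conversion and
  round-trips losslessly.

## Problem sizes used by the test and acceptance suites

The suites run the full chain at the study's own scale: 12 compounds × 18
segments (216 cells, ~13 000 measurements) for recovery and pipeline
checks, 500 seeded runs for break-classifier specificity, and 200
repeats × 999 permutations for the permutation-calibration checks;
smaller constructed fixtures cover the exact hand-checkable cases. These
sizes give the statistical checks enough resolution (e.g. a binomial
standard error of about 1% on the specificity rate) while keeping a full
run in the order of a minute.

## Known limitations

* No nonlinear kinetic models (DFOP/HS as continuous fits), no
  error-in-variables regression, and no censored-likelihood (Tobit)
  fitting — censoring is handled by exclusion above the LOQ, as in the
  assay's own evaluation.
* The speciation model is proportional-uptake only; activity corrections,
  temperature-dependent pKa and microstate-resolved speciation are out of
  scope.
* Gap-filled values are order statistics of observed values, not
  model-based imputations; they deliberately carry no extra uncertainty
  into downstream summaries beyond their status labels.
* Spatial and seasonal variability cannot be separated by this design;
  the package makes no attempt to.
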