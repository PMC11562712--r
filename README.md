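# riverkin

Evaluation chain for river biodegradation screens of trace organic
chemicals. Starting from raw incubation time series — peak areas of
spiked micropollutants in water-sediment suspensions following a modified
OECD 309 design — the package estimates first-order biodegradation rate
constants, corrects them for sorption and ionization speciation,
gap-fills invalid estimates, quantifies spatial variability between river
segments, and attributes that variability to environmental factors by
constrained ordination. A synthetic-experiment generator emulates the
study design so the whole chain runs and is tested without laboratory
data.

It is written for environmental chemists and exposure modellers who work
with simulation-test kinetics and need a transparent, reproducible route
from integrated peak areas to comparable, pH-normalized rate constants.

## The model in brief

Dissolved-phase dissipation is first order. Per compound and river
segment, all points above the limit of quantification from three
replicate TEST vessels enter one regression of ln(area) on time:

    k_observed = − slope        [1/day]

after division by the fitted dissipation curve of the sterile sorption
control (SC). Biphasic (fast-then-slow) kinetics are detected by a Chow
structural-break F-test over the scheduled sampling times; when a break
is significant the initial-segment rate is reported. An estimate is valid
with ≥ 5 points and a one-sided p < 0.05 for a negative slope.

Two corrections make rates comparable across segments:

    k     = k_observed / f_Dis                  (sorption; f_Dis from the
                                                 SC/HC area quotient at t = 0)
    k_pH7 = k · f_N(7) / f_N(pH_site)           (speciation; f_N from
                                                 Henderson–Hasselbalch)

Invalid estimates are gap-filled by a three-step decision chain anchored
on their 99% confidence intervals (same-compound median → same-compound
minimum → global minimum of valid values). Spatial variability is the
standard deviation of log10 k across segments (its antilog is a fold
difference), with per-compound ANOVA on replicate-level fits, and a
redundancy analysis of log10 k_pH7 on ten standardized environmental
predictors with permutation tests (999 permutations).

## Worked example

The numbered scripts under `analysis/` run the chain on a synthetic
study: 12 compounds × 18 river segments in five countries, the 10-time
schedule over 10 days, 3 TEST + 2 SC + 1 HC replicates, 9% measurement
RSD, LOQ censoring.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_rates.R
Rscript analysis/03_correct_gapfill.R
Rscript analysis/04_variability.R
Rscript analysis/05_ordination.R
```

which prints, stage by stage:

```
simulated 12960 measurements (1067 censored, 8.2%) for 12 compounds x 18 segments
pH range across segments: 6.98 - 8.48
fitted 216 cells: 198 valid, 17 invalid, 1 not available
39 cells classified biphasic; median k_observed = 0.77 /d
gap-filled statuses: gapfilled_global_min=7, gapfilled_median=1, gapfilled_min_compound=9, not_available=1, valid=198
11 of 12 compounds valid at >= 12 of 18 segments
median stddev of log k_pH7 across all segments: 0.48 (a factor of 3)
100% of compounds differ significantly between segments (ANOVA)
median k_pH7 vs log10 TOC: Pearson r = 0.81 (p = 3.9e-05)
RDA on 10 compounds x 18 segments
model explains 73% of variance (35% unbiased), p = 0.001
first two constrained axes: 42% (RDA1 30%)
strongest envfit variables: toc (R2=0.71, p=0.001), do (R2=0.36, p=0.035), ph (R2=0.21, p=0.159)
```

Reading the output: a median between-segment spread of 0.48 log10 units
means a typical compound's rate constant varies by about a factor of 3
between segments; the generator's built-in TOC effect is recovered as the
dominant environmental correlate, and the Ezekiel-adjusted ("unbiased")
share of variance explained by the ten environmental factors is 35% in
this realization. All tables land under `results/`.

The same chain is available as a single call:

```r
library(riverkin)
bundle <- run_pipeline(pipeline_config(seed = 1))
bundle$variability$by_scope
```

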