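---
title: "Temporal clusters, quiet periods and cross-site synchrony: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal clusters, quiet periods and cross-site synchrony: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdsync)
```

## The problem

Kawasaki disease (KD) is an acute pediatric vasculitis of unknown etiology.
Its incidence is strongly seasonal (a winter/spring peak in the northern
hemisphere, a lesser mid-summer bump) and drifts slowly over the years, but
on top of that structure, surveillance series show short bursts of cases —
several onsets within about a week — and anomalously long stretches with no
cases at all. If environmental exposures trigger KD, such **clusters** and
**quiet periods** should occur more often than trend and seasonality alone
predict, and they may co-occur across distant sites that share large-scale
environmental drivers.

`kdsync` implements that analysis for per-site case onset-date series: local
episode detection, a trend- and seasonality-respecting Monte Carlo null, and
pairwise plus ensemble cross-site overlap significance. Because real patient
records are confidential, the package also ships a synthetic onset-series
generator emulating the scale and structure of real surveillance sites, and
the entire pipeline is validated against it.

## Local definitions and episode detection

For each day $d$ of a site's record, the density profile is
$m[d] = \max \{ \sum_{t \in W} c_t : W \ni d,\ |W| = 7 \}$, the largest
number of cases in any 7-day span containing $d$ (spans clipped at the record
edges). The site's cluster threshold is the 97.5th or 99.5th empirical
percentile of $\{m[d]\}$, rounded up to the next integer and used with a
$\ge$ comparison; maximal runs of qualifying days become clusters, which can
therefore extend well beyond 7 days (e.g. 11 cases over 15 consecutive
qualifying days). Symmetrically, every zero-case day carries the length of
its maximal zero run, the quiet threshold is a high percentile of those
lengths, and runs at or above it are quiet periods.

Three conventions are deliberate and documented rather than universal:

* **Percentile rule.** The empirical quantile uses linear interpolation
  between order statistics (R's default type 7), then a ceiling, with a
  floor of 1. On integer-valued profiles this guarantees an attainable tail
  threshold. Any other sane interpolation changes thresholds by at most one
  unit; per-site percentile overrides are configuration, not code.
* **Percentile choice.** By default low-incidence sites (mean under 60
  cases/year) use the 99.5th percentile for clusters — a single integer
  density value can span a wide percentile range when counts are small — and
  high-incidence sites use 99.5 for quiet periods, by the symmetric
  argument. Both are per-site configurable.
* **Edge clipping.** Windows never extend past the observation window: days
  outside it do not exist, so phantom zero-days are not invented.

A cluster's day-span may contain interior zero-case days whose density
profile still qualifies; patients belong to a cluster when their onset falls
anywhere in the span. Quiet periods by construction contain no cases, and
with percentile-derived thresholds the two episode kinds do not overlap in
practice (an assertable invariant in the test-suite's simulated conditions).

## The within-site null

The null model asks: given this site's long-term trend and average
seasonality, how much clustering arises by chance? Daily resampling weights
are

$$ w_d \propto \max\{\epsilon,\ \hat a + \hat b\,y_d\} \cdot s_{\mathrm{month}(d)}, $$

where $y_d$ is the fractional year, $(\hat a, \hat b)$ is a least-squares
line through annual incidence rates (annual totals divided by the days of
that year inside the window, day-weighted, so partial edge years do not bias
the slope), and $s_m$ is calendar month $m$'s per-day case rate. Both
factors are floored at a small positive constant ($10^{-6}$ of their mean)
so no calendar day has probability exactly zero; a record spanning a single
calendar year falls back to a flat trend with a warning. A synthetic control
series draws exactly $N$ onset dates with replacement from $w$ — equal-N by
construction — and episodes are re-detected in each replicate **with the
thresholds derived from the observed record**. The default ensemble size is
100 replicates.

The observed distribution of per-cluster case counts (and of quiet-period
lengths, unit-day bins up to the null's 99th percentile plus one overflow
bin) is compared bin-by-bin against the replicate ensemble. A bin is flagged
when the observed count falls outside the null mean ± 2 standard deviations
of the replicate counts. The spread used is the SD of the null distribution
itself, not the SD of its mean: the question is whether the observed record
looks like *one draw* from the null, and with the mean's standard error the
band would shrink with the replicate count and flag nearly every bin of a
perfectly null series. Under self-consistency simulations (the "observed"
series itself drawn from the fitted null) the average flagged fraction is
about 3%.

## Cross-site overlap

Cluster overlap is directional: the fraction of reference-site clusters
whose span, padded by ±6 days, intersects any cluster at the other site.
The pad absorbs onset-date uncertainty and allows lagged common exposure.
Quiet-period overlap uses no pad — quiet endpoints are sharply defined by
the next case — and is day-weighted: for each reference quiet period, the
fraction of its days lying inside the other site's quiet periods, averaged
(unweighted) across reference episodes. A pooled variant (total shared days
over total quiet days) is available behind a flag. Interval intersection is
computed on closed calendar-aligned intervals; a one-day touch counts.
Cross-site work should use a common analysis window
(`restrict_series()`, post-2000 by default, when diagnostic awareness is
comparable across sites); sites with no episodes in the window yield missing
overlaps, not zeros.

### The null for overlaps, and why the default is series resampling

Two null constructions are implemented:

* `resample_series` (default): draw a full equal-N series from the site's
  weight model and re-detect episodes with the observed thresholds.
* `shuffle_episodes`: keep each observed episode's duration and redraw its
  start day — clusters with probability proportional to $w$, quiet periods
  proportional to $\exp(-N \sum_{d \in \mathrm{span}} w_d)$ (the null
  probability that the span is empty) — rejecting placements that land on an
  already-placed episode.

The default matters. Detected clusters concentrate in the high season more
sharply than the daily rate itself, because threshold exceedance is a highly
nonlinear function of the rate. Measured on independent synthetic site
pairs, the duration-preserving shuffle gives a null overlap mean of 0.15
where truly independent observed pairs average 0.236; the resampling null
reproduces 0.238. An anticonservative null would manufacture spurious
synchrony, so `resample_series` is the default and the shuffle is retained
as a sensitivity switch.

### Significance and the ensemble statistic

A pair is flagged when its observed overlap exceeds the null mean by more
than two null standard deviations (one-sided: excess overlap). The whole
flag computation is repeated `R_outer` times with fresh inner ensembles
(`R_inner` realizations each, 500 × 500 at full scale): `S[i,j]` is the
fraction of repetitions flagging the pair, `Tn` the per-repetition count of
flagged ordered pairs, and the null reference for `Tn` is obtained by
letting each synthetic member play "observed" against the remaining members
(leave-one-out mean and SD). The SD threshold is applied to overlap
*fractions*, not counts.

The >2 SD rule is not an exact 2.5% test: the null overlap distribution is
discrete and right-skewed (fractions over a few dozen episodes), and for a
fixed pair of records the observed overlap is constant across repetitions,
so `S[i,j]` is close to all-or-nothing. Measured over many independently
generated site pairs the per-direction flag rate under full independence is
about 5%, and rises well past one half when five shared 7-day bursts (about
three times a typical local threshold, lags up to 6 days) are injected.
That separation — not the nominal size — is what the test suite asserts.

## The synthetic-data generator

`simulate_site()` draws baseline onsets i.i.d. from the same
trend × monthly-weight construction the null uses (multinomial with
replacement, keeping generator and null mutually consistent), then adds
burst cases uniformly within burst spans, and forces gap intervals to zero.
Defaults emulate a mid-range surveillance site: 1,000 cases over 15 years
(about 67/year), winter-peaked monthly weights with a small July bump, flat
trend. Test fixtures use sizes between 200 and 5,000 cases and windows of
8–20 years, matching the span of real sites (roughly 200–2,300 cases over
11–20 years).

Synchrony is injected by adding shared bursts to several sites at a common
date plus per-site lags of 0–6 days. In the validation fixtures the shared
bursts are spread across the calendar year: all-winter bursts would sit
where the seasonal null already concentrates coincidental overlap, testing
seasonality rather than the anomalous synchrony the method targets.

What the generator does **not** emulate: reporting artifacts (onset dates
estimated from hospitalization dates), week-of-year reporting cycles,
overdispersion beyond the multinomial, multi-year epidemic waves, or any
mechanistic transmission. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated generative assumptions, not that
real records satisfy those assumptions.

## Numerical and design choices

* Day intervals are inclusive on both ends; internal day indices are
  0-based offsets from the window start; dates are ISO-8601 on disk.
* Thresholds are integers; comparisons are `>=`.
* RNG: every stochastic function takes a `seed`; streams are split
  deterministically (a fixed linear-congruential child-seed map below
  $2^{31}$), and the global RNG state is always restored.
* `local_threshold()` subtracts $10^{-9}$ before the ceiling to guard
  against floating-point exact-integer quantiles.
* Zero-weight floors: $10^{-6}$ of the mean rate (trend) and mean monthly
  rate (seasonality); the generator floors daily weights at $10^{-6}$
  before gap masking.
* `R_inner < 30` is rejected outright — an SD estimated from fewer
  synthetic overlaps is unusable for the 2 SD rule.
* Episode shuffling retries a placement up to 500 times before giving up
  with a pointer to `resample_series` (relevant only for very dense episode
  sets).

## Problem sizes in the shipped validation

The test suite and the acceptance script exercise: 200 random fixtures
(records up to 400 days) against exhaustive brute-force oracles; 100
parameter-recovery runs at 5,000 cases; 50 null self-consistency runs and 50
burst-detectability runs at 100 replicates each; 40 independent and 10
synchronized site-pair significance runs at `R_inner` 100; and one 6-site
ensemble (four synchronized pairs) at 100 × 100 repetitions. These sizes
give stable rates while keeping a full run to a few minutes; the full-scale
500 × 500 setting is a configuration change, not a code path change.

## Known limitations

* The percentile interpolation convention cannot be validated against the
  real sites' thresholds (the patient records are confidential); it is
  documented configuration.
* The trend component is linear; sites with strongly non-linear incidence
  histories (e.g. epidemic waves) would need a richer trend model before
  the null is credible.
* Quiet-period overlap between sites with very different window lengths is
  sensitive to the aggregation choice (mean-of-fractions vs pooled days);
  both are provided.
* No multiple-testing correction is applied beyond the Monte Carlo ensemble
  construction itself, by design.
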