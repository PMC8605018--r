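# kdsync

Temporal cluster, quiet-period and cross-site synchrony analysis for
disease onset-date series.

Kawasaki disease (KD) surveillance records — one onset date per patient —
show more structure than their well-known seasonality: short bursts of
cases within about a week, anomalously long stretches with no cases, and
suspicious co-timing of both across distant sites. `kdsync` implements the
statistical pipeline for detecting and testing these phenomena, for
epidemiologists analyzing sparse event-onset series:

* **Local definitions.** For each day, the maximum number of cases in any
  7-day window containing it, `m[d]`; the site's cluster threshold is the
  97.5th/99.5th percentile of `m` (ceiling, used with `>=`), and maximal
  runs of qualifying days are clusters. Quiet periods are maximal zero-case
  runs at or above a percentile-derived gap threshold.
* **Within-site null.** 100 equal-N synthetic control series drawn from
  daily weights `w[d] ∝ trend(d) × monthly(month(d))` (a linear fit to
  annual rates times the mean monthly pattern); the observed cluster-size
  and quiet-length histograms are compared to the replicate ensemble, with
  bins flagged outside mean ± 2 SD.
* **Cross-site overlap.** Directional overlap `O[i,j]`: the fraction of
  site *i*'s clusters within ±6 days of a cluster at site *j* (quiet
  periods: day-weighted shared fraction, no pad). Significance is Monte
  Carlo: a pair is flagged when its observed overlap exceeds the synthetic
  mean by > 2 SD; repeating with fresh ensembles gives the flag fraction
  `S[i,j]` and the distribution of `Tn`, the number of flagged pairs, versus
  its leave-one-out synthetic reference.
* **Synthetic data.** Because patient records are confidential, a
  generator produces realistic series (seasonality, trend, injected bursts
  and gaps, cross-site burst synchrony with 0–6 day lags) so the whole
  pipeline is testable end-to-end.

## Worked example

```r
library(kdsync)

# a synthetic site at realistic scale: ~1332 baseline cases over 18 years,
# winter-peaked seasonality, rising trend, three injected 15-case bursts
spec <- site_sim_spec("SD-like", n_cases = 1332,
                      start_date = "1997-01-01", end_date = "2014-12-31",
                      trend_slope = 0.03,
                      bursts = data.frame(
                        center = c("2003-02-01", "2008-12-10", "2011-06-20"),
                        duration = 7, n_extra = 15))
series <- simulate_site(spec, seed = 42)

fit <- kd_fit(series, replicates = 100, seed = 1)
fit
#> Temporal clustering fit for 'SD-like'
#>   1377 cases, 1997-01-01 .. 2014-12-31
#>   cluster definition: >= 6 cases in 7 days (p97.5) -> 20 clusters, 14% of patients
#>   quiet definition:   >= 45 zero-case days (p99.5) -> 1 quiet periods
#>   null ensemble: 100 equal-N replicates

summary(fit)
#>  site_id n_patients n_clusters n_patients_in_clusters fraction_in_clusters
#>  SD-like       1377         20                    187            0.1358025
#>  n_quiet_periods cluster_threshold cluster_percentile quiet_threshold
#>                1                 6               97.5              45
#>  quiet_percentile
#>              99.5
#> trend slope: 0.00377 cases/day per year
#> cluster bins outside the null mean +/- 2 SD band: 16, 18, 26
#> quiet bins outside the null mean +/- 2 SD band: 45
```

Reading the output: the site's local cluster definition came out as 6 cases
in 7 days; 20 clusters hold 13.6% of all patients (real sites range from
12% to 28%). The three injected 15-case bursts produce clusters of 16, 18
and 26 cases — exactly the bins flagged above the null band, which 100
trend- and seasonality-respecting resamples cannot explain. `plot(fit)`
draws the observed-vs-null histogram; `coef(fit)`, `predict(fit)`,
`simulate(fit)` and `residuals(fit)` expose the fitted weight model, its
daily weights, equal-N synthetic controls, and per-bin excesses.

Cross-site significance on a list of fitted sites:

```r
ot <- ensemble_significance(fits, kind = "cluster",
                            R_inner = 500, R_outer = 500, seed = 11)
summary(ot)   # flagged pairs, S matrix, Tn medians
```

`run_pipeline(config)` drives the whole analysis (detection → null
comparison → overlap) from a YAML/JSON config and writes every table as CSV
plus a JSON manifest; reruns with the same manifest are byte-identical.

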