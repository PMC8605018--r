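test_that("simulation is deterministic given a seed", {
  spec <- site_sim_spec("d", n_cases = 300, trend_slope = 0.03,
                        bursts = data.frame(center = "2005-02-01",
                                            duration = 7, n_extra = 10))
  a <- simulate_site(spec, seed = 11)
  b <- simulate_site(spec, seed = 11)
  c <- simulate_site(spec, seed = 12)
  expect_identical(a$onsets, b$onsets)
  expect_false(identical(a$onsets, c$onsets))
  expect_equal(length(a$onsets), 310) # baseline + burst extras
})

test_that("flat weights give uniform monthly totals within 3 binomial SDs", {
  s <- simulate_site(flat_spec(n = 3000, seed = 21))
  mon <- as.POSIXlt(s$onsets)$mon + 1
  days <- as.POSIXlt(seq(s$start_date, s$end_date, by = "day"))$mon + 1
  for (m in 1:12) {
    p <- mean(days == m)
    expect_lt(abs(sum(mon == m) - 3000 * p), 3 * sqrt(3000 * p * (1 - p)))
  }
})

test_that("a rate-doubling trend doubles the second-half yield", {
  # slope 1/T doubles the daily rate across a T-year window; with flat
  # seasonality the expected second/first half case ratio is the weight
  # integral ratio (7/8)/(5/8) = 1.4
  spec <- site_sim_spec("t", n_cases = 20000,
                        monthly_weights = rep(1, 12),
                        trend_slope = 1 / 15)
  s <- simulate_site(spec, seed = 31)
  mid <- s$start_date + n_days(s) %/% 2
  ratio <- sum(s$onsets >= mid) / sum(s$onsets < mid)
  expect_lt(abs(ratio - 1.4), 0.08)
})

test_that("forced gaps always contain zero onsets", {
  spec <- site_sim_spec("g", n_cases = 2000,
                        gaps = data.frame(start = "2000-04-10",
                                          length = 31))
  for (seed in 1:5) {
    s <- simulate_site(spec, seed = seed)
    gap_days <- seq(as.Date("2000-04-10"), by = "day", length.out = 31)
    expect_equal(sum(s$onsets %in% gap_days), 0)
  }
  bad <- site_sim_spec("g2", n_cases = 10, start_date = "2000-01-01",
                       end_date = "2000-03-01",
                       gaps = data.frame(start = "2000-01-01", length = 61))
  expect_error(simulate_site(bad, seed = 1), "all-zero")
})

test_that("ensemble with no synchrony equals independent simulation", {
  specs <- lapply(1:3, function(i) site_sim_spec(paste0("S", i),
                                                 n_cases = 200))
  a <- simulate_ensemble(specs, sync = NULL, seed = 5)
  b <- simulate_ensemble(specs, sync = synchrony_spec(character(0),
                                                      "2002-01-01"),
                         seed = 5)
  expect_identical(lapply(a, `[[`, "onsets"), lapply(b, `[[`, "onsets"))
  expect_error(simulate_ensemble(specs,
                                 synchrony_spec("nope", "2002-01-01"),
                                 seed = 5),
               "unknown site_id")
})

test_that("shared bursts put the inflation count into each site's window", {
  specs <- lapply(1:2, function(i) site_sim_spec(paste0("S", i),
                                                 n_cases = 100))
  bursts <- as.Date(c("2003-01-10", "2004-02-01", "2005-12-20",
                      "2006-01-05", "2008-02-14"))
  sync <- synchrony_spec(c("S1", "S2"), bursts, inflation = 12,
                         duration = 7, lags = c(S1 = 0, S2 = 4))
  ens <- simulate_ensemble(specs, sync, seed = 9)
  for (id in c("S1", "S2")) {
    lag <- sync$lags[[id]]
    for (b in bursts) {
      win <- seq(as.Date(b, origin = "1970-01-01") + lag, by = "day",
                 length.out = 7)
      expect_gte(sum(ens[[id]]$onsets %in% win), 12)
    }
  }
})

test_that("seasonality is recoverable from a large simulated series", {
  w <- winter_monthly_weights()
  s <- simulate_site(site_sim_spec("w", n_cases = 20000), seed = 13)
  mon <- as.POSIXlt(s$onsets)$mon + 1
  days_m <- tabulate(as.POSIXlt(seq(s$start_date, s$end_date,
                                    by = "day"))$mon + 1, 12)
  rate_m <- tabulate(mon, 12) / days_m
  expect_gt(cor(rate_m, w), 0.9)
})

test_that("injected bursts are found by episode detection", {
  base <- site_sim_spec("p", n_cases = 1000)
  thr <- site_definition(simulate_site(base, seed = 1))$cluster_threshold
  spec <- site_sim_spec("p", n_cases = 1000,
                        bursts = data.frame(center = "2007-06-15",
                                            duration = 7,
                                            n_extra = 5 * thr))
  hits <- vapply(1:10, function(seed) {
    s <- simulate_site(spec, seed = seed)
    f <- kd_fit(s, replicates = 0)
    any(f$clusters$first_date <= as.Date("2007-06-18") &
          f$clusters$last_date >= as.Date("2007-06-12"))
  }, logical(1))
  expect_true(all(hits))
})
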