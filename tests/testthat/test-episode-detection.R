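test_that("density profile matches hand-enumerated windows", {
  expect_equal(density_profile(rep(0L, 20)), rep(0L, 20))

  x <- integer(30); x[11] <- 1L # single case on day index 10 (0-based)
  m <- density_profile(x, 7)
  expect_equal(which(m == 1), 5:17) # every 7-day window touching day 11
  expect_true(all(m[-(5:17)] == 0))

  # record shorter than the window: one clipped window = whole record
  expect_equal(density_profile(c(1L, 0L, 2L), 7), rep(3L, 3))
})

test_that("density and detection agree with the brute-force oracle", {
  set.seed(42)
  for (i in 1:25) {
    x <- random_counts()
    w <- sample(2:10, 1)
    expect_equal(density_profile(x, w), as.integer(oracle_density(x, w)))
    thr <- sample(1:5, 1)
    got <- detect_clusters(x, thr, w)
    want <- oracle_clusters(x, thr, w)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) {
      origin <- as.Date("2000-01-01") # default origin for bare vectors
      expect_equal(as.integer(got$first_date - origin) + 1, want[, 1])
      expect_equal(as.integer(got$last_date - origin) + 1, want[, 2])
      expect_equal(got$n_cases, want[, 3])
    }
  }
})

test_that("percentile thresholds follow the ceiling-of-quantile rule", {
  expect_equal(local_threshold(rep(3, 1000), 97.5), 3L)

  # 990 zero days and 10 ten-days: the 97.5th type-7 quantile sits among
  # the zeros, and the threshold is clamped to its floor of 1
  prof <- c(rep(0, 990), rep(10, 10))
  expect_equal(local_threshold(prof, 97.5), 1L)

  set.seed(7)
  for (i in 1:20) {
    p <- rpois(sample(50:500, 1), runif(1, 0.5, 4))
    expect_gte(local_threshold(p, 99.5), local_threshold(p, 97.5))
  }
  expect_error(local_threshold(rep(NA_integer_, 5), 97.5), "quiet periods")
  expect_error(local_threshold(1:5, 90), "97.5 or 99.5")
})

test_that("clusters span the full window of qualifying days", {
  x <- integer(30); x[10:14] <- 1L # one case per day, days 10-14 (1-based)
  got <- detect_clusters(x, 5, 7)
  expect_equal(nrow(got), 1)
  expect_equal(got$length, 9) # qualifying days 9..17 (1-based)
  expect_equal(got$n_cases, 5)

  # 11 cases over two heavy days two apart -> one 15-day cluster
  x2 <- integer(40); x2[11] <- 5L; x2[12] <- 1L; x2[13] <- 5L
  got2 <- detect_clusters(x2, 5, 7)
  expect_equal(nrow(got2), 1)
  expect_equal(got2$n_cases, 11)
  expect_equal(got2$length, 15)
})

test_that("threshold 1 saturates to every day within a window of a case", {
  set.seed(3)
  x <- random_counts(D = 120, lambda = 0.1)
  got <- detect_clusters(x, 1, 7)
  in_cluster <- logical(120)
  for (k in seq_len(nrow(got))) {
    a <- as.integer(got$first_date[k] - as.Date("2000-01-01")) + 1
    b <- as.integer(got$last_date[k] - as.Date("2000-01-01")) + 1
    in_cluster[a:b] <- TRUE
  }
  case_days <- which(x > 0)
  near_case <- vapply(seq_len(120), function(d)
    any(abs(case_days - d) <= 6), logical(1))
  expect_equal(in_cluster, near_case)
})

test_that("quiet periods are maximal zero runs at or above the threshold", {
  expect_equal(nrow(detect_quiet(rep(1L, 50), 3)), 0)

  x <- c(1, rep(0, 3), 1, rep(0, 8), 2, rep(0, 12), 1)
  got <- detect_quiet(x, 8)
  expect_equal(nrow(got), 2)
  expect_equal(sort(got$length), c(8L, 12L))

  got1 <- detect_quiet(x, 1)
  expect_equal(sort(got1$length), c(3L, 8L, 12L))
})

test_that("raising the cluster threshold never grows the clustered days", {
  set.seed(11)
  for (i in 1:10) {
    x <- random_counts(D = 300, lambda = 0.4)
    days <- vapply(1:6, function(thr) {
      e <- detect_clusters(x, thr, 7)
      sum(e$length)
    }, numeric(1))
    expect_true(all(diff(days) <= 0))
  }
})

test_that("site summaries report the standard schema", {
  # all cases in one dense burst -> everything clustered
  s <- onset_series(rep(c("2005-01-10", "2005-01-11"), 10), "burst",
                    "2000-01-01", "2009-12-31")
  row <- site_summary(s)
  expect_equal(row$fraction_in_clusters, 1.0)
  expect_equal(row$n_patients_in_clusters, 20)

  # unattainable threshold -> no clusters at all
  defs <- site_definition(s)
  defs$cluster_threshold <- 999L
  row2 <- site_summary(s, defs)
  expect_equal(row2$n_clusters, 0)
  expect_equal(row2$fraction_in_clusters, 0)
})

test_that("detected episodes respect the structural invariants", {
  for (seed in 1:6) {
    s <- simulate_site(site_sim_spec("inv", n_cases = 800), seed = seed)
    f <- kd_fit(s, replicates = 0)
    cnt <- as.integer(daily_counts(s))
    origin <- s$start_date
    # quiet periods contain zero cases on every day
    for (k in seq_len(nrow(f$quiet))) {
      a <- as.integer(f$quiet$first_date[k] - origin) + 1
      b <- as.integer(f$quiet$last_date[k] - origin) + 1
      expect_equal(sum(cnt[a:b]), 0)
    }
    # patients in clusters never exceed total patients
    expect_lte(sum(f$clusters$n_cases), length(s$onsets))
    # clusters and quiet periods never share a day
    if (nrow(f$quiet) && nrow(f$clusters)) {
      qdays <- unlist(Map(seq, as.integer(f$quiet$first_date),
                          as.integer(f$quiet$last_date)))
      cdays <- unlist(Map(seq, as.integer(f$clusters$first_date),
                          as.integer(f$clusters$last_date)))
      expect_length(intersect(qdays, cdays), 0)
    }
    # episodes sorted with a gap of at least one day
    for (e in list(f$clusters, f$quiet)) {
      if (nrow(e) > 1)
        expect_true(all(diff(as.integer(e$first_date)) > 0) &&
                      all(e$first_date[-1] > e$last_date[-nrow(e)] + 1))
    }
  }
})
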