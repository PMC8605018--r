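origin <- as.Date("2000-01-01")

ep <- function(first, last, kind = "cluster", id = "x") {
  kd_episodes(origin + first, origin + last,
              if (kind == "cluster") rep(1L, length(first)) else NULL,
              kind = kind, site_id = id)
}

test_that("cluster overlap follows padded interval intersection", {
  ref <- ep(c(10, 50), c(12, 55))
  oth <- ep(c(20, 60), c(21, 61))
  # only [50,55] reaches [60,61] under a 6-day pad
  expect_equal(cluster_overlap(ref, oth, pad = 6), 0.5)
  expect_equal(cluster_overlap(oth, ref, pad = 6), 0.5)
  expect_equal(cluster_overlap(ref, ref), 1.0)
  expect_equal(cluster_overlap(oth, oth), 1.0)

  # directionality: two ref clusters near one other cluster
  ref2 <- ep(c(10, 30), c(11, 31))
  oth2 <- ep(12, 13)
  expect_equal(cluster_overlap(ref2, oth2), 0.5)
  expect_equal(cluster_overlap(oth2, ref2), 1.0)

  expect_error(cluster_overlap(ref, ep(1, 20, kind = "quiet")),
               "cluster episode sets")
})

test_that("quiet overlap is day-weighted with no pad", {
  ref <- ep(100, 109, kind = "quiet")
  oth <- ep(105, 120, kind = "quiet")
  expect_equal(quiet_overlap(ref, oth), 0.5)
  expect_equal(quiet_overlap(ep(1, 10, kind = "quiet"),
                             ep(50, 60, kind = "quiet")), 0)
  expect_equal(quiet_overlap(ref, ep(0, 400, kind = "quiet")), 1.0)

  # aggregation across episodes: mean of fractions vs pooled days
  ref2 <- ep(c(10, 100), c(11, 139), kind = "quiet") # lengths 2 and 40
  oth2 <- ep(c(10, 100), c(11, 119), kind = "quiet") # covers 2 and 20
  expect_equal(quiet_overlap(ref2, oth2), mean(c(1, 0.5)))
  expect_equal(quiet_overlap(ref2, oth2, method = "pooled_days"), 22 / 42)
  expect_error(quiet_overlap(ref, ep(1, 2)), "quiet episode sets")
})

test_that("overlaps agree with the day-set oracle and grow with the pad", {
  set.seed(19)
  for (i in 1:25) {
    a <- random_episode_set()
    b <- random_episode_set()
    ai <- cbind(as.integer(a$first_date), as.integer(a$last_date))
    bi <- cbind(as.integer(b$first_date), as.integer(b$last_date))
    expect_equal(cluster_overlap(a, b), oracle_cluster_overlap(ai, bi))
    pads <- vapply(c(0, 3, 6, 12), function(p)
      cluster_overlap(a, b, pad = p), numeric(1))
    if (!anyNA(pads)) expect_true(all(diff(pads) >= 0))

    aq <- random_episode_set("quiet")
    bq <- random_episode_set("quiet")
    aqi <- cbind(as.integer(aq$first_date), as.integer(aq$last_date))
    bqi <- cbind(as.integer(bq$first_date), as.integer(bq$last_date))
    expect_equal(quiet_overlap(aq, bq), oracle_quiet_overlap(aqi, bqi))
    expect_equal(quiet_overlap(aq, bq, method = "pooled_days"),
                 oracle_quiet_overlap(aqi, bqi, pooled = TRUE))
  }
})

test_that("overlap matrices have a unit diagonal where episodes exist", {
  ser <- simulate_ensemble(lapply(1:3, function(i)
    site_sim_spec(paste0("S", i), n_cases = 700)), seed = 23)
  fits <- lapply(ser, kd_fit, replicates = 0)
  O <- overlap_matrix(fits, "cluster")
  expect_equal(unname(diag(O)), rep(1, 3))
  expect_true(all(O >= 0 & O <= 1, na.rm = TRUE))
})

test_that("pairs with no reference episodes are reported missing", {
  s <- simulate_site(site_sim_spec("z", n_cases = 700), seed = 2)
  f <- kd_fit(s, replicates = 0)
  empty <- list(episodes = kd_episodes(as.Date(character(0)),
                                       as.Date(character(0))),
                model = f$model)
  v <- pair_null_overlaps(empty, f, "cluster", R = 10,
                          mode = "shuffle_episodes", seed = 1)
  expect_true(all(is.na(v)))
  expect_true(is.na(cluster_overlap(empty$episodes, f$clusters)))
})

test_that("null overlap generation is seeded and well-formed", {
  ser <- simulate_ensemble(lapply(1:2, function(i)
    site_sim_spec(paste0("S", i), n_cases = 800)), seed = 31)
  fits <- lapply(ser, kd_fit, replicates = 0)
  for (mode in c("resample_series", "shuffle_episodes")) {
    v1 <- pair_null_overlaps(fits[[1]], fits[[2]], "cluster", R = 25,
                             mode = mode, seed = 4)
    v2 <- pair_null_overlaps(fits[[1]], fits[[2]], "cluster", R = 25,
                             mode = mode, seed = 4)
    expect_identical(v1, v2)
    expect_true(all(v1 >= 0 & v1 <= 1))
  }
  # quiet resamples may legitimately have zero episodes (missing fraction)
  vq <- pair_null_overlaps(fits[[1]], fits[[2]], "quiet", R = 10, seed = 5)
  expect_true(all(is.na(vq) | (vq >= 0 & vq <= 1)))
})

test_that("ensemble significance validates its inputs", {
  ser <- simulate_ensemble(lapply(1:2, function(i)
    site_sim_spec(paste0("S", i), n_cases = 600)), seed = 41)
  fits <- lapply(ser, kd_fit, replicates = 0)
  expect_error(ensemble_significance(fits[1], "cluster"), "two sites")
  expect_error(ensemble_significance(fits, "cluster", R_inner = 10),
               "R_inner")
  expect_error(ensemble_significance(fits, "cluster", R_inner = 40,
                                     R_outer = 2, exclude = "S2"),
               "two sites")
})

test_that("perfectly coincident abundant clusters are always flagged", {
  # identical, abundant cluster sets in both sites, nulls independent:
  # observed overlap 1.0 in both directions, far beyond any null draw
  starts <- seq(40, 5300, by = 260)
  shared <- ep(starts, starts + 2)
  sites <- lapply(1:2, function(i) {
    s <- simulate_site(site_sim_spec(paste0("S", i), n_cases = 800),
                       seed = 60 + i)
    list(episodes = shared, model = fit_weight_model(s))
  })
  names(sites) <- c("S1", "S2")
  ot <- ensemble_significance(sites, "cluster", R_inner = 50, R_outer = 10,
                              mode = "shuffle_episodes", seed = 6)
  expect_equal(unname(ot$S[1, 2]), 1)
  expect_equal(unname(ot$S[2, 1]), 1)
  expect_true(all(ot$Tn_observed == 2))
})
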