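# Exhaustive brute-force oracles, kept deliberately naive and independent
# of the package's vectorized implementations.

oracle_density <- function(x, w = 7) {
  D <- length(x)
  vapply(seq_len(D), function(d) {
    best <- 0
    for (s in (d - w + 1):d) {
      a <- max(1, s)
      b <- min(D, s + w - 1)
      best <- max(best, sum(x[a:b]))
    }
    best
  }, numeric(1))
}

oracle_clusters <- function(x, thr, w = 7) {
  m <- oracle_density(x, w)
  inside <- m >= thr
  out <- NULL
  d <- 1
  while (d <= length(x)) {
    if (inside[d]) {
      e <- d
      while (e < length(x) && inside[e + 1]) e <- e + 1
      out <- rbind(out, c(d, e, sum(x[d:e])))
      d <- e + 1
    } else d <- d + 1
  }
  out
}

oracle_quiet <- function(x, thr) {
  out <- NULL
  d <- 1
  while (d <= length(x)) {
    if (x[d] == 0) {
      e <- d
      while (e < length(x) && x[e + 1] == 0) e <- e + 1
      if (e - d + 1 >= thr) out <- rbind(out, c(d, e))
      d <- e + 1
    } else d <- d + 1
  }
  out
}

# day-set versions of the overlap statistics
oracle_cluster_overlap <- function(ref, oth, pad = 6) {
  if (nrow(ref) == 0) return(NA_real_)
  oth_days <- unlist(apply(oth, 1, function(r) seq(r[1], r[2])))
  hits <- apply(ref, 1, function(r)
    length(intersect(seq(r[1] - pad, r[2] + pad), oth_days)) > 0)
  mean(hits)
}

oracle_quiet_overlap <- function(ref, oth, pooled = FALSE) {
  if (nrow(ref) == 0) return(NA_real_)
  oth_days <- unlist(apply(oth, 1, function(r) seq(r[1], r[2])))
  fr <- apply(ref, 1, function(r) {
    days <- seq(r[1], r[2])
    c(length(intersect(days, oth_days)), length(days))
  })
  if (pooled) sum(fr[1, ]) / sum(fr[2, ]) else mean(fr[1, ] / fr[2, ])
}

# random sparse count fixture
random_counts <- function(D = NULL, lambda = NULL) {
  D <- D %||% sample(30:400, 1)
  lambda <- lambda %||% stats::runif(1, 0.02, 0.6)
  stats::rpois(D, lambda)
}

# random non-overlapping interval set on absolute days, as kd_episodes
random_episode_set <- function(kind = "cluster", origin = as.Date("2000-01-01"),
                               D = 400, max_n = 8) {
  n <- sample(0:max_n, 1)
  if (n == 0)
    return(kd_episodes(as.Date(character(0)), as.Date(character(0)),
                       kind = kind))
  cand_start <- sort(sample.int(D - 10, n))
  cand_last <- pmin(cand_start + sample(1:8, n, replace = TRUE) - 1, D)
  starts <- integer(0); last <- integer(0)
  for (i in seq_len(n)) { # greedy: keep only intervals clear of the previous
    if (!length(last) || cand_start[i] > last[length(last)] + 1) {
      starts <- c(starts, cand_start[i])
      last <- c(last, cand_last[i])
    }
  }
  kd_episodes(origin + starts, origin + last,
              if (kind == "cluster") rep(1L, length(starts)) else NULL,
              kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flat_spec <- function(site_id = "flat", n = 2000, seed = 1, ...) {
  site_sim_spec(site_id, n_cases = n, monthly_weights = rep(1, 12),
                trend_slope = 0, seed = seed, ...)
}
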