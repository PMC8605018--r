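#' Fit the trend-and-seasonality weight model for a site
#'
#' The Monte Carlo null resamples onset dates from per-day probability
#' weights composed of the site's long-term trend and its average monthly
#' pattern. The trend is a least-squares line through annual incidence
#' rates (annual totals divided by days observed that year, so partial edge
#' years are handled; fits are day-weighted), evaluated at each day's
#' fractional year and floored at a small positive constant. The monthly
#' factor is each calendar month's per-day case rate. The daily weight is
#' their product, normalized.
#'
#' @param series an [onset_series()] spanning at least two calendar years
#'   (a single-year record falls back to a flat trend with a warning).
#' @return A list of class `weight_model` with the normalized daily weights
#'   `w`, `trend` coefficients (intercept and slope, per-day rate per
#'   year), the `monthly` per-day factors, and window metadata.
#' @export
fit_weight_model <- function(series) {
  stopifnot(inherits(series, "onset_series"))
  dates <- seq(series$start_date, series$end_date, by = "day")
  lt <- as.POSIXlt(dates)
  yr <- lt$year + 1900L
  mon <- lt$mon + 1L
  ydays <- ifelse((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0, 366, 365)
  fy <- yr + lt$yday / ydays
  N <- length(series$onsets)
  D <- length(dates)

  on_lt <- as.POSIXlt(series$onsets)
  cases_mon <- tabulate(on_lt$mon + 1L, nbins = 12)
  days_mon <- tabulate(mon, nbins = 12)
  s_mon <- ifelse(days_mon > 0, cases_mon / pmax(days_mon, 1L), 0)
  s_mon <- pmax(s_mon, 1e-6 * max(mean(s_mon), 1e-12)) # zero-month floor

  years <- sort(unique(yr))
  if (length(years) >= 2) {
    n_y <- tabulate(match(on_lt$year + 1900L, years), nbins = length(years))
    d_y <- tabulate(match(yr, years), nbins = length(years))
    ctr_y <- vapply(years, function(y) mean(fy[yr == y]), numeric(1))
    fit <- stats::lm(I(n_y / d_y) ~ ctr_y, weights = d_y)
    ab <- stats::coef(fit)
  } else {
    warning("series spans a single calendar year; trend set to constant",
            call. = FALSE)
    ab <- c(N / D, 0)
  }
  t_d <- pmax(ab[1] + ab[2] * fy, 1e-6 * max(N / D, 1e-12))
  w <- t_d * s_mon[mon]
  w <- w / sum(w)
  structure(list(site_id = series$site_id, start_date = series$start_date,
                 end_date = series$end_date, D = D, n = N, w = w,
                 trend = c(intercept = unname(ab[1]), slope = unname(ab[2])),
                 monthly = s_mon),
            class = "weight_model")
}

#' @export
print.weight_model <- function(x, ...) {
  cat("Weight model for '", x$site_id, "': ", x$n, " cases over ", x$D,
      " days\n  trend slope ", format(x$trend["slope"], digits = 3),
      " cases/day per year; monthly factor range ",
      format(min(x$monthly), digits = 3), " .. ",
      format(max(x$monthly), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
coef.weight_model <- function(object, ...) {
  c(object$trend,
    stats::setNames(object$monthly, paste0("monthly.", month.abb)))
}

#' Draw a synthetic control onset series from a weight model
#'
#' Selects `n` dates with replacement from the observation window using the
#' fitted daily weights — an equal-N resample respecting trend and
#' seasonality.
#'
#' @param model a [fit_weight_model()] result.
#' @param n number of onsets (defaults to the observed count).
#' @param seed RNG seed for determinism.
#' @return An [onset_series()].
#' @export
draw_null_series <- function(model, n = model$n, seed = NULL) {
  stopifnot(inherits(model, "weight_model"), n >= 0)
  with_seed(seed, {
    idx <- if (n > 0)
      sample.int(model$D, n, replace = TRUE, prob = model$w)
    else integer(0)
    onset_series(model$start_date + idx - 1L, model$site_id,
                 model$start_date, model$end_date)
  })
}

#' Monte Carlo null ensemble for one site
#'
#' Generates `R` equal-N synthetic control series from the site's weight
#' model and detects clusters and quiet periods in each, using the
#' thresholds determined on the observed record.
#'
#' @param series the observed [onset_series()].
#' @param defs a [site_definition()] (computed from `series` when omitted).
#' @param R number of replicates (100 by default).
#' @param seed RNG seed; replicate seeds are split deterministically.
#' @param model optional pre-fitted [fit_weight_model()].
#' @return A list of class `null_ensemble` with per-replicate cluster and
#'   quiet [kd_episodes()] sets.
#' @export
null_ensemble <- function(series, defs = NULL, R = 100L, seed = NULL,
                          model = NULL) {
  defs <- defs %||% site_definition(series)
  model <- model %||% fit_weight_model(series)
  clusters <- vector("list", R)
  quiet <- vector("list", R)
  for (r in seq_len(R)) {
    rep_seed <- if (is.null(seed)) NULL else child_seed(seed, r)
    s <- draw_null_series(model, model$n, seed = rep_seed)
    cnt <- daily_counts(s)
    clusters[[r]] <- detect_clusters(cnt, defs$cluster_threshold, defs$window)
    quiet[[r]] <- if (!is.na(defs$quiet_threshold))
      detect_quiet(cnt, defs$quiet_threshold)
  }
  structure(list(site_id = series$site_id, R = as.integer(R), n = model$n,
                 model = model, defs = defs, clusters = clusters,
                 quiet = quiet, seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null ensemble for '", x$site_id, "': ", x$R, " equal-N replicates (n = ",
      x$n, ")\n  mean clusters/replicate: ",
      format(mean(vapply(x$clusters, nrow, integer(1))), digits = 3), "\n",
      sep = "")
  invisible(x)
}

bin_counts <- function(values, lo, hi) {
  # inclusive integer bins [lo_i, hi_i]; hi may be Inf (overflow)
  vapply(seq_along(lo), function(i)
    sum(values >= lo[i] & values <= hi[i]), numeric(1))
}

#' Compare observed episode distributions to the null ensemble
#'
#' For clusters the comparison is over per-cluster case counts; for quiet
#' periods over episode lengths in days (unit bins up to the 99th
#' percentile of the null lengths, then one overflow bin). For each bin the
#' null mean and spread across replicates are reported, and bins where the
#' observed count falls outside mean +/- 2 * spread are flagged. The band
#' half-width is two standard deviations of the replicate counts — the
#' spread of the null distribution itself, so a series actually drawn from
#' the null is flagged rarely.
#'
#' @param observed a [kd_episodes()] set from the observed record.
#' @param ensemble a [null_ensemble()] built with the same thresholds.
#' @param kind `"cluster"` or `"quiet"`; must match `observed`'s kind.
#' @return A data frame of class `kd_comparison` with columns `bin`,
#'   `bin_lo`, `bin_hi`, `observed`, `null_mean`, `null_se`, `flagged`.
#' @export
compare_distributions <- function(observed, ensemble,
                                  kind = c("cluster", "quiet")) {
  kind <- match.arg(kind)
  if (!identical(episode_kind(observed), kind))
    stop("kind mismatch: observed episodes are of kind '",
         episode_kind(observed), "'", call. = FALSE)
  rep_sets <- if (kind == "cluster") ensemble$clusters else ensemble$quiet
  if (kind == "quiet" && any(vapply(rep_sets, is.null, logical(1))))
    stop("ensemble has no quiet-period detections", call. = FALSE)
  value_of <- function(e) if (kind == "cluster") e$n_cases else e$length
  obs_v <- value_of(observed)
  null_v <- lapply(rep_sets, value_of)
  all_v <- c(obs_v, unlist(null_v))
  if (length(all_v) == 0) {
    out <- data.frame(bin = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), observed = numeric(0),
                      null_mean = numeric(0), null_se = numeric(0),
                      flagged = logical(0))
    return(structure(out, kind = kind, R = ensemble$R,
                     class = c("kd_comparison", "data.frame")))
  }
  if (kind == "cluster") {
    lo <- seq(min(all_v), max(all_v))
    hi <- lo
  } else {
    pooled <- unlist(null_v)
    cap <- if (length(pooled))
      as.integer(ceiling(stats::quantile(pooled, 0.99, names = FALSE)))
    else max(all_v)
    lo <- seq(min(all_v), cap)
    hi <- lo
    if (max(all_v) > cap) { lo <- c(lo, cap + 1); hi <- c(hi, Inf) }
  }
  obs_cnt <- bin_counts(obs_v, lo, hi)
  null_mat <- vapply(null_v, bin_counts, numeric(length(lo)), lo = lo, hi = hi)
  null_mat <- matrix(null_mat, nrow = length(lo)) # guard 1-bin drop
  mu <- rowMeans(null_mat)
  se <- apply(null_mat, 1, stats::sd)
  flagged <- obs_cnt > mu + 2 * se | obs_cnt < mu - 2 * se
  out <- data.frame(
    bin = ifelse(is.finite(hi), as.character(lo), paste0(lo, "+")),
    bin_lo = lo, bin_hi = hi, observed = obs_cnt,
    null_mean = mu, null_se = se, flagged = flagged,
    stringsAsFactors = FALSE)
  structure(out, kind = kind, R = ensemble$R,
            class = c("kd_comparison", "data.frame"))
}
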