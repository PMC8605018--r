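#' Default winter-peaked monthly seasonality weights
#'
#' Relative per-day incidence by calendar month (Jan..Dec), shaped like the
#' northern-hemisphere Kawasaki disease profile: a winter/spring peak and a
#' lesser mid-summer bump. Used as the generator default.
#'
#' @return Numeric vector of 12 non-negative weights.
#' @export
winter_monthly_weights <- function() {
  c(Jan = 1.6, Feb = 1.5, Mar = 1.3, Apr = 1.0, May = 0.8, Jun = 0.7,
    Jul = 0.9, Aug = 0.7, Sep = 0.6, Oct = 0.8, Nov = 1.1, Dec = 1.4)
}

#' Specification for one simulated site
#'
#' Describes a synthetic onset series: total baseline cases, observation
#' window, monthly seasonality, a linear long-term trend, plus optional
#' injected bursts (local case excesses) and forced gaps (zero-case
#' intervals). Scales default to a mid-range surveillance site: about a
#' thousand cases over fifteen years.
#'
#' @param site_id site label.
#' @param n_cases baseline number of cases (bursts add on top).
#' @param start_date,end_date observation window (inclusive).
#' @param monthly_weights 12 non-negative per-day weights, Jan..Dec.
#' @param trend_slope relative change in the annual rate per year; 0 is
#'   flat, e.g. `1/15` doubles the rate across a 15-year window.
#' @param bursts data frame with columns `center` (date), `duration` (days)
#'   and `n_extra` (cases added uniformly inside the burst span), or `NULL`.
#' @param gaps data frame with columns `start` (date) and `length` (days):
#'   intervals forced to zero baseline cases, or `NULL`.
#' @param seed default RNG seed for [simulate_site()].
#' @return A list of class `site_sim_spec`.
#' @export
site_sim_spec <- function(site_id, n_cases = 1000L,
                          start_date = "2000-01-01", end_date = "2014-12-31",
                          monthly_weights = winter_monthly_weights(),
                          trend_slope = 0, bursts = NULL, gaps = NULL,
                          seed = NULL) {
  start_date <- as_iso_date(start_date, "start_date")
  end_date <- as_iso_date(end_date, "end_date")
  if (end_date < start_date) stop("end_date before start_date", call. = FALSE)
  if (length(monthly_weights) != 12 || any(monthly_weights < 0) ||
      all(monthly_weights == 0))
    stop("monthly_weights must be 12 non-negative values, not all zero",
         call. = FALSE)
  if (n_cases < 0) stop("n_cases must be >= 0", call. = FALSE)
  if (!is.null(bursts)) {
    stopifnot(all(c("center", "duration", "n_extra") %in% names(bursts)))
    bursts$center <- as_iso_date(bursts$center, "burst center")
  }
  if (!is.null(gaps)) {
    stopifnot(all(c("start", "length") %in% names(gaps)))
    gaps$start <- as_iso_date(gaps$start, "gap start")
    if (any(gaps$start < start_date |
            gaps$start + gaps$length - 1 > end_date))
      stop("gap intervals must lie within the observation window",
           call. = FALSE)
  }
  structure(list(site_id = as.character(site_id),
                 n_cases = as.integer(n_cases),
                 start_date = start_date, end_date = end_date,
                 monthly_weights = as.numeric(monthly_weights),
                 trend_slope = trend_slope, bursts = bursts, gaps = gaps,
                 seed = seed),
            class = "site_sim_spec")
}

sim_daily_weights <- function(spec) {
  dates <- seq(spec$start_date, spec$end_date, by = "day")
  yrs <- as.numeric(dates - spec$start_date) / 365.25
  mon <- as.POSIXlt(dates)$mon + 1L
  w <- pmax(1e-6, 1 + spec$trend_slope * yrs) * spec$monthly_weights[mon]
  if (!is.null(spec$gaps)) {
    for (g in seq_len(nrow(spec$gaps))) {
      a <- as.integer(spec$gaps$start[g] - spec$start_date) + 1L
      b <- a + as.integer(spec$gaps$length[g]) - 1L
      w[a:b] <- 0
    }
  }
  if (all(w == 0))
    stop("all-zero daily weights after gap masking", call. = FALSE)
  w / sum(w)
}

burst_span <- function(center, duration, start_date, end_date) {
  first <- center - (as.integer(duration) - 1L) %/% 2L
  last <- first + as.integer(duration) - 1L
  c(max(first, start_date), min(last, end_date))
}

#' Simulate one site's onset series
#'
#' Baseline onsets are drawn i.i.d. (with replacement, the same mechanism
#' the Monte Carlo null uses) from normalized daily weights
#' `w[d] proportional to max(1e-6, 1 + trend_slope * years(d)) *
#' monthly_weights[month(d)]`; forced gaps carry zero weight. Burst cases
#' are then added uniformly inside each burst span. The total case count is
#' `n_cases` plus the burst extras, and the result is deterministic given
#' the seed.
#'
#' @param spec a [site_sim_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return An [onset_series()].
#' @examples
#' s <- simulate_site(site_sim_spec("demo", n_cases = 200, seed = 1))
#' length(s$onsets)
#' @export
simulate_site <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "site_sim_spec"))
  seed <- seed %||% spec$seed
  w <- sim_daily_weights(spec)
  dates <- seq(spec$start_date, spec$end_date, by = "day")
  with_seed(seed, {
    idx <- if (spec$n_cases > 0)
      sample.int(length(w), spec$n_cases, replace = TRUE, prob = w)
    else integer(0)
    onsets <- dates[idx]
    if (!is.null(spec$bursts)) {
      for (b in seq_len(nrow(spec$bursts))) {
        span <- burst_span(spec$bursts$center[b], spec$bursts$duration[b],
                           spec$start_date, spec$end_date)
        days <- seq(span[1], span[2], by = "day")
        extra <- days[sample.int(length(days), spec$bursts$n_extra[b],
                                 replace = TRUE)]
        onsets <- c(onsets, extra)
      }
    }
    onset_series(onsets, spec$site_id, spec$start_date, spec$end_date)
  })
}

#' Cross-site burst synchrony specification
#'
#' Shared bursts injected into several sites at (nearly) the same calendar
#' time, emulating a common environmental exposure. Each listed site
#' receives `inflation` extra cases per burst, placed uniformly in a
#' `duration`-day span starting at the shared date plus that site's lag.
#'
#' @param sites character vector of synchronized site ids.
#' @param burst_dates shared burst start dates.
#' @param inflation extra cases per burst per site.
#' @param duration burst span in days.
#' @param lags named integer vector of per-site lags in days (0..6 typical);
#'   missing sites get 0.
#' @return A list of class `synchrony_spec`.
#' @export
synchrony_spec <- function(sites, burst_dates, inflation = 15L,
                           duration = 7L, lags = NULL) {
  burst_dates <- as_iso_date(burst_dates, "burst date")
  lags <- lags %||% stats::setNames(integer(length(sites)), sites)
  if (any(lags < 0)) stop("lags must be >= 0", call. = FALSE)
  structure(list(sites = as.character(sites), burst_dates = burst_dates,
                 inflation = as.integer(inflation),
                 duration = as.integer(duration), lags = lags),
            class = "synchrony_spec")
}

#' Simulate a multi-site ensemble with optional synchrony
#'
#' Each site is simulated independently (seeds split deterministically from
#' the master seed), then shared bursts from `sync` are injected. With
#' `sync = NULL` the result is seed-for-seed identical to independent
#' [simulate_site()] calls.
#'
#' @param specs list of [site_sim_spec()] with unique `site_id`s.
#' @param sync a [synchrony_spec()], a list of them (several independent
#'   synchronized groups), or `NULL`.
#' @param seed master RNG seed (required when `sync` is given; otherwise
#'   falls back to the per-spec seeds).
#' @return Named list of [onset_series()].
#' @export
simulate_ensemble <- function(specs, sync = NULL, seed = NULL) {
  ids <- vapply(specs, function(s) s$site_id, character(1))
  if (anyDuplicated(ids)) stop("site_ids must be unique", call. = FALSE)
  if (inherits(sync, "synchrony_spec")) sync <- list(sync)
  sync <- Filter(function(s) length(s$sites) > 0, sync)
  if (length(sync)) {
    if (is.null(seed))
      stop("a master seed is required when sync is given", call. = FALSE)
    unknown <- setdiff(unlist(lapply(sync, `[[`, "sites")), ids)
    if (length(unknown))
      stop("sync references unknown site_id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", length(specs))
  names(out) <- ids
  for (i in seq_along(specs)) {
    s_seed <- if (is.null(seed)) specs[[i]]$seed else child_seed(seed, i)
    out[[i]] <- simulate_site(specs[[i]], seed = s_seed)
  }
  for (g in seq_along(sync)) {
    sy <- sync[[g]]
    for (i in seq_along(sy$sites)) {
      id <- sy$sites[i]
      spec <- specs[[match(id, ids)]]
      lag <- if (id %in% names(sy$lags)) sy$lags[[id]] else 0L
      extra <- with_seed(child_seed(seed, 100000 * g + i), {
        unlist(lapply(seq_along(sy$burst_dates), function(b) {
          first <- max(sy$burst_dates[b] + lag, spec$start_date)
          last <- min(first + sy$duration - 1L, spec$end_date)
          days <- seq(first, last, by = "day")
          as.integer(days[sample.int(length(days), sy$inflation,
                                     replace = TRUE)])
        }))
      })
      ser <- out[[id]]
      out[[id]] <- onset_series(
        c(ser$onsets, as.Date(extra, origin = "1970-01-01")),
        id, ser$start_date, ser$end_date)
    }
  }
  out
}
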