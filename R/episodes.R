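#' Construct an episode set
#'
#' An episode set holds detected clusters (high case-density intervals) or
#' quiet periods (long zero-case intervals) for one site, as inclusive
#' calendar day-intervals. Episodes are sorted, non-overlapping, and
#' separated by at least one day; quiet episodes contain no cases.
#'
#' @param first_date,last_date inclusive episode bounds (`Date` or ISO
#'   strings), one entry per episode.
#' @param n_cases cases with onset inside each episode (0 for quiet).
#' @param kind `"cluster"` or `"quiet"`.
#' @param site_id site label.
#' @param threshold,window the local definition that produced the episodes
#'   (stored as attributes; optional).
#' @return A data frame of class `kd_episodes` with columns `first_date`,
#'   `last_date`, `n_cases` and `length` (days).
#' @export
kd_episodes <- function(first_date, last_date, n_cases = NULL,
                        kind = c("cluster", "quiet"), site_id = "site",
                        threshold = NA_integer_, window = NA_integer_) {
  kind <- match.arg(kind)
  first_date <- as_iso_date(first_date, "first_date")
  last_date <- as_iso_date(last_date, "last_date")
  if (length(first_date) != length(last_date))
    stop("first_date and last_date lengths differ", call. = FALSE)
  if (any(last_date < first_date))
    stop("episode with last_date before first_date", call. = FALSE)
  n_cases <- as.integer(n_cases %||% rep(0L, length(first_date)))
  if (kind == "quiet" && any(n_cases != 0))
    stop("quiet episodes must have zero cases", call. = FALSE)
  o <- order(first_date)
  df <- data.frame(first_date = first_date[o], last_date = last_date[o],
                   n_cases = n_cases[o])
  df$length <- as.integer(df$last_date - df$first_date) + 1L
  if (nrow(df) > 1 &&
      any(df$first_date[-1] <= df$last_date[-nrow(df)] + 1L))
    stop("episodes overlap or touch; adjacent days must have been merged",
         call. = FALSE)
  structure(df, kind = kind, site_id = site_id,
            threshold = threshold, window = window,
            class = c("kd_episodes", "data.frame"))
}

#' @export
print.kd_episodes <- function(x, ...) {
  cat(attr(x, "kind"), " episodes for '", attr(x, "site_id"), "': ",
      nrow(x), " episode(s)", sep = "")
  thr <- attr(x, "threshold")
  if (!is.na(thr)) cat(", threshold ", thr, sep = "")
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

episode_kind <- function(x) attr(x, "kind")

counts_vector <- function(counts) {
  x <- as.integer(unclass(counts))
  if (any(is.na(x)) || any(x < 0)) stop("counts must be non-negative integers")
  x
}

counts_start_date <- function(counts) {
  attr(counts, "start_date") %||% as.Date("2000-01-01")
}

#' Maximum 7-day case density containing each day
#'
#' For every day `d` of the record, the profile value is the largest number
#' of cases found in any `window`-day span that contains `d`. Spans are
#' clipped at the record edges — days outside the observation window do not
#' exist and contribute nothing.
#'
#' @param counts per-day case counts ([daily_counts()] or a plain
#'   non-negative integer vector).
#' @param window span length in days (default 7).
#' @return Integer vector, same length as `counts`.
#' @export
density_profile <- function(counts, window = 7L) {
  x <- counts_vector(counts)
  w <- as.integer(window)
  if (w < 1) stop("window must be >= 1", call. = FALSE)
  D <- length(x)
  if (D == 0) return(integer(0))
  if (D <= w) return(rep(sum(x), D))
  cs <- cumsum(c(0L, x))
  ws <- cs[(w + 1):(D + 1)] - cs[1:(D - w + 1)] # full-window sums, start s
  m <- rep(-1L, D)
  for (j in 0:(w - 1)) { # a window starting at s covers days s..s+w-1
    idx <- (j + 1):(D - w + 1 + j)
    m[idx] <- pmax(m[idx], ws)
  }
  m
}

#' Zero-run length containing each zero-case day
#'
#' For days with no cases, the length of the maximal run of consecutive
#' zero-count days containing that day; `NA` on days with cases. The value
#' is constant across each run.
#'
#' @inheritParams density_profile
#' @return Integer vector with `NA` on non-zero days.
#' @export
quiet_profile <- function(counts) {
  x <- counts_vector(counts)
  if (length(x) == 0) return(integer(0))
  r <- rle(x == 0L)
  vals <- ifelse(r$values, r$lengths, NA_integer_)
  inverse.rle(list(lengths = r$lengths, values = as.integer(vals)))
}

#' Percentile-derived local threshold
#'
#' The site-local integer threshold is the empirical percentile (linear
#' interpolation between order statistics) of a per-day profile, rounded up
#' to the next integer and floored at 1; it is subsequently used with a
#' `>=` comparison. Ceiling guarantees the threshold describes attainable
#' tail behaviour on integer-valued data.
#'
#' @param profile per-day values ([density_profile()] or [quiet_profile()];
#'   `NA`s — non-zero days in a quiet profile — are dropped).
#' @param percentile 97.5 or 99.5.
#' @return Integer threshold.
#' @export
local_threshold <- function(profile, percentile = 97.5) {
  if (!percentile %in% c(97.5, 99.5))
    stop("percentile must be 97.5 or 99.5", call. = FALSE)
  v <- profile[!is.na(profile)]
  if (length(v) == 0)
    stop("no days available to compute a threshold; ",
         "no quiet periods definable", call. = FALSE)
  q <- stats::quantile(v, percentile / 100, type = 7, names = FALSE)
  max(1L, as.integer(ceiling(q - 1e-9)))
}

runs_at_or_above <- function(flag) {
  # maximal runs of TRUE; returns matrix cols first,last (1-based)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(first = starts[keep], last = ends[keep])
}

#' Detect temporal clusters
#'
#' Days whose maximum 7-day density meets the local threshold are grouped
#' into maximal consecutive runs; each run is one cluster spanning the full
#' window of qualifying days (a cluster seeded by a 7-day definition can
#' extend to any number of days). `n_cases` counts onsets inside the span.
#'
#' @inheritParams density_profile
#' @param threshold integer cases-in-`window`-days threshold (`>=`).
#' @return A [kd_episodes()] set of kind `"cluster"` (possibly empty).
#' @export
detect_clusters <- function(counts, threshold, window = 7L) {
  x <- counts_vector(counts)
  if (is.na(threshold) || threshold < 1)
    stop("threshold must be a positive integer", call. = FALSE)
  start <- counts_start_date(counts)
  m <- density_profile(x, window)
  runs <- runs_at_or_above(m >= threshold)
  cs <- cumsum(c(0L, x))
  n_in <- cs[runs[, "last"] + 1L] - cs[runs[, "first"]]
  kd_episodes(start + runs[, "first"] - 1L, start + runs[, "last"] - 1L,
              n_in, kind = "cluster",
              site_id = attr(counts, "site_id") %||% "site",
              threshold = as.integer(threshold), window = as.integer(window))
}

#' Detect quiet periods
#'
#' Every maximal run of consecutive zero-case days whose length meets the
#' local gap threshold becomes one quiet episode.
#'
#' @inheritParams density_profile
#' @param threshold minimum gap length in days (`>=`).
#' @return A [kd_episodes()] set of kind `"quiet"` (possibly empty).
#' @export
detect_quiet <- function(counts, threshold) {
  x <- counts_vector(counts)
  if (is.na(threshold) || threshold < 1)
    stop("threshold must be a positive integer", call. = FALSE)
  start <- counts_start_date(counts)
  runs <- runs_at_or_above(x == 0L)
  len <- runs[, "last"] - runs[, "first"] + 1L
  runs <- runs[len >= threshold, , drop = FALSE]
  kd_episodes(start + runs[, "first"] - 1L, start + runs[, "last"] - 1L,
              rep(0L, nrow(runs)), kind = "quiet",
              site_id = attr(counts, "site_id") %||% "site",
              threshold = as.integer(threshold))
}

#' Site-local cluster and quiet-period definitions
#'
#' Computes the per-site integer thresholds from the 97.5th or 99.5th
#' percentile of the density and zero-run profiles. When a percentile is not
#' supplied, the choice follows incidence: low-incidence sites (mean under
#' 60 cases/year) take the more conservative 99.5th percentile for clusters,
#' because an integer density value can span a wide percentile range there;
#' high-incidence sites take 99.5 for quiet periods by the symmetric logic.
#'
#' @param series an [onset_series()].
#' @param cluster_percentile,quiet_percentile 97.5, 99.5, or `NULL` for the
#'   incidence-based default.
#' @param window cluster density span in days.
#' @return A list of class `site_definition` with the thresholds and the
#'   percentiles used. `quiet_threshold` is `NA` when the record has no
#'   zero-case days.
#' @export
site_definition <- function(series, cluster_percentile = NULL,
                            quiet_percentile = NULL, window = 7L) {
  counts <- daily_counts(series)
  mean_annual <- length(series$onsets) / (n_days(series) / 365.25)
  cluster_percentile <- cluster_percentile %||%
    (if (mean_annual < 60) 99.5 else 97.5)
  quiet_percentile <- quiet_percentile %||%
    (if (mean_annual >= 60) 99.5 else 97.5)
  cluster_threshold <- local_threshold(density_profile(counts, window),
                                       cluster_percentile)
  quiet_threshold <- tryCatch(
    local_threshold(quiet_profile(counts), quiet_percentile),
    error = function(e) {
      warning("site '", series$site_id, "': ", conditionMessage(e),
              call. = FALSE)
      NA_integer_
    })
  structure(
    list(site_id = series$site_id,
         cluster_threshold = cluster_threshold,
         cluster_percentile = cluster_percentile,
         quiet_threshold = quiet_threshold,
         quiet_percentile = quiet_percentile,
         window = as.integer(window), mean_annual = mean_annual),
    class = "site_definition")
}

#' @export
print.site_definition <- function(x, ...) {
  cat("Local definitions for '", x$site_id, "' (",
      format(x$mean_annual, digits = 3), " cases/yr):\n",
      "  cluster: >= ", x$cluster_threshold, " cases in ", x$window,
      " days (p", x$cluster_percentile, ")\n",
      "  quiet:   >= ", x$quiet_threshold, " zero-case days (p",
      x$quiet_percentile, ")\n", sep = "")
  invisible(x)
}

#' Per-site summary of patients, clusters and quiet periods
#'
#' One row in the standard site-summary schema: patients, number of
#' clusters, patients falling inside clusters, the fraction they represent,
#' and the number of quiet periods, alongside the local definitions used.
#'
#' @param series an [onset_series()].
#' @param defs a [site_definition()]; computed from `series` when omitted.
#' @return A one-row data frame.
#' @export
site_summary <- function(series, defs = NULL) {
  defs <- defs %||% site_definition(series)
  counts <- daily_counts(series)
  clusters <- detect_clusters(counts, defs$cluster_threshold, defs$window)
  n_quiet <- if (is.na(defs$quiet_threshold)) 0L
             else nrow(detect_quiet(counts, defs$quiet_threshold))
  n <- length(series$onsets)
  in_clusters <- sum(clusters$n_cases)
  data.frame(
    site_id = series$site_id,
    n_patients = n,
    n_clusters = nrow(clusters),
    n_patients_in_clusters = in_clusters,
    fraction_in_clusters = if (n > 0) in_clusters / n else 0,
    n_quiet_periods = n_quiet,
    cluster_threshold = defs$cluster_threshold,
    cluster_percentile = defs$cluster_percentile,
    quiet_threshold = defs$quiet_threshold,
    quiet_percentile = defs$quiet_percentile,
    stringsAsFactors = FALSE)
}

#' Write episode sets to CSV
#'
#' Output columns: `site_id,kind,first_date,last_date,n_cases`.
#'
#' @param x a [kd_episodes()] set or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(x, path) {
  if (inherits(x, "kd_episodes")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(e)
    data.frame(site_id = rep(attr(e, "site_id"), nrow(e)),
               kind = rep(attr(e, "kind"), nrow(e)),
               first_date = format(e$first_date, "%Y-%m-%d"),
               last_date = format(e$last_date, "%Y-%m-%d"),
               n_cases = e$n_cases)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
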