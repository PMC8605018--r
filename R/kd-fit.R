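#' Fit the temporal-clustering model to one site
#'
#' The one-stop per-site analysis: derives the local percentile
#' definitions, detects clusters and quiet periods, fits the
#' trend-and-seasonality weight model, builds the equal-N Monte Carlo null
#' ensemble, and compares the observed episode distributions to it. The
#' returned object supports `print`, `summary`, `coef`, `predict`, `plot`,
#' `simulate` and `residuals`.
#'
#' @param series an [onset_series()].
#' @param cluster_percentile,quiet_percentile see [site_definition()].
#' @param window cluster density span in days (default 7).
#' @param replicates null replicates (default 100); 0 skips the null
#'   ensemble and distribution comparisons (useful when only episodes and
#'   the weight model are needed, e.g. for cross-site overlap work).
#' @param seed RNG seed for the null ensemble.
#' @return An object of class `kd_fit`.
#' @examples
#' s <- simulate_site(site_sim_spec("demo", n_cases = 600,
#'                                  end_date = "2009-12-31", seed = 3))
#' fit <- kd_fit(s, replicates = 20, seed = 1)
#' fit
#' coef(fit)[1:2]
#' @export
kd_fit <- function(series, cluster_percentile = NULL,
                   quiet_percentile = NULL, window = 7L,
                   replicates = 100L, seed = NULL) {
  stopifnot(inherits(series, "onset_series"))
  defs <- site_definition(series, cluster_percentile, quiet_percentile,
                          window)
  counts <- daily_counts(series)
  clusters <- detect_clusters(counts, defs$cluster_threshold, window)
  quiet <- if (!is.na(defs$quiet_threshold))
    detect_quiet(counts, defs$quiet_threshold)
  else kd_episodes(as.Date(character(0)), as.Date(character(0)),
                   kind = "quiet", site_id = series$site_id)
  model <- fit_weight_model(series)
  ensemble <- NULL
  comparison <- list(cluster = NULL, quiet = NULL)
  if (replicates > 0) {
    ensemble <- null_ensemble(series, defs, R = replicates, seed = seed,
                              model = model)
    comparison$cluster <- compare_distributions(clusters, ensemble,
                                                "cluster")
    if (!is.na(defs$quiet_threshold))
      comparison$quiet <- compare_distributions(quiet, ensemble, "quiet")
  }
  structure(list(series = series, counts = counts, definition = defs,
                 clusters = clusters, quiet = quiet, model = model,
                 ensemble = ensemble, comparison = comparison,
                 window = as.integer(window), seed = seed,
                 call = match.call()),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  s <- x$series
  cat("Temporal clustering fit for '", s$site_id, "'\n", sep = "")
  cat("  ", length(s$onsets), " cases, ", format(s$start_date), " .. ",
      format(s$end_date), "\n", sep = "")
  cat("  cluster definition: >= ", x$definition$cluster_threshold,
      " cases in ", x$window, " days (p", x$definition$cluster_percentile,
      ") -> ", nrow(x$clusters), " clusters, ",
      round(100 * sum(x$clusters$n_cases) / max(1, length(s$onsets))),
      "% of patients\n", sep = "")
  cat("  quiet definition:   >= ", x$definition$quiet_threshold,
      " zero-case days (p", x$definition$quiet_percentile, ") -> ",
      nrow(x$quiet), " quiet periods\n", sep = "")
  if (!is.null(x$ensemble))
    cat("  null ensemble: ", x$ensemble$R, " equal-N replicates\n", sep = "")
  invisible(x)
}

#' @export
summary.kd_fit <- function(object, ...) {
  tab <- site_summary(object$series, object$definition)
  flg <- lapply(object$comparison, function(cmp)
    if (!is.null(cmp)) cmp[cmp$flagged, , drop = FALSE])
  structure(list(table = tab, flagged = flg,
                 trend_slope = object$model$trend[["slope"]]),
            class = "summary.kd_fit")
}

#' @export
print.summary.kd_fit <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("trend slope:", format(x$trend_slope, digits = 3),
      "cases/day per year\n")
  for (kind in names(x$flagged)) {
    f <- x$flagged[[kind]]
    if (is.null(f)) next
    cat(kind, "bins outside the null mean +/- 2 SD band:",
        if (nrow(f)) paste(f$bin, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) coef(object$model)

#' @rdname kd_fit
#' @param object,x a `kd_fit` object.
#' @param type `"weight"` for the normalized daily resampling weight,
#'   `"expected"` for the implied expected daily case count.
#' @param ... unused.
#' @export
predict.kd_fit <- function(object, type = c("weight", "expected"), ...) {
  type <- match.arg(type)
  m <- object$model
  data.frame(date = seq(m$start_date, m$end_date, by = "day"),
             value = if (type == "weight") m$w else m$n * m$w)
}

#' @rdname kd_fit
#' @param nsim number of synthetic control series.
#' @param seed RNG seed.
#' @export
simulate.kd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  lapply(seq_len(nsim), function(r)
    draw_null_series(object$model, object$model$n,
                     seed = if (is.null(seed)) NULL else child_seed(seed, r)))
}

#' @rdname kd_fit
#' @param kind `"cluster"` or `"quiet"`: which distribution comparison to
#'   use.
#' @export
residuals.kd_fit <- function(object, kind = c("cluster", "quiet"), ...) {
  kind <- match.arg(kind)
  cmp <- object$comparison[[kind]]
  if (is.null(cmp))
    stop("fit was built without a null ensemble (replicates = 0) or has ",
         "no ", kind, " comparison", call. = FALSE)
  stats::setNames(cmp$observed - cmp$null_mean, cmp$bin)
}

#' @rdname kd_fit
#' @param log_y plot counts on a log axis (zeroes shown at the axis floor).
#' @export
plot.kd_fit <- function(x, kind = c("cluster", "quiet"), log_y = FALSE,
                        ...) {
  kind <- match.arg(kind)
  cmp <- x$comparison[[kind]]
  if (is.null(cmp) || nrow(cmp) == 0)
    stop("no ", kind, " comparison available to plot", call. = FALSE)
  ylab <- "episodes"
  xlab <- if (kind == "cluster") "cases per cluster"
          else "quiet period length (days)"
  xs <- cmp$bin_lo
  obs <- cmp$observed
  mu <- cmp$null_mean
  lo <- pmax(0, mu - 2 * cmp$null_se)
  hi <- mu + 2 * cmp$null_se
  if (log_y) {
    floor_v <- 0.05
    obs <- pmax(obs, floor_v); mu <- pmax(mu, floor_v)
    lo <- pmax(lo, floor_v); hi <- pmax(hi, floor_v)
  }
  plot(xs, obs, pch = 16, col = "black", xlab = xlab, ylab = ylab,
       ylim = range(c(obs, lo, hi)), log = if (log_y) "y" else "",
       main = paste0(x$series$site_id, ": observed vs ",
                     if (!is.null(x$ensemble)) x$ensemble$R else "?",
                     " null replicates"), ...)
  segments(xs, lo, xs, hi, col = "steelblue")
  points(xs, mu, pch = 15, col = "steelblue")
  legend("topright", c("observed", "null mean +/- 2 SD"),
         pch = c(16, 15), col = c("black", "steelblue"), bty = "n")
  invisible(x)
}
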