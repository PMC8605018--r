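## Cross-site overlap statistics.
## Episodes are handled internally as two-column integer matrices of
## absolute day numbers (days since 1970-01-01), so sites with different
## observation windows are compared on a common calendar.

ep_intervals <- function(e) {
  if (is.null(e) || nrow(e) == 0)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("first", "last"))))
  cbind(first = as.integer(e$first_date), last = as.integer(e$last_date))
}

overlap_frac <- function(ri, oi, kind, pad = 6L,
                         quiet_method = "mean_fraction") {
  if (is.null(ri) || nrow(ri) == 0) return(NA_real_)
  if (is.null(oi) || nrow(oi) == 0) return(0)
  if (kind == "cluster") {
    hits <- vapply(seq_len(nrow(ri)), function(k)
      any(oi[, 1] <= ri[k, 2] + pad & oi[, 2] >= ri[k, 1] - pad), logical(1))
    mean(hits)
  } else {
    len <- ri[, 2] - ri[, 1] + 1
    cov <- vapply(seq_len(nrow(ri)), function(k)
      sum(pmax(0, pmin(ri[k, 2], oi[, 2]) - pmax(ri[k, 1], oi[, 1]) + 1)),
      numeric(1))
    if (quiet_method == "pooled_days") sum(cov) / sum(len)
    else mean(cov / len)
  }
}

#' Directional cluster overlap between two sites
#'
#' The fraction of reference-site clusters that occur within `pad` days of
#' any cluster at the other site: a reference cluster `[a, b]` counts as
#' overlapped when `[a - pad, b + pad]` intersects an other-site cluster
#' interval on the calendar. The 6-day pad absorbs onset-date uncertainty
#' and allows for lagged common exposure, so the measure is directional —
#' its value depends on which site is the reference.
#'
#' @param ref,other cluster [kd_episodes()] sets (calendar-dated).
#' @param pad tolerance in days on each side (default 6).
#' @return Fraction in `[0, 1]`, or `NA` when `ref` has no clusters.
#' @export
cluster_overlap <- function(ref, other, pad = 6L) {
  if (!identical(episode_kind(ref), "cluster") ||
      !identical(episode_kind(other), "cluster"))
    stop("cluster_overlap requires two cluster episode sets", call. = FALSE)
  overlap_frac(ep_intervals(ref), ep_intervals(other), "cluster", pad)
}

#' Directional quiet-period overlap between two sites
#'
#' Quiet-period overlap requires at least one shared day (no pad — quiet
#' endpoints are sharply defined by the occurrence of any case) and is
#' weighted by the shared length: for each reference quiet period, the
#' fraction of its days lying inside any other-site quiet period. The
#' default aggregates these per-episode fractions by unweighted mean;
#' `"pooled_days"` instead returns total shared days over total quiet days.
#'
#' @param ref,other quiet [kd_episodes()] sets.
#' @param method `"mean_fraction"` (default) or `"pooled_days"`.
#' @return Fraction in `[0, 1]`, or `NA` when `ref` has no quiet periods.
#' @export
quiet_overlap <- function(ref, other,
                          method = c("mean_fraction", "pooled_days")) {
  method <- match.arg(method)
  if (!identical(episode_kind(ref), "quiet") ||
      !identical(episode_kind(other), "quiet"))
    stop("quiet_overlap requires two quiet episode sets", call. = FALSE)
  overlap_frac(ep_intervals(ref), ep_intervals(other), "quiet",
               quiet_method = method)
}

site_parts <- function(x, kind) {
  if (inherits(x, "kd_fit"))
    return(list(episodes = if (kind == "cluster") x$clusters else x$quiet,
                model = x$model))
  if (is.list(x) && !is.null(x$episodes))
    return(list(episodes = x$episodes, model = x$model))
  stop("expected a kd_fit object or list(episodes=, model=)", call. = FALSE)
}

# Start-day redraw machinery for the episode-shuffling null. Cluster starts
# are drawn in proportion to the daily weight (clusters live where cases
# are likely); quiet starts in proportion to the null probability that the
# whole span stays empty, exp(-N * sum of w over the span).
make_shuffler <- function(episodes, model, kind, max_try = 500L) {
  iv <- ep_intervals(episodes)
  k <- nrow(iv)
  D <- model$D
  start_abs <- as.integer(model$start_date)
  if (k == 0) {
    empty <- iv
    return(function() empty)
  }
  dur <- sort(iv[, 2] - iv[, 1] + 1L, decreasing = TRUE)
  W <- c(0, cumsum(model$w))
  cdf_for <- function(L) {
    ns <- D - L + 1L
    wts <- if (kind == "cluster") model$w[seq_len(ns)]
           else exp(-model$n * (W[seq_len(ns) + L] - W[seq_len(ns)]))
    cumsum(wts)
  }
  cdfs <- lapply(stats::setNames(unique(dur), unique(dur)), cdf_for)
  function() {
    occupied <- logical(D)
    out <- matrix(0L, nrow = k, ncol = 2,
                  dimnames = list(NULL, c("first", "last")))
    for (e in seq_len(k)) {
      L <- dur[e]
      cw <- cdfs[[as.character(L)]]
      placed <- FALSE
      for (try in seq_len(max_try)) {
        s <- min(findInterval(stats::runif(1) * cw[length(cw)], cw) + 1L,
                 length(cw))
        if (!any(occupied[s:(s + L - 1L)])) {
          occupied[s:(s + L - 1L)] <- TRUE
          out[e, ] <- c(start_abs + s - 1L, start_abs + s + L - 2L)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("episode set too dense to shuffle without overlap; ",
             "consider mode = 'resample_series'", call. = FALSE)
    }
    out
  }
}

make_resampler <- function(model, n, threshold, window, kind) {
  # fast path: equal-N redraw + re-detection without Date bookkeeping
  start_abs <- as.integer(model$start_date)
  D <- model$D
  w <- model$w
  function() {
    x <- tabulate(sample.int(D, n, replace = TRUE, prob = w), nbins = D)
    if (kind == "cluster") {
      runs <- runs_at_or_above(density_profile(x, window) >= threshold)
    } else {
      runs <- runs_at_or_above(x == 0L)
      runs <- runs[runs[, 2] - runs[, 1] + 1L >= threshold, , drop = FALSE]
    }
    cbind(first = start_abs + runs[, 1] - 1L,
          last = start_abs + runs[, 2] - 1L)
  }
}

null_generator <- function(fit, kind, mode) {
  p <- site_parts(fit, kind)
  if (mode == "shuffle_episodes")
    make_shuffler(p$episodes, p$model, kind)
  else {
    defs <- fit$definition
    thr <- if (kind == "cluster") defs$cluster_threshold
           else defs$quiet_threshold
    make_resampler(p$model, p$model$n, thr, defs$window, kind)
  }
}

#' Null distribution of pairwise overlap for one site pair
#'
#' Computes `R` overlap fractions between synthetic realizations of the two
#' sites. The default `resample_series` mode draws full equal-N null series
#' from each site's weight model and re-detects episodes with the observed
#' thresholds, so synthetic episode dates carry exactly the seasonal
#' concentration that detection induces; under independence the observed
#' overlap is then distributed like the null overlaps. The alternative
#' `shuffle_episodes` mode keeps each observed episode's duration and
#' redraws its start day from the seasonal weights (rejecting placements
#' that land on an already-placed episode); it is retained as a sensitivity
#' switch but is anticonservative, because detected clusters concentrate in
#' the high season more sharply than the daily rate itself.
#'
#' @param site_i,site_j [kd_fit()] objects; `site_i` is the reference.
#' @param kind `"cluster"` or `"quiet"`.
#' @param R number of synthetic pairings (default 500).
#' @param mode `"resample_series"` (default) or `"shuffle_episodes"`.
#' @param pad cluster pad in days.
#' @param seed RNG seed.
#' @param quiet_method see [quiet_overlap()].
#' @return Numeric vector of `R` overlap fractions (`NA` throughout when
#'   the reference site has no episodes).
#' @export
pair_null_overlaps <- function(site_i, site_j, kind = c("cluster", "quiet"),
                               R = 500L,
                               mode = c("resample_series", "shuffle_episodes"),
                               pad = 6L, seed = NULL,
                               quiet_method = "mean_fraction") {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  gen_i <- null_generator(site_i, kind, mode)
  gen_j <- null_generator(site_j, kind, mode)
  vapply(seq_len(R), function(r) {
    with_seed(if (is.null(seed)) NULL else child_seed(seed, r),
              overlap_frac(gen_i(), gen_j(), kind, pad, quiet_method))
  }, numeric(1))
}

#' Observed overlap matrix across sites
#'
#' @param sites named list of [kd_fit()] objects.
#' @param kind `"cluster"` or `"quiet"`.
#' @param pad cluster pad in days.
#' @param quiet_method see [quiet_overlap()].
#' @return Square matrix `O` with `O[i, j]` the overlap of site `i`'s
#'   episodes referenced against site `j`'s; `NA` where the reference site
#'   has no episodes.
#' @export
overlap_matrix <- function(sites, kind = c("cluster", "quiet"), pad = 6L,
                           quiet_method = "mean_fraction") {
  kind <- match.arg(kind)
  ints <- lapply(sites, function(f) ep_intervals(site_parts(f, kind)$episodes))
  n <- length(sites)
  O <- matrix(NA_real_, n, n, dimnames = list(names(sites), names(sites)))
  for (i in seq_len(n)) for (j in seq_len(n))
    O[i, j] <- overlap_frac(ints[[i]], ints[[j]], kind, pad, quiet_method)
  O
}

loo_flags <- function(x) {
  # one-sided high flags of each value against the mean/sd of the others
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA, length(x))
  if (n < 3) return(out)
  S <- sum(x[ok]); Q <- sum(x[ok]^2)
  m <- (S - x[ok]) / (n - 1)
  v <- pmax(0, (Q - x[ok]^2 - (n - 1) * m^2) / (n - 2))
  out[ok] <- x[ok] > m + 2 * sqrt(v)
  out
}

#' Ensemble significance of cross-site overlaps
#'
#' The full Monte Carlo exercise behind the pairwise synchrony test. For
#' each of `R_outer` repetitions a fresh set of `R_inner` synthetic
#' realizations is generated per site; each ordered pair's observed overlap
#' is flagged significant when it exceeds the synthetic mean by more than
#' two standard deviations (one-sided: excess overlap). Reported are
#' `S[i, j]`, the fraction of repetitions in which pair `(i, j)` was
#' flagged; `Tn_observed`, the per-repetition count of flagged ordered
#' pairs; and `Tn_null`, the same count when each synthetic member in turn
#' plays the role of the observed record against the remaining members.
#'
#' @param sites named list of [kd_fit()] objects (at least two after
#'   exclusions); short-record sites can be dropped via `exclude`.
#' @param kind `"cluster"` or `"quiet"`.
#' @param R_inner synthetic realizations per repetition (>= 30; default
#'   500).
#' @param R_outer number of repetitions (default 500).
#' @param pad cluster pad in days.
#' @param mode null mode, see [pair_null_overlaps()].
#' @param seed RNG seed.
#' @param exclude character vector of site ids to drop.
#' @param quiet_method see [quiet_overlap()].
#' @return A list of class `kd_overlap_test` with elements `O`, `S`
#'   (matrices), `Tn_observed` (length `R_outer`), `Tn_null` (length
#'   `R_outer * R_inner`), `pairs` (per-pair data frame with mean null
#'   overlap and flags), and the run settings.
#' @export
ensemble_significance <- function(sites, kind = c("cluster", "quiet"),
                                  R_inner = 500L, R_outer = 500L, pad = 6L,
                                  mode = c("resample_series",
                                           "shuffle_episodes"),
                                  seed = NULL, exclude = NULL,
                                  quiet_method = "mean_fraction") {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (!is.null(exclude)) sites <- sites[setdiff(names(sites), exclude)]
  n <- length(sites)
  if (n < 2) stop("need at least two sites", call. = FALSE)
  if (R_inner < 30)
    stop("R_inner must be >= 30 for a usable SD estimate", call. = FALSE)
  ids <- names(sites) %||% paste0("site", seq_len(n))

  gens <- lapply(sites, null_generator, kind = kind, mode = mode)
  obs_int <- lapply(sites, function(f)
    ep_intervals(site_parts(f, kind)$episodes))
  pairs <- expand.grid(ref = seq_len(n), other = seq_len(n))
  pairs <- pairs[pairs$ref != pairs$other, ]
  P <- nrow(pairs)
  O_obs <- vapply(seq_len(P), function(p)
    overlap_frac(obs_int[[pairs$ref[p]]], obs_int[[pairs$other[p]]],
                 kind, pad, quiet_method), numeric(1))

  flags <- matrix(NA, P, R_outer)
  null_mu <- matrix(NA_real_, P, R_outer)
  null_sd <- matrix(NA_real_, P, R_outer)
  Tn_null <- numeric(0)
  for (t in seq_len(R_outer)) {
    synth <- vector("list", n)
    for (si in seq_len(n)) {
      synth[[si]] <- lapply(seq_len(R_inner), function(r)
        with_seed(if (is.null(seed)) NULL
                  else child_seed(seed, (t - 1) * n * R_inner +
                                        (si - 1) * R_inner + r),
                  gens[[si]]()))
    }
    O_null <- matrix(NA_real_, R_inner, P)
    for (p in seq_len(P)) {
      ri <- pairs$ref[p]; oj <- pairs$other[p]
      O_null[, p] <- vapply(seq_len(R_inner), function(r)
        overlap_frac(synth[[ri]][[r]], synth[[oj]][[r]], kind, pad,
                     quiet_method), numeric(1))
    }
    mu <- colMeans(O_null, na.rm = TRUE)
    sdv <- apply(O_null, 2, stats::sd, na.rm = TRUE)
    null_mu[, t] <- mu
    null_sd[, t] <- sdv
    flags[, t] <- !is.na(O_obs) & !is.na(mu) & !is.na(sdv) &
      O_obs > mu + 2 * sdv
    flags[is.na(O_obs), t] <- NA
    member_flags <- apply(O_null, 2, loo_flags)
    member_flags <- matrix(member_flags, nrow = R_inner)
    Tn_null <- c(Tn_null, rowSums(member_flags, na.rm = TRUE))
  }
  Tn_observed <- colSums(flags, na.rm = TRUE)
  S_vec <- rowMeans(flags, na.rm = TRUE)
  S_vec[is.na(O_obs)] <- NA_real_

  Om <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  Sm <- Om
  for (p in seq_len(P)) {
    Om[pairs$ref[p], pairs$other[p]] <- O_obs[p]
    Sm[pairs$ref[p], pairs$other[p]] <- S_vec[p]
  }
  diag(Om) <- ifelse(vapply(obs_int, nrow, integer(1)) > 0, 1, NA_real_)

  pair_df <- data.frame(
    ref = ids[pairs$ref], other = ids[pairs$other],
    observed = O_obs,
    null_mean = rowMeans(null_mu, na.rm = TRUE),
    null_sd = rowMeans(null_sd, na.rm = TRUE),
    S = S_vec, stringsAsFactors = FALSE)

  structure(list(kind = kind, O = Om, S = Sm, pairs = pair_df,
                 Tn_observed = Tn_observed, Tn_null = Tn_null,
                 R_inner = as.integer(R_inner),
                 R_outer = as.integer(R_outer),
                 pad = as.integer(pad), mode = mode, seed = seed,
                 quiet_method = quiet_method),
            class = "kd_overlap_test")
}

#' @export
print.kd_overlap_test <- function(x, digits = 2, ...) {
  cat("Cross-site ", x$kind, " overlap test (", nrow(x$O), " sites, ",
      x$R_outer, " x ", x$R_inner, " Monte Carlo, mode ", x$mode, ")\n",
      sep = "")
  cat("Observed overlap O[i,j] (rows = reference site):\n")
  print(round(x$O, digits))
  cat("Significance fraction S[i,j]:\n")
  print(round(x$S, digits))
  cat("Tn (flagged pairs): observed median ",
      stats::median(x$Tn_observed), ", null median ",
      stats::median(x$Tn_null), "\n", sep = "")
  invisible(x)
}

#' @export
summary.kd_overlap_test <- function(object, s_cut = 0.95, ...) {
  sig <- object$pairs[!is.na(object$pairs$S) & object$pairs$S >= s_cut, ]
  out <- list(kind = object$kind, s_cut = s_cut, significant = sig,
              Tn_observed_median = stats::median(object$Tn_observed),
              Tn_null_median = stats::median(object$Tn_null))
  class(out) <- "summary.kd_overlap_test"
  out
}

#' @export
print.summary.kd_overlap_test <- function(x, ...) {
  cat("Site pairs with S >= ", x$s_cut, " (", x$kind, "):\n", sep = "")
  if (nrow(x$significant)) print(x$significant) else cat("  none\n")
  cat("Tn medians: observed ", x$Tn_observed_median, ", null ",
      x$Tn_null_median, "\n", sep = "")
  invisible(x)
}

#' @export
plot.kd_overlap_test <- function(x, ...) {
  rng <- range(c(x$Tn_observed, x$Tn_null))
  br <- seq(rng[1] - 0.5, rng[2] + 0.5, by = 1)
  h_null <- hist(x$Tn_null, breaks = br, plot = FALSE)
  h_obs <- hist(x$Tn_observed, breaks = br, plot = FALSE)
  plot(h_null$mids, h_null$density, type = "h", lwd = 6, col = "steelblue",
       xlab = "significant pairs per repetition (Tn)", ylab = "density",
       main = paste("Ensemble", x$kind, "overlap significance"), ...)
  points(h_obs$mids + 0.2, h_obs$density, type = "h", lwd = 6,
         col = adjustcolor("firebrick", 0.7))
  legend("topright", c("synthetic members", "observed record"),
         fill = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
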