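## End-to-end run driver: detect -> nullcheck -> overlap, with every
## figure-style artifact written as a CSV twin plus a JSON manifest.

normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(replicates = 100L, inner = 500L, outer = 500L,
                   mode = "resample_series", kinds = c("cluster", "quiet"),
                   cross_site_start = "2000-01-01", exclude = character(0),
                   seed = 1L, pad = 6L, quiet_method = "mean_fraction",
                   sites = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$onsets)) stop("config$onsets (CSV path) is required",
                                   call. = FALSE)
  config$kinds <- as.character(unlist(config$kinds))
  config$exclude <- as.character(unlist(config$exclude))
  config$seed <- as.integer(config$seed)
  config
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA, null = "null")), tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, site, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed for site '", site, "': ",
         conditionMessage(e), call. = FALSE))
}

#' Run the full multi-site analysis pipeline
#'
#' Reads per-site onset series, runs episode detection and the within-site
#' null comparison on each site's full window, then the cross-site overlap
#' significance analysis on the common analysis window (post-2000 by
#' default, when diagnostic awareness is comparable across sites), and
#' writes all artifacts into a run directory:
#' `summary.csv` (the site-summary table), `episodes.csv`,
#' `comparison_<site>_<kind>.csv`, `overlap_O_<kind>.csv`,
#' `overlap_S_<kind>.csv`, `pairs_<kind>.csv`, `tn_<kind>.csv`, and a
#' `manifest.json` recording the configuration, seeds and a config hash so
#' a rerun reproduces every output byte-for-byte.
#'
#' @param config a list, or path to a YAML/JSON file, with elements:
#'   `onsets` (CSV path, required), `sites` (optional named list of
#'   per-site `start_date`, `end_date`, `cluster_percentile`,
#'   `quiet_percentile`), `replicates`, `inner`, `outer`, `mode`, `kinds`,
#'   `cross_site_start`, `exclude`, `pad`, `seed`.
#' @param out_dir run directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return Invisibly, a list with the per-site fits, overlap tests and the
#'   summary table; side effect is the populated run directory.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- normalize_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  all_series <- read_onsets(config$onsets)
  site_cfg <- config$sites %||% list()
  for (id in names(site_cfg)) {
    sc <- site_cfg[[id]]
    if (!id %in% names(all_series)) next
    if (!is.null(sc$start_date) || !is.null(sc$end_date)) {
      s <- all_series[[id]]
      all_series[[id]] <- onset_series(
        s$onsets, id,
        sc$start_date %||% s$start_date, sc$end_date %||% s$end_date)
    }
  }

  message("detect + nullcheck: ", length(all_series), " site(s)")
  fits <- list()
  for (id in names(all_series)) {
    sc <- site_cfg[[id]] %||% list()
    fits[[id]] <- stage("detect/nullcheck", id, kd_fit(
      all_series[[id]],
      cluster_percentile = sc$cluster_percentile,
      quiet_percentile = sc$quiet_percentile,
      replicates = config$replicates,
      seed = child_seed(config$seed, match(id, names(all_series)))))
  }

  summary_tab <- do.call(rbind, lapply(fits, function(f)
    site_summary(f$series, f$definition)))
  utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  write_episodes(c(lapply(fits, `[[`, "clusters"),
                   lapply(fits, `[[`, "quiet")),
                 file.path(out_dir, "episodes.csv"))
  for (id in names(fits)) for (kind in config$kinds) {
    cmp <- fits[[id]]$comparison[[kind]]
    if (is.null(cmp)) next
    utils::write.csv(as.data.frame(cmp),
                     file.path(out_dir,
                               paste0("comparison_", id, "_", kind, ".csv")),
                     row.names = FALSE)
  }

  cross_ids <- setdiff(names(all_series), config$exclude)
  overlap <- list()
  if (length(cross_ids) >= 2) {
    message("overlap: ", length(cross_ids), " site(s), post-",
            config$cross_site_start)
    cross_fits <- list()
    for (id in cross_ids) {
      sc <- site_cfg[[id]] %||% list()
      cross_fits[[id]] <- stage("overlap/restrict", id, kd_fit(
        restrict_series(all_series[[id]],
                        start = as.Date(config$cross_site_start)),
        cluster_percentile = sc$cluster_percentile,
        quiet_percentile = sc$quiet_percentile,
        replicates = 0L))
    }
    for (kind in config$kinds) {
      if (kind == "quiet" &&
          any(vapply(cross_fits, function(f)
            is.na(f$definition$quiet_threshold), logical(1)))) {
        message("skipping quiet overlap: a site has no definable quiet ",
                "periods in the analysis window")
        next
      }
      ot <- stage("overlap", kind, ensemble_significance(
        cross_fits, kind = kind, R_inner = config$inner,
        R_outer = config$outer, pad = config$pad, mode = config$mode,
        seed = child_seed(config$seed, 7000 + match(kind, config$kinds)),
        quiet_method = config$quiet_method))
      overlap[[kind]] <- ot
      utils::write.csv(as.data.frame(ot$O),
                       file.path(out_dir, paste0("overlap_O_", kind, ".csv")))
      utils::write.csv(as.data.frame(ot$S),
                       file.path(out_dir, paste0("overlap_S_", kind, ".csv")))
      utils::write.csv(ot$pairs,
                       file.path(out_dir, paste0("pairs_", kind, ".csv")),
                       row.names = FALSE)
      tn_vals <- sort(unique(c(ot$Tn_observed, ot$Tn_null)))
      tn <- data.frame(
        tn = tn_vals,
        observed = vapply(tn_vals, function(v) sum(ot$Tn_observed == v),
                          numeric(1)),
        null = vapply(tn_vals, function(v) sum(ot$Tn_null == v), numeric(1)))
      utils::write.csv(tn, file.path(out_dir, paste0("tn_", kind, ".csv")),
                       row.names = FALSE)
    }
  }

  manifest <- list(
    package = "kdsync",
    version = as.character(utils::packageVersion("kdsync")),
    config = config[order(names(config))],
    config_hash = config_hash(config[order(names(config))]),
    sites = lapply(fits, function(f) list(
      n = length(f$series$onsets),
      window = c(format(f$series$start_date), format(f$series$end_date)),
      cluster_threshold = f$definition$cluster_threshold,
      quiet_threshold = f$definition$quiet_threshold)),
    warnings = character(0))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           pretty = TRUE, digits = NA,
                                           null = "null")),
             file.path(out_dir, "manifest.json"))
  invisible(list(fits = fits, overlap = overlap, summary = summary_tab,
                 out_dir = out_dir))
}
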