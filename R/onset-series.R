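#' Construct an onset series
#'
#' An onset series is one site's record of case-onset dates (one entry per
#' patient, repeats allowed when several patients fall ill on the same day)
#' together with a fixed, inclusive observation window. All downstream
#' analyses — daily counts, cluster and quiet-period detection, the Monte
#' Carlo null model — operate on this container.
#'
#' @param onsets vector of onset dates (`Date` or ISO-8601 strings), one per
#'   patient. May be empty if an explicit window is supplied.
#' @param site_id short label identifying the site.
#' @param start_date,end_date inclusive bounds of the observation window.
#'   Default to the range of `onsets`.
#' @return An object of class `onset_series`: a list with elements `site_id`,
#'   `start_date`, `end_date` and the sorted `onsets`.
#' @examples
#' s <- onset_series(c("2001-01-02", "2001-01-02", "2001-01-09"), "demo")
#' n_days(s)
#' @export
onset_series <- function(onsets, site_id = "site",
                         start_date = NULL, end_date = NULL) {
  onsets <- as_iso_date(onsets, "onset date")
  if (length(onsets) == 0 && (is.null(start_date) || is.null(end_date)))
    stop("empty onset series requires an explicit observation window",
         call. = FALSE)
  start_date <- as_iso_date(start_date %||% min(onsets), "start date")
  end_date <- as_iso_date(end_date %||% max(onsets), "end date")
  if (end_date < start_date)
    stop("end_date must be on or after start_date", call. = FALSE)
  if (length(onsets) && (min(onsets) < start_date || max(onsets) > end_date))
    stop("onset dates fall outside the declared observation window for site '",
         site_id, "'", call. = FALSE)
  structure(
    list(site_id = as.character(site_id), start_date = start_date,
         end_date = end_date, onsets = sort(onsets)),
    class = "onset_series"
  )
}

#' @export
print.onset_series <- function(x, ...) {
  cat("Onset series '", x$site_id, "': ", length(x$onsets), " cases, ",
      format(x$start_date), " .. ", format(x$end_date),
      " (", n_days(x), " days)\n", sep = "")
  invisible(x)
}

#' Number of days in an observation window
#'
#' @param series an [onset_series()].
#' @return Integer length of the inclusive window.
#' @export
n_days <- function(series) {
  as.integer(series$end_date - series$start_date) + 1L
}

#' Read onset series from a CSV file
#'
#' The interchange format is a CSV with header columns `site_id` and
#' `onset_date` (ISO-8601), one row per patient. Several sites may share one
#' file; `site_id` disambiguates.
#'
#' @param path CSV file path.
#' @param site_id site to extract; rows for other sites are ignored. `NULL`
#'   returns a named list with one [onset_series()] per site in the file.
#' @param start_date,end_date optional declared observation window (applied
#'   to every returned site). When omitted the window defaults to the range
#'   of each site's onsets.
#' @return An [onset_series()], or a named list of them when `site_id` is
#'   `NULL`.
#' @export
read_onsets <- function(path, site_id = NULL,
                        start_date = NULL, end_date = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "onset_date")
  if (!all(need %in% names(df)))
    stop("onsets CSV must have columns 'site_id' and 'onset_date'",
         call. = FALSE)
  dates <- as.Date(as.character(df$onset_date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stop("unparseable onset_date '", df$onset_date[bad], "' at data row ",
         bad, " of ", path, call. = FALSE)
  }
  df$onset_date <- dates
  if (!is.null(site_id)) {
    df <- df[df$site_id == site_id, , drop = FALSE]
    if (nrow(df) == 0)
      stop("no rows for site '", site_id, "' in ", path, call. = FALSE)
    return(onset_series(df$onset_date, site_id, start_date, end_date))
  }
  if (nrow(df) == 0) stop("no rows in ", path, call. = FALSE)
  ids <- unique(df$site_id)
  out <- lapply(ids, function(id)
    onset_series(df$onset_date[df$site_id == id], id, start_date, end_date))
  stats::setNames(out, ids)
}

#' Write onset series to CSV
#'
#' @param x an [onset_series()] or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_onsets <- function(x, path) {
  if (inherits(x, "onset_series")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(s)
    data.frame(site_id = rep(s$site_id, length(s$onsets)),
               onset_date = format(s$onsets, "%Y-%m-%d"))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Daily case counts over a site's observation window
#'
#' Maps the multiset of onset dates onto a vector of per-day counts, day 0
#' being `start_date`. Counts always sum to the number of onsets.
#'
#' @param series an [onset_series()].
#' @return Integer vector of length [n_days()] with attributes `site_id` and
#'   `start_date`, class `daily_counts`.
#' @export
daily_counts <- function(series) {
  D <- n_days(series)
  idx <- as.integer(series$onsets - series$start_date) + 1L
  counts <- tabulate(idx, nbins = D)
  structure(counts, site_id = series$site_id,
            start_date = series$start_date, class = "daily_counts")
}

#' @export
print.daily_counts <- function(x, ...) {
  cat("Daily counts '", attr(x, "site_id"), "': ", length(x), " days from ",
      format(attr(x, "start_date")), ", ", sum(x), " cases\n", sep = "")
  invisible(x)
}

#' Restrict an onset series to a sub-window
#'
#' Used to align sites onto a common analysis window before cross-site
#' comparison (by default everything from 2000-01-01 on, since earlier
#' records reflect uneven diagnostic awareness).
#'
#' @param series an [onset_series()].
#' @param start,end new inclusive bounds; `NULL` keeps the existing bound.
#' @return A new [onset_series()]; onsets outside the sub-window are dropped.
#' @export
restrict_series <- function(series, start = as.Date("2000-01-01"),
                            end = NULL) {
  start <- if (is.null(start)) series$start_date
           else max(series$start_date, as_iso_date(start, "start"))
  end <- if (is.null(end)) series$end_date
         else min(series$end_date, as_iso_date(end, "end"))
  if (end < start)
    stop("restriction window does not intersect the observation window",
         call. = FALSE)
  keep <- series$onsets >= start & series$onsets <= end
  onset_series(series$onsets[keep], series$site_id, start, end)
}
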