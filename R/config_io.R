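#' Run configuration
#'
#' Central bundle of the pipeline's tunable constants. Values default to the
#' study conditions the pipeline was designed around: a 0.03 degree grid, a
#' 2 m/s migratory swimming speed for the movement kernel, a 10 m two-sided
#' bathymetric band, a 300 m conservative seafloor cap for days without
#' depth data, a 20 km/day post-release tag drift speed, 60-minute acoustic
#' bins, a March-August spawning season, the 95th MA percentile for
#' high-activity events and a 5-position minimum for seasonal KUDs.
#'
#' @param grid_resolution_deg grid cell size, degrees
#' @param migratory_speed_mps hard daily movement bound, m/s
#' @param depth_band_m two-sided bathymetric band, m
#' @param max_seafloor_m seafloor cap when no depth data, m
#' @param drift_speed_km_day pop-up drift speed, km/day
#' @param bin_minutes acoustic binning interval, minutes
#' @param spawning_months integer months of the spawning season (contiguous)
#' @param ma_percentile percentile defining high-activity events
#' @param kud_min_positions minimum daily positions per season for KUDs
#' @param random_seed integer seed for stochastic steps
#' @return a validated list of class `RunConfig`
#' @export
runConfig <- function(grid_resolution_deg = 0.03, migratory_speed_mps = 2.0,
                      depth_band_m = 10, max_seafloor_m = 300,
                      drift_speed_km_day = 20, bin_minutes = 60,
                      spawning_months = 3:8, ma_percentile = 95,
                      kud_min_positions = 5, random_seed = 1L) {
  cfg <- list(grid_resolution_deg = grid_resolution_deg,
              migratory_speed_mps = migratory_speed_mps,
              depth_band_m = depth_band_m, max_seafloor_m = max_seafloor_m,
              drift_speed_km_day = drift_speed_km_day,
              bin_minutes = bin_minutes,
              spawning_months = as.integer(spawning_months),
              ma_percentile = ma_percentile,
              kud_min_positions = kud_min_positions,
              random_seed = as.integer(random_seed))
  num <- cfg[!(names(cfg) %in% c("spawning_months", "random_seed"))]
  if (any(vapply(num, function(x) !is.numeric(x) || x <= 0, logical(1))))
    stop("all RunConfig numeric fields must be positive")
  sm <- cfg$spawning_months
  if (length(sm) < 1 || any(sm < 1 | sm > 12) || any(diff(sm) != 1))
    stop("spawning_months must be a contiguous month set")
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname runConfig
#' @param path YAML file whose top-level keys override the defaults
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown RunConfig fields: ", paste(bad, collapse = ", "))
  do.call(runConfig, vals)
}

## half-up rounding to the printed precision of summary tables
## (base round() is banker's rounding, which printed tables do not use)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Day-count conventions
#'
#' Two deliberately distinct conventions coexist in telemetry summaries:
#' the acoustic detection span counts both endpoint days (release day and
#' last-detection day), while PSAT deployment duration is the plain date
#' difference. `spanDaysInclusive` implements the former,
#' `durationDaysExclusive` the latter.
#'
#' @param from,to Dates
#' @return integer day count
#' @export
spanDaysInclusive <- function(from, to) {
  as.integer(as.Date(to) - as.Date(from)) + 1L
}

#' @rdname spanDaysInclusive
#' @export
durationDaysExclusive <- function(from, to) {
  as.integer(as.Date(to) - as.Date(from))
}

parseUtc <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read acoustic detection records
#'
#' CSV with header `tag_id,receiver_id,timestamp` (ISO-8601, UTC). Records
#' are returned sorted by tag then time. When receiver metadata is supplied,
#' detections at unknown receivers are reported with a warning (they are
#' retained; filtering is the caller's decision).
#'
#' @param path CSV path
#' @param receivers optional data.frame from [readReceivers()]
#' @return data.frame(tag_id, receiver_id, timestamp [POSIXct UTC])
#' @export
readDetections <- function(path, receivers = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("tag_id", "receiver_id", "timestamp")
  if (!all(need %in% names(d)))
    stop("detections CSV must have columns ", paste(need, collapse = ","))
  if (nrow(d) == 0) {
    warning("empty detections file: ", path)
    return(data.frame(tag_id = character(), receiver_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC")))
  }
  ts <- suppressWarnings(parseUtc(d$timestamp))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("malformed timestamp '%s' in row %d of %s",
                 d$timestamp[bad], bad, path))
  }
  d$timestamp <- ts
  if (!is.null(receivers)) {
    unknown <- setdiff(unique(d$receiver_id), receivers$receiver_id)
    if (length(unknown))
      warning("detections at unknown receivers: ",
              paste(unknown, collapse = ", "))
  }
  d <- d[order(d$tag_id, d$timestamp), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @rdname readDetections
#' @param detections data.frame as returned by `readDetections`
#' @export
writeDetections <- function(detections, path) {
  out <- detections
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read receiver station metadata
#'
#' CSV with columns `receiver_id,lon,lat,site_label,active_from,active_to`.
#'
#' @param path CSV path
#' @return data.frame with Dates for the deployment interval
#' @export
readReceivers <- function(path) {
  r <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("receiver_id", "lon", "lat", "site_label", "active_from", "active_to")
  if (!all(need %in% names(r)))
    stop("receivers CSV must have columns ", paste(need, collapse = ","))
  r$active_from <- as.Date(r$active_from)
  r$active_to <- as.Date(r$active_to)
  if (any(r$lon < -180 | r$lon > 180 | r$lat < -90 | r$lat > 90))
    stop("receiver coordinates out of range")
  if (any(r$active_from > r$active_to, na.rm = TRUE))
    stop("receiver active_from must be <= active_to")
  r
}

#' @rdname readReceivers
#' @param receivers data.frame as returned by `readReceivers`
#' @export
writeReceivers <- function(receivers, path) {
  write.csv(receivers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tagging cohort table
#'
#' CSV with columns `tag_id,total_length,tagging_site,release_date` and
#' optionally `psat_programmed_days,psat_popup_date`.
#'
#' @param path CSV path
#' @return data.frame, dates parsed
#' @export
readCohort <- function(path) {
  k <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "total_length", "tagging_site", "release_date")
  if (!all(need %in% names(k)))
    stop("cohort CSV must have columns ", paste(need, collapse = ","))
  k$release_date <- as.Date(k$release_date)
  if ("psat_popup_date" %in% names(k)) {
    k$psat_popup_date <- as.Date(k$psat_popup_date)
    if (any(k$psat_popup_date < k$release_date, na.rm = TRUE))
      stop("pop-up date before release date")
  }
  if (any(k$total_length <= 0)) stop("total_length must be positive")
  k
}

#' Cohort summary table with a mean +- SE bottom row
#'
#' Builds the classic telemetry cohort table: one row per individual with
#' its per-tag metrics, plus a bottom row of column means and standard
#' errors (sample sd / sqrt(n) over non-missing entries), rounded half-up to
#' each column's printed precision.
#'
#' @param cohort data.frame with at least `tag_id`
#' @param metrics data.frame keyed by `tag_id`; remaining numeric columns are
#'   the per-tag metrics to summarise
#' @param digits named integer vector of printed decimal places per metric
#'   column (default 0 for all)
#' @return list with `table` (per-individual rows), `mean` and `se` (named
#'   numeric vectors, rounded), and `n` (non-missing counts)
#' @export
cohortSummary <- function(cohort, metrics, digits = NULL) {
  if (nrow(cohort) == 0) stop("empty cohort")
  tab <- merge(cohort, metrics, by = "tag_id", all.x = TRUE, sort = FALSE)
  tab <- tab[match(cohort$tag_id, tab$tag_id), , drop = FALSE]
  rownames(tab) <- NULL
  numcols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  numcols <- setdiff(numcols, "tag_id")
  if (is.null(digits)) digits <- setNames(rep(0L, length(numcols)), numcols)
  mu <- se <- setNames(numeric(length(numcols)), numcols)
  nn <- setNames(integer(length(numcols)), numcols)
  for (cn in numcols) {
    x <- tab[[cn]][!is.na(tab[[cn]])]
    nn[cn] <- length(x)
    dg <- if (cn %in% names(digits)) digits[[cn]] else 0L
    mu[cn] <- roundHalfUp(mean(x), dg)
    se[cn] <- if (length(x) > 1)
      roundHalfUp(sd(x) / sqrt(length(x)), dg) else NA_real_
  }
  list(table = tab, mean = mu, se = se, n = nn)
}
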