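#' Filter spurious acoustic detections
#'
#' A detection is spurious when it occurs isolated in a period shorter than
#' 24 h: it is retained iff at least one other detection of the same tag (at
#' any receiver) lies within +-24 h. A gap of exactly 24 h counts as within.
#' The filter is idempotent.
#'
#' @param detections data.frame(tag_id, receiver_id, timestamp) as from
#'   [readDetections()]
#' @param window_hours companion window (default 24)
#' @return the retained rows, in (tag, time) order
#' @export
filterSpurious <- function(detections, window_hours = 24) {
  if (nrow(detections) == 0) return(detections)
  d <- detections[order(detections$tag_id, detections$timestamp), , drop = FALSE]
  keep <- logical(nrow(d))
  win <- window_hours * 3600
  for (tag in unique(d$tag_id)) {
    idx <- which(d$tag_id == tag)
    t <- as.numeric(d$timestamp[idx])
    n <- length(t)
    if (n == 1) { keep[idx] <- FALSE; next }
    prevgap <- c(Inf, diff(t))
    nextgap <- c(diff(t), Inf)
    keep[idx] <- prevgap <= win | nextgap <= win
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residency summary for one individual
#'
#' Days detected `D_D` is the number of distinct UTC calendar days with at
#' least one detection; the detection span `T_P` is the inclusive day count
#' from release to last detection (both endpoint days counted); the
#' residency index is `I_R = D_D / T_P` (0 = never present, 1 = detected
#' every day at liberty), reported rounded to 2 decimals.
#'
#' @param release_date Date of release
#' @param detections detections of this tag (already filtered)
#' @return list(tag_id, D_D, T_P, I_R, I_R_raw, detected); with no
#'   detections `I_R` is NA and `detected` FALSE
#' @export
residencyIndex <- function(release_date, detections) {
  tag <- if (nrow(detections)) detections$tag_id[1] else NA_character_
  if (nrow(detections) == 0)
    return(list(tag_id = tag, D_D = 0L, T_P = NA_integer_, I_R = NA_real_,
                I_R_raw = NA_real_, detected = FALSE))
  days <- unique(as.Date(detections$timestamp, tz = "UTC"))
  D_D <- length(days)
  T_P <- spanDaysInclusive(release_date, max(as.Date(detections$timestamp,
                                                     tz = "UTC")))
  raw <- D_D / T_P
  list(tag_id = tag, D_D = D_D, T_P = T_P, I_R = roundHalfUp(raw, 2),
       I_R_raw = raw, detected = TRUE)
}

#' Pool detections into clock-aligned time bins
#'
#' One row per (tag, receiver, bin) with the detection count. Bins are
#' aligned to UTC clock time (a 60-min bin starts on the hour).
#'
#' @param detections filtered detections
#' @param bin_minutes bin width in minutes (default 60)
#' @return data.frame(tag_id, receiver_id, bin_start [POSIXct], n)
#' @export
binDetections <- function(detections, bin_minutes = 60) {
  if (nrow(detections) == 0)
    return(data.frame(tag_id = character(), receiver_id = character(),
                      bin_start = as.POSIXct(character(), tz = "UTC"),
                      n = integer()))
  w <- bin_minutes * 60
  bin <- as.POSIXct(floor(as.numeric(detections$timestamp) / w) * w,
                    origin = "1970-01-01", tz = "UTC")
  agg <- aggregate(list(n = rep(1L, nrow(detections))),
                   by = list(tag_id = detections$tag_id,
                             receiver_id = detections$receiver_id,
                             bin_start = bin),
                   FUN = sum)
  agg <- agg[order(agg$tag_id, agg$bin_start, agg$receiver_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Daily centre-of-activity positions
#'
#' For each tag-day, the detection-count-weighted arithmetic mean of the
#' positions of the receivers that heard the tag over the 24 h (UTC) bin.
#' Receiver arrays span well under one degree, so planar averaging of
#' degrees is adequate.
#'
#' @param detections filtered detections
#' @param receivers receiver metadata ([readReceivers()])
#' @return data.frame(tag_id, date, lon, lat, n_detections)
#' @export
centreOfActivity <- function(detections, receivers) {
  if (nrow(detections) == 0)
    return(data.frame(tag_id = character(), date = as.Date(character()),
                      lon = numeric(), lat = numeric(),
                      n_detections = integer()))
  pos <- receivers[match(detections$receiver_id, receivers$receiver_id),
                   c("lon", "lat")]
  if (anyNA(pos$lon))
    stop("detections reference receivers missing from metadata")
  day <- as.Date(detections$timestamp, tz = "UTC")
  key <- interaction(detections$tag_id, day, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_along(key), key), function(idx) {
    data.frame(tag_id = detections$tag_id[idx[1]], date = day[idx[1]],
               lon = mean(pos$lon[idx]), lat = mean(pos$lat[idx]),
               n_detections = length(idx))
  }))
  out <- out[order(out$tag_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-occurrence events from binned detections
#'
#' A co-occurrence event is a (receiver, bin) pair at which two or more
#' distinct tags were detected: joint space usage requires overlap in both
#' space (same receiver) and time (same bin). Each event is labelled by the
#' diel phase of the bin midpoint at the receiver position.
#'
#' @param binned output of [binDetections()]
#' @param receivers receiver metadata
#' @param bin_minutes bin width used, minutes
#' @return list with `events` (data.frame receiver_id, bin_start, group_size,
#'   members, diel) and `group_size_histogram` (named integer vector)
#' @export
coOccurrences <- function(binned, receivers, bin_minutes = 60) {
  if (length(unique(binned$tag_id)) < 2)
    return(list(events = data.frame(receiver_id = character(),
                                    bin_start = as.POSIXct(character(), tz = "UTC"),
                                    group_size = integer(), members = character(),
                                    diel = character()),
                group_size_histogram = integer()))
  key <- interaction(binned$receiver_id, binned$bin_start, drop = TRUE)
  ev <- lapply(split(seq_along(key), key), function(idx) {
    tags <- sort(unique(binned$tag_id[idx]))
    if (length(tags) < 2) return(NULL)
    data.frame(receiver_id = binned$receiver_id[idx[1]],
               bin_start = binned$bin_start[idx[1]],
               group_size = length(tags),
               members = paste(tags, collapse = ";"))
  })
  ev <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(ev))
    return(list(events = data.frame(receiver_id = character(),
                                    bin_start = as.POSIXct(character(), tz = "UTC"),
                                    group_size = integer(), members = character(),
                                    diel = character()),
                group_size_histogram = integer()))
  mid <- ev$bin_start + bin_minutes * 60 / 2
  rp <- receivers[match(ev$receiver_id, receivers$receiver_id), ]
  ev$diel <- vapply(seq_len(nrow(ev)), function(i)
    dielPhase(mid[i], rp$lon[i], rp$lat[i]), character(1))
  ev <- ev[order(ev$bin_start, ev$receiver_id), , drop = FALSE]
  rownames(ev) <- NULL
  hist <- table(factor(ev$group_size, levels = 2:max(ev$group_size)))
  list(events = ev, group_size_histogram = setNames(as.integer(hist),
                                                    names(hist)))
}
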