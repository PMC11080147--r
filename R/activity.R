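#' Acceleration magnitude
#'
#' Euclidean norm of the three acceleration axes,
#' `MA = sqrt(X^2 + Y^2 + Z^2)`.
#'
#' @param x,y,z axis accelerations in g (vectorised)
#' @return magnitude in g
#' @export
accelMagnitude <- function(x, y, z) sqrt(x^2 + y^2 + z^2)

#' High-activity events from an acceleration-magnitude series
#'
#' The high-activity threshold is the individual's 95th percentile of MA
#' (linear-interpolation percentile, never pooled across individuals); an
#' event is a sample strictly above the threshold, so the overall event rate
#' is at most 5% by construction. The daily percentage is 100 x events /
#' samples within each UTC day, summarised per month and per hour.
#'
#' @param time POSIXct sample times (UTC)
#' @param ma acceleration magnitude series (g), >= 100 samples
#' @param percentile threshold percentile (default 95)
#' @return list: `threshold`, `is_event` (logical per sample), `daily`
#'   data.frame(date, pct), `monthly` data.frame(month, mean_pct),
#'   `hourly` data.frame(hour, mean_frac), `overall_rate_pct`
#' @export
highActivityEvents <- function(time, ma, percentile = 95) {
  stopifnot(length(time) == length(ma))
  if (length(ma) < 100) stop("at least 100 samples required")
  thr <- as.numeric(quantile(ma, percentile / 100, type = 7))
  if (diff(range(ma)) == 0)
    warning("constant MA series: threshold equals the constant, no events")
  ev <- ma > thr
  day <- as.Date(time, tz = "UTC")
  daily <- aggregate(list(pct = ev * 100), by = list(date = day), FUN = mean)
  mon <- as.integer(format(daily$date, "%m"))
  monthly <- aggregate(list(mean_pct = daily$pct), by = list(month = mon),
                       FUN = mean)
  hr <- as.integer(format(time, "%H", tz = "UTC"))
  hourly <- aggregate(list(mean_frac = ev * 1), by = list(hour = hr),
                      FUN = mean)
  list(threshold = thr, is_event = ev, daily = daily, monthly = monthly,
       hourly = hourly, overall_rate_pct = 100 * mean(ev))
}

## compact letter display from a logical "significantly different" matrix
## (insert-absorb): groups sharing a letter are not significantly different
compactLetters <- function(signif) {
  lev <- rownames(signif)
  groups <- list(lev)  # start with one group holding everything
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i || !signif[i, j]) next
    for (g in seq_along(groups)) {
      if (all(c(lev[i], lev[j]) %in% groups[[g]])) {
        g1 <- setdiff(groups[[g]], lev[i])
        g2 <- setdiff(groups[[g]], lev[j])
        groups[[g]] <- g1
        groups[[length(groups) + 1]] <- g2
      }
    }
    # absorb redundant groups
    keep <- rep(TRUE, length(groups))
    for (a in seq_along(groups)) for (b in seq_along(groups))
      if (a != b && keep[a] && keep[b] &&
          all(groups[[a]] %in% groups[[b]])) keep[a] <- FALSE
    groups <- groups[keep]
  }
  out <- setNames(rep("", length(lev)), lev)
  for (g in seq_along(groups))
    out[groups[[g]]] <- paste0(out[groups[[g]]], letters[g])
  out
}

#' Pairwise monthly activity comparison
#'
#' Wilcoxon signed-rank tests on per-individual monthly mean daily activity
#' percentages, paired within individual for each month pair (exact
#' distribution for n <= 25 without ties, normal approximation with
#' continuity correction otherwise), with Bonferroni correction
#' (p multiplied by the number of tested pairs, capped at 1) and a compact
#' letter display at alpha = 0.05. Month pairs with fewer than 2 individuals
#' observed in both months are skipped and listed in `skipped`.
#'
#' @param monthly data.frame(tag_id, month, mean_pct): one row per
#'   individual-month
#' @param alpha significance level for the letter display
#' @return list: `p_raw`, `p_adj` (month x month matrices), `letters`
#'   (named by month), `skipped` (character pair labels)
#' @export
monthlyActivityTest <- function(monthly, alpha = 0.05) {
  months <- sort(unique(monthly$month))
  if (length(months) < 2) stop("at least 2 months required")
  m <- length(months)
  p_raw <- matrix(NA_real_, m, m, dimnames = list(months, months))
  skipped <- character(0)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    a <- monthly[monthly$month == months[i], c("tag_id", "mean_pct")]
    b <- monthly[monthly$month == months[j], c("tag_id", "mean_pct")]
    both <- merge(a, b, by = "tag_id")
    if (nrow(both) < 2) {
      skipped <- c(skipped, sprintf("%d-%d", months[i], months[j]))
      next
    }
    d <- both$mean_pct.x - both$mean_pct.y
    if (all(d == 0)) {  # identical months carry no evidence of a difference
      p_raw[i, j] <- p_raw[j, i] <- 1
      next
    }
    exact <- nrow(both) <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
    p_raw[i, j] <- p_raw[j, i] <- suppressWarnings(
      wilcox.test(both$mean_pct.x, both$mean_pct.y, paired = TRUE,
                  exact = exact, correct = TRUE)$p.value)
  }
  n_pairs <- sum(!is.na(p_raw[upper.tri(p_raw)]))
  p_adj <- pmin(p_raw * n_pairs, 1)
  signif <- !is.na(p_adj) & p_adj < alpha
  rownames(signif) <- colnames(signif) <- as.character(months)
  list(p_raw = p_raw, p_adj = p_adj, letters = compactLetters(signif),
       skipped = skipped)
}

#' Monthly depth-occupancy densities
#'
#' Density of depth usage per calendar month over 1-m depth bins (each
#' month's density sums to 1), with the mean temperature per occupied bin
#' for colour-coding depth-use plots.
#'
#' @param time POSIXct sample times (UTC)
#' @param depth depth series, m positive down
#' @param temp optional matching temperature series, degC
#' @param bin_m depth bin width, m (default 1)
#' @return data.frame(month, depth_bin [lower edge m], density, mean_temp);
#'   months absent from the data are absent from the table
#' @export
depthDensityByMonth <- function(time, depth, temp = NULL, bin_m = 1) {
  stopifnot(length(time) == length(depth))
  mon <- as.integer(format(time, "%m", tz = "UTC"))
  bin <- floor(depth / bin_m) * bin_m
  out <- lapply(sort(unique(mon)), function(m) {
    sel <- mon == m
    tb <- table(bin[sel])
    dens <- as.numeric(tb) / sum(tb)
    mt <- if (is.null(temp)) rep(NA_real_, length(tb)) else
      vapply(names(tb), function(b)
        mean(temp[sel][bin[sel] == as.numeric(b)]), numeric(1))
    data.frame(month = m, depth_bin = as.numeric(names(tb)),
               density = dens, mean_temp = mt)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
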