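#' Merge PSAT and acoustic daily positions
#'
#' Union of the two position streams by tag-day. When both streams hold a
#' position for the same day the acoustic centre of activity is retained
#' (COAs are treated as known locations upstream, so they are the more
#' trusted stream). Season labels and spawning season-years (e.g.
#' `"spawning-2019"`) are attached.
#'
#' @param psat data.frame(tag_id, date, lon, lat) reconstructed positions
#' @param coas data.frame(tag_id, date, lon, lat) centre-of-activity
#'   positions
#' @param spawning_months months of the spawning season
#' @return data.frame(tag_id, date, lon, lat, source, season, season_year)
#' @export
mergeDailyPositions <- function(psat, coas, spawning_months = 3:8) {
  take <- function(d, src) {
    if (is.null(d) || nrow(d) == 0)
      return(data.frame(tag_id = character(), date = as.Date(character()),
                        lon = numeric(), lat = numeric(),
                        source = character()))
    data.frame(tag_id = d$tag_id, date = as.Date(d$date), lon = d$lon,
               lat = d$lat, source = src)
  }
  all <- rbind(take(coas, "coa"), take(psat, "psat"))
  if (nrow(all) == 0) return(cbind(all, season = character(),
                                   season_year = character()))
  all <- all[!duplicated(all[, c("tag_id", "date")]), , drop = FALSE]
  all <- all[order(all$tag_id, all$date), , drop = FALSE]
  all$season <- seasonLabel(all$date, spawning_months)
  yr <- format(all$date, "%Y")
  all$season_year <- paste0(all$season, "-", yr)
  rownames(all) <- NULL
  all
}

#' Philopatry eligibility filter
#'
#' Tags eligible for the inter-seasonal spawning-site comparison: monitored
#' in at least two distinct spawning season-years, with at least
#' `min_positions` daily positions in each.
#'
#' @param positions output of [mergeDailyPositions()]
#' @param min_positions minimum daily positions per spawning season
#'   (default 5)
#' @return character vector of eligible tag ids
#' @export
philopatryFilter <- function(positions, min_positions = 5) {
  sp <- positions[positions$season == "spawning", , drop = FALSE]
  if (nrow(sp) == 0) return(character(0))
  tab <- table(sp$tag_id, sp$season_year)
  eligible <- rownames(tab)[rowSums(tab >= min_positions) >= 2]
  sort(eligible)
}

## azimuthal equidistant projection (km) about an origin, and its inverse
aeqdProject <- function(lon, lat, origin) {
  d <- gcDistKm(origin[1], origin[2], lon, lat)
  az <- geosphere::bearing(matrix(origin, ncol = 2),
                           cbind(lon, lat)) * pi / 180
  az[is.na(az)] <- 0  # point at the origin
  cbind(x = d * sin(az), y = d * cos(az))
}

aeqdInverse <- function(x, y, origin) {
  d <- sqrt(x^2 + y^2)
  az <- atan2(x, y) * 180 / pi
  p <- geosphere::destPoint(matrix(origin, ncol = 2), az, d * 1000)
  cbind(lon = p[, 1], lat = p[, 2])
}

#' Kernel utilisation distribution
#'
#' Bivariate Gaussian product-kernel density of daily positions, evaluated
#' on a planar azimuthal-equidistant projection local to the positions'
#' centroid (degree-space KDE distorts at mid latitudes). The default
#' bandwidth is the reference bandwidth `href = sigma_hat * n^(-1/6)` with
#' `sigma_hat = sqrt((var(x) + var(y)) / 2)`. Contours are drawn at the
#' density levels enclosing 50% and 95% of the total mass.
#'
#' @param positions data.frame with `lon`, `lat` (>= 5 rows)
#' @param bandwidth kernel sd in km; NULL for href
#' @param grid list(x, y) of evaluation-grid vectors in km about `origin`,
#'   or NULL to span the positions plus a 4-bandwidth margin (n = 150 per
#'   axis); pass a common grid to compare KUDs
#' @param origin c(lon, lat) projection origin; default the centroid
#' @return list of class `KudResult`: `origin`, `x`, `y` (km), `density`
#'   (rows = y, integrates to 1), `h`, `cell_area_km2`, `levels` (named
#'   50/95 density levels), `masks` (logical matrices), `contours`
#'   (lon/lat polygon list per level), `n`
#' @export
kud <- function(positions, bandwidth = NULL, grid = NULL, origin = NULL) {
  stopifnot(nrow(positions) >= 5)
  if (is.null(origin)) origin <- c(mean(positions$lon), mean(positions$lat))
  xy <- aeqdProject(positions$lon, positions$lat, origin)
  n <- nrow(xy)
  sigma <- sqrt((var(xy[, 1]) + var(xy[, 2])) / 2)
  if (sigma == 0 && is.null(bandwidth))
    stop("all positions identical: supply a minimum bandwidth or jitter")
  h <- if (is.null(bandwidth)) sigma * n^(-1 / 6) else bandwidth
  if (is.null(grid)) {
    pad <- 4 * h
    grid <- list(x = seq(min(xy[, 1]) - pad, max(xy[, 1]) + pad,
                         length.out = 150),
                 y = seq(min(xy[, 2]) - pad, max(xy[, 2]) + pad,
                         length.out = 150))
  }
  gx <- grid$x; gy <- grid$y
  dx <- outer(rep(1, length(gy)), gx)
  dens <- matrix(0, length(gy), length(gx))
  for (i in seq_len(n)) {
    kx <- dnorm(gx, xy[i, 1], h)
    ky <- dnorm(gy, xy[i, 2], h)
    dens <- dens + outer(ky, kx)
  }
  dens <- dens / n
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  levelFor <- function(p) {
    o <- order(dens, decreasing = TRUE)
    cum <- cumsum(dens[o]) * cell
    dens[o][which(cum >= p * sum(dens) * cell)[1]]
  }
  lv <- c("50" = levelFor(0.5), "95" = levelFor(0.95))
  masks <- lapply(lv, function(l) dens >= l)
  contours <- lapply(lv, function(l) {
    cl <- contourLines(gx, gy, t(dens), levels = l)
    lapply(cl, function(p) aeqdInverse(p$x, p$y, origin))
  })
  res <- list(origin = origin, x = gx, y = gy, density = dens, h = h,
              cell_area_km2 = cell, levels = lv, masks = masks,
              contours = contours, n = n)
  class(res) <- "KudResult"
  res
}

#' Area of a KUD probability contour
#'
#' @param k a `KudResult`
#' @param level `"50"` or `"95"`
#' @return area of the contour region, km^2
#' @export
kudArea <- function(k, level = "50") {
  sum(k$masks[[level]]) * k$cell_area_km2
}

#' Overlap between two kernel utilisation distributions
#'
#' Quantifies inter-seasonal habitat re-use: intersection-over-union of the
#' 50% and 95% contour regions, the utilisation-distribution product
#' integral, and the UDOI (product integral scaled by the area of the union
#' of the two 95% regions). Both KUDs must share the evaluation grid and
#' projection origin.
#'
#' @param a,b `KudResult` objects on a common grid
#' @return list(iou50, iou95, overlap_integral, udoi)
#' @export
seasonalOverlap <- function(a, b) {
  if (!isTRUE(all.equal(a$x, b$x)) || !isTRUE(all.equal(a$y, b$y)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop("KUDs must share the evaluation grid and origin")
  iou <- function(level) {
    ia <- a$masks[[level]]; ib <- b$masks[[level]]
    un <- sum(ia | ib)
    if (un == 0) return(0)
    sum(ia & ib) / un
  }
  ov <- sum(a$density * b$density) * a$cell_area_km2
  union_area <- sum(a$masks[["95"]] | b$masks[["95"]]) * a$cell_area_km2
  list(iou50 = iou("50"), iou95 = iou("95"), overlap_integral = ov,
       udoi = ov * union_area)
}
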