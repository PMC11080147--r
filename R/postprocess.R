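#' Depth-based position correction
#'
#' Posterior-mean positions can fall on land or on seafloor incompatible
#' with the tag's daily maximum depth. A position is kept when the local
#' seafloor depth is within `band` metres of the day's maximum depth;
#' otherwise it is moved to the nearest (great-circle) water cell whose
#' seafloor satisfies the band, with deterministic tie-breaking by lowest
#' cell index. Days without depth data are corrected only off land and off
#' seafloor deeper than `cap`. Idempotent.
#'
#' @param lon,lat the daily position
#' @param day_max_depth daily maximum depth (m) or NA
#' @param bathy bathymetry [RasterGrid-class]
#' @param band admissible seafloor band, m (default 10)
#' @param cap conservative seafloor cap for no-depth days, m (default 300)
#' @return list(lon, lat, snapped, flagged) -- `flagged` TRUE when no
#'   admissible cell exists and the position was left unchanged
#' @export
depthSnap <- function(lon, lat, day_max_depth, bathy, band = 10, cap = 300) {
  sf <- bathy@values
  ci <- cellIndex(bathy, lon, lat)
  here <- sf[ci["row"], ci["col"]]
  if (is.null(day_max_depth) || is.na(day_max_depth)) {
    if (here > 0 && here <= cap)
      return(list(lon = lon, lat = lat, snapped = FALSE, flagged = FALSE))
    ok <- sf > 0 & sf <= cap
  } else {
    if (here > 0 && abs(here - day_max_depth) <= band)
      return(list(lon = lon, lat = lat, snapped = FALSE, flagged = FALSE))
    ok <- abs(sf - day_max_depth) <= band
  }
  nc <- nearestWaterCell(bathy, lon, lat, ok)
  if (is.null(nc))
    return(list(lon = lon, lat = lat, snapped = FALSE, flagged = TRUE))
  list(lon = nc$lon, lat = nc$lat, snapped = TRUE, flagged = FALSE)
}

#' @rdname depthSnap
#' @param positions data.frame(date, lon, lat)
#' @param max_depth numeric daily maximum depths aligned with `positions`
#' @return for `snapTrack`: the positions with corrected coordinates and
#'   logical columns `snapped`, `flagged`
#' @export
snapTrack <- function(positions, max_depth, bathy, band = 10, cap = 300) {
  stopifnot(nrow(positions) == length(max_depth))
  out <- positions
  out$snapped <- FALSE
  out$flagged <- FALSE
  for (i in seq_len(nrow(out))) {
    s <- depthSnap(out$lon[i], out$lat[i], max_depth[i], bathy, band, cap)
    out$lon[i] <- s$lon; out$lat[i] <- s$lat
    out$snapped[i] <- s$snapped; out$flagged[i] <- s$flagged
  }
  out
}

#' Water-cell movement graph
#'
#' 16-neighbour (rook + diagonal + knight moves) undirected graph over the
#' water cells, edge weights the great-circle distance between cell centres
#' in km. The knight moves keep the grid-metric overestimate of the
#' geodesic within a few percent (up to ~4% on this anisotropic lon/lat
#' lattice; unobstructed pairs short-circuit to the exact great-circle
#' distance in [leastCostPath()]). Note that, as in any 16-neighbour
#' lattice, knight-move edges can step across a single-cell-wide land
#' barrier; barriers two or more cells wide are impassable.
#'
#' @param bathy bathymetry [RasterGrid-class]
#' @return an igraph graph whose vertex names are water cell indices
#'   (column-major in the grid matrix)
#' @export
waterGraph <- function(bathy) {
  wm <- waterMask(bathy)
  nr <- nrow(wm); ncol_ <- ncol(wm)
  idx <- which(wm)
  id <- matrix(NA_integer_, nr, ncol_)
  id[idx] <- seq_along(idx)
  rc <- arrayInd(idx, dim(wm))
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1),
                c(1, 2), c(2, 1), c(1, -2), c(2, -1))
  from <- to <- integer(0)
  w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- rc[, 1] + offs[k, 1]
    c2 <- rc[, 2] + offs[k, 2]
    valid <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol_
    v2 <- rep(NA_integer_, length(idx))
    v2[valid] <- id[cbind(r2[valid], c2[valid])]
    ok <- !is.na(v2)
    if (!any(ok)) next
    from <- c(from, seq_along(idx)[ok])
    to <- c(to, v2[ok])
    w <- c(w, gcDistKm(bathy@lon[rc[ok, 2]], bathy@lat[rc[ok, 1]],
                       bathy@lon[c2[ok]], bathy@lat[r2[ok]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  igraph::V(g)$cell <- idx
  igraph::V(g)$lon <- bathy@lon[rc[, 2]]
  igraph::V(g)$lat <- bathy@lat[rc[, 1]]
  g
}

## TRUE when the straight segment between two points stays on water
segmentClear <- function(p1, p2, bathy) {
  d_km <- gcDistKm(p1[1], p1[2], p2[1], p2[2])
  if (d_km < 1e-9) return(TRUE)
  step_km <- cellSizeDeg(bathy) * 111.32 / 2
  npts <- max(2, ceiling(d_km / step_km))
  pts <- geosphere::gcIntermediate(p1, p2, n = npts, addStartEnd = TRUE)
  for (i in seq_len(nrow(pts))) {
    ci <- cellIndex(bathy, pts[i, 1], pts[i, 2])
    if (bathy@values[ci["row"], ci["col"]] <= 0) return(FALSE)
  }
  TRUE
}

#' Shortest in-water path between two positions
#'
#' Straight great-circle distance when the segment is unobstructed;
#' otherwise the least-cost path over the 16-neighbour water graph
#' (Dijkstra). Both endpoints are snapped to their containing (or nearest)
#' water cell. Endpoints in disconnected water components raise an error
#' naming both points.
#'
#' @param p1,p2 c(lon, lat)
#' @param bathy bathymetry [RasterGrid-class]
#' @param graph optional precomputed [waterGraph()] (built on the fly when
#'   NULL; precompute it when measuring many segments)
#' @return list(path = matrix lon/lat polyline, length_km)
#' @export
leastCostPath <- function(p1, p2, bathy, graph = NULL) {
  d_straight <- gcDistKm(p1[1], p1[2], p2[1], p2[2])
  if (d_straight < 1e-9)
    return(list(path = rbind(p1, p2), length_km = 0))
  if (segmentClear(p1, p2, bathy))
    return(list(path = rbind(p1, p2), length_km = d_straight))
  if (is.null(graph)) graph <- waterGraph(bathy)
  vcells <- igraph::V(graph)$cell
  toVertex <- function(p) {
    nc <- nearestWaterCell(bathy, p[1], p[2])
    if (is.null(nc)) stop("no water cell available for path endpoint")
    cell <- (nc$col - 1) * nrow(bathy@values) + nc$row
    match(cell, vcells)
  }
  v1 <- toVertex(p1); v2 <- toVertex(p2)
  sp <- suppressWarnings(igraph::shortest_paths(graph, from = v1, to = v2,
                                                output = "vpath"))
  vp <- sp$vpath[[1]]
  if (length(vp) == 0)
    stop(sprintf("no in-water path between (%.3f, %.3f) and (%.3f, %.3f): disconnected water components",
                 p1[1], p1[2], p2[1], p2[2]))
  lonp <- igraph::V(graph)$lon[as.integer(vp)]
  latp <- igraph::V(graph)$lat[as.integer(vp)]
  seg <- gcDistKm(lonp[-length(lonp)], latp[-length(latp)],
                  lonp[-1], latp[-1])
  list(path = cbind(lon = lonp, lat = latp), length_km = sum(seg))
}

#' Interpolate around land and measure minimum travelled distance
#'
#' For each pair of consecutive daily positions whose straight segment
#' crosses land, intermediate positions are inserted along the least-cost
#' in-water polyline, placed by linear interpolation in time proportional to
#' cumulative path length. The minimum travelled distance is the sum of the
#' per-segment in-water path lengths.
#'
#' @param positions data.frame(date, lon, lat) of >= 2 corrected positions
#' @param bathy bathymetry [RasterGrid-class]
#' @param graph optional precomputed [waterGraph()]
#' @return list of class `CorrectedTrack`: `positions` (with inserted rows,
#'   flagged by the logical `interpolated` column and fractional-day
#'   `time`), `segment_km` per original consecutive pair, and `total_km`
#' @export
interpolateAndMeasure <- function(positions, bathy, graph = NULL) {
  stopifnot(nrow(positions) >= 2)
  needGraph <- FALSE
  segs <- vector("list", nrow(positions) - 1)
  for (i in seq_len(nrow(positions) - 1)) {
    p1 <- c(positions$lon[i], positions$lat[i])
    p2 <- c(positions$lon[i + 1], positions$lat[i + 1])
    if (!segmentClear(p1, p2, bathy)) needGraph <- TRUE
  }
  if (needGraph && is.null(graph)) graph <- waterGraph(bathy)
  out <- list()
  seg_km <- numeric(nrow(positions) - 1)
  for (i in seq_len(nrow(positions) - 1)) {
    p1 <- c(positions$lon[i], positions$lat[i])
    p2 <- c(positions$lon[i + 1], positions$lat[i + 1])
    lcp <- leastCostPath(p1, p2, bathy, graph)
    seg_km[i] <- lcp$length_km
    t1 <- as.numeric(positions$date[i])
    t2 <- as.numeric(positions$date[i + 1])
    out[[length(out) + 1]] <- data.frame(
      time = t1, lon = p1[1], lat = p1[2], interpolated = FALSE)
    if (nrow(lcp$path) > 2) {
      mid <- lcp$path[-c(1, nrow(lcp$path)), , drop = FALSE]
      d <- gcDistKm(lcp$path[-nrow(lcp$path), 1], lcp$path[-nrow(lcp$path), 2],
                    lcp$path[-1, 1], lcp$path[-1, 2])
      frac <- cumsum(d)[-length(d)] / sum(d)
      out[[length(out) + 1]] <- data.frame(
        time = t1 + frac * (t2 - t1), lon = mid[, 1], lat = mid[, 2],
        interpolated = TRUE)
    }
  }
  n <- nrow(positions)
  out[[length(out) + 1]] <- data.frame(
    time = as.numeric(positions$date[n]), lon = positions$lon[n],
    lat = positions$lat[n], interpolated = FALSE)
  pts <- do.call(rbind, out)
  rownames(pts) <- NULL
  res <- list(positions = pts, segment_km = seg_km, total_km = sum(seg_km))
  class(res) <- "CorrectedTrack"
  res
}
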