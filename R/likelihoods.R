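## All layers are non-negative weight matrices on the bathymetry grid,
## land-masked, and renormalised to max 1 (the HMM posterior is invariant to
## per-day scale). A layer that is degenerate (all zero after masking) is
## signalled by returning NULL so the caller can drop it with a warning.

maskAndScale <- function(w, water) {
  w[!water] <- 0
  w[!is.finite(w)] <- 0
  mx <- max(w)
  if (mx <= 0) return(NULL)
  w / mx
}

#' Light-based longitude likelihood layer
#'
#' Gaussian density in longitude around the tag's light-based estimate,
#' constant across latitude (light geolocation on short deployments resolves
#' longitude only).
#'
#' @param lon_estimate daily longitude estimate, degrees
#' @param sd its standard deviation, degrees (> 0)
#' @param bathy bathymetry [RasterGrid-class] (geometry + land mask)
#' @return weight matrix (max 1) or NULL when the estimate lies more than
#'   3 sd outside the grid (layer dropped with a warning)
#' @export
lightLongitudeLayer <- function(lon_estimate, sd, bathy) {
  stopifnot(sd > 0)
  if (lon_estimate < min(bathy@lon) - 3 * sd ||
      lon_estimate > max(bathy@lon) + 3 * sd) {
    warning("light longitude estimate beyond grid +- 3 sd: layer dropped")
    return(NULL)
  }
  w <- matrix(dnorm(bathy@lon, lon_estimate, sd), nrow = length(bathy@lat),
              ncol = length(bathy@lon), byrow = TRUE)
  maskAndScale(w, waterMask(bathy))
}

## integrated Gaussian likelihood of an observed [lo, hi] interval against a
## field value f with error sd: integral of N(f, sd) over [lo - sd, hi + sd]
intGauss <- function(f, lo, hi, sd) {
  pnorm((hi + sd - f) / sd) - pnorm((lo - sd - f) / sd)
}

#' SST likelihood layer
#'
#' Integrated-Gaussian likelihood of the tag's daily SST range against the
#' SST field: weight(x) = integral over [min - tol, max + tol] of a Gaussian
#' centred at field(x) with sd = tol.
#'
#' @param sst_min,sst_max daily range of tag SST samples, degC
#' @param sst_field matrix of field SST on the grid
#' @param bathy bathymetry grid
#' @param tolerance SST error sd, degC (default 0.5)
#' @return weight matrix (max 1) or NULL if degenerate
#' @export
sstLayer <- function(sst_min, sst_max, sst_field, bathy, tolerance = 0.5) {
  stopifnot(tolerance > 0, sst_min <= sst_max)
  w <- intGauss(sst_field, sst_min, sst_max, tolerance)
  maskAndScale(w, waterMask(bathy))
}

#' Depth-temperature profile likelihood layer
#'
#' Product over profile levels of the integrated Gaussian likelihood of the
#' tag's [min, max] temperature at that level against the field, computed in
#' log space and renormalised to max 1. Profile levels deeper than the
#' field's deepest level are truncated with a warning.
#'
#' @param profile data.frame(depth, tmin, tmax)
#' @param temp_fields named list of field matrices, names = depth levels (m)
#' @param bathy bathymetry grid
#' @param sd per-level error sd, degC (default 1)
#' @return weight matrix (max 1) or NULL if degenerate
#' @export
profileLayer <- function(profile, temp_fields, bathy, sd = 1) {
  stopifnot(nrow(profile) >= 2)
  levels <- as.numeric(names(temp_fields))
  if (max(profile$depth) > max(levels)) {
    warning("profile deeper than field levels: truncating")
    profile <- profile[profile$depth <= max(levels), , drop = FALSE]
    if (nrow(profile) == 0) return(NULL)
  }
  lw <- 0
  for (i in seq_len(nrow(profile))) {
    lev <- levels[which.min(abs(levels - profile$depth[i]))]
    f <- temp_fields[[as.character(lev)]]
    lw <- lw + log(pmax(intGauss(f, profile$tmin[i], profile$tmax[i], sd),
                        1e-300))
  }
  w <- exp(lw - max(lw))
  maskAndScale(w, waterMask(bathy))
}

## ocean heat content (J m^-2) above the iso_temp isotherm from a set of
## (depth, temp) levels: rho * c_p * sum (T - iso) dz over levels with
## T >= iso_temp, with layer thicknesses from consecutive level midpoints
ohcIntegral <- function(depths, temps, iso_temp) {
  rho <- 1025; cp <- 3993
  edge <- c(depths[1], (depths[-1] + depths[-length(depths)]) / 2,
            depths[length(depths)])
  dz <- diff(edge)
  keep <- temps >= iso_temp
  rho * cp * sum((temps[keep] - iso_temp) * dz[keep])
}

#' Ocean-heat-content likelihood layer
#'
#' Integrated ocean heat content above a reference isotherm, compared
#' between the tag profile and the field: weight(x) is the Gaussian
#' likelihood of the tag-derived OHC against the field OHC, with sd a fixed
#' fraction of the field OHC range.
#'
#' @param profile data.frame(depth, tmin, tmax); midpoint temperature is used
#' @param temp_fields named list of field matrices by level (m)
#' @param bathy bathymetry grid
#' @param iso_temp reference isotherm, degC (must be below the profile max)
#' @param sd_fraction sd as a fraction of the field OHC range (default 0.1)
#' @return weight matrix (max 1) or NULL when the isotherm is not crossed
#' @export
ohcLayer <- function(profile, temp_fields, bathy, iso_temp,
                     sd_fraction = 0.1) {
  tmid <- (profile$tmin + profile$tmax) / 2
  if (iso_temp >= max(tmid)) stop("iso_temp must be below the profile maximum")
  tag_ohc <- ohcIntegral(profile$depth, tmid, iso_temp)
  levels <- as.numeric(names(temp_fields))
  use <- levels <= max(profile$depth) + 1e-9
  levels <- levels[use]
  flds <- temp_fields[use]
  if (length(levels) < 2) return(NULL)
  edge <- c(levels[1], (levels[-1] + levels[-length(levels)]) / 2,
            levels[length(levels)])
  dz <- diff(edge)
  ohc <- 0
  for (i in seq_along(levels)) {
    excess <- pmax(flds[[i]] - iso_temp, 0)
    ohc <- ohc + 1025 * 3993 * excess * dz[i]
  }
  rng <- diff(range(ohc[waterMask(bathy)]))
  if (rng <= 0) return(NULL)
  w <- dnorm(tag_ohc, mean = ohc, sd = sd_fraction * rng)
  maskAndScale(w, waterMask(bathy))
}

#' Two-sided bathymetric likelihood layer
#'
#' The demersal assumption: the fish touches the seafloor at least once a
#' day, so on days with a maximum-depth record only cells whose seafloor
#' depth lies within `band` metres of that record are admissible (two-sided
#' binary layer). On days without depth data the layer admits all water
#' shallower than the conservative `cap`. If the two-sided band is empty
#' (depth exceeding all seafloor), the layer falls back to the one-sided
#' rule seafloor >= max_depth - band, with a warning.
#'
#' @param day_max_depth daily maximum depth (m) or NA/NULL when absent
#' @param bathy bathymetry grid
#' @param band two-sided band, m (default 10)
#' @param cap fallback seafloor cap, m (default 300)
#' @return binary weight matrix
#' @export
bathyLayer <- function(day_max_depth, bathy, band = 10, cap = 300) {
  stopifnot(band > 0)
  sf <- bathy@values
  water <- waterMask(bathy)
  if (is.null(day_max_depth) || is.na(day_max_depth)) {
    w <- (sf > 0 & sf <= cap) * 1
    return(maskAndScale(w, water))
  }
  w <- (abs(sf - day_max_depth) <= band) * 1
  w[!water] <- 0
  if (!any(w > 0)) {
    warning("two-sided bathymetric band empty: falling back to one-sided rule")
    w <- (sf >= day_max_depth - band) * 1
  }
  maskAndScale(w, water)
}

#' Known-location likelihood layer
#'
#' Gaussian bump centred on a tagging, pop-up or acoustic centre-of-activity
#' position. Positions on land are snapped to the nearest water cell with a
#' warning. The bump sd is one grid cell for tagging/pop-up locations and
#' max(one cell, the acoustic detection range) for COAs. Known-location
#' layers mask (replace the support of) other layers for their day: see
#' [combineDay()].
#'
#' @param lon,lat the known position
#' @param kind `"tagging"`, `"popup"` or `"coa"`
#' @param bathy bathymetry grid
#' @param detection_range_m acoustic detection range for COA sd (default 800)
#' @return weight matrix (max 1)
#' @export
knownLocationLayer <- function(lon, lat, kind = c("tagging", "popup", "coa"),
                               bathy, detection_range_m = 800) {
  kind <- match.arg(kind)
  ci <- cellIndex(bathy, lon, lat)
  if (bathy@values[ci["row"], ci["col"]] <= 0) {
    nc <- nearestWaterCell(bathy, lon, lat)
    warning(sprintf("known %s location on land: snapped %.1f km to water",
                    kind, nc$dist_km))
    lon <- nc$lon; lat <- nc$lat
  }
  res <- cellSizeDeg(bathy)
  cell_km <- res * 111.32 * cos(mean(bathy@lat) * pi / 180)
  sd_km <- if (kind == "coa") max(cell_km, detection_range_m / 1000) else cell_km
  cc <- cellCentres(bathy)
  d <- gcDistKm(lon, lat, cc$lon, cc$lat)
  w <- matrix(dnorm(d, 0, sd_km), nrow = nrow(cc$lon))
  maskAndScale(w, waterMask(bathy))
}

#' Pop-up drift buffer layer
#'
#' Tags that do not transmit immediately after surfacing drift before their
#' first Argos fix. The buffer is a binary great-circle disk around the
#' first transmitted position with radius = surface gap (days) x drift
#' speed, used as the final day's layer (or to mask other final-day layers).
#' A zero gap reduces to the single cell containing the transmit position.
#'
#' @param lon,lat first transmitted position
#' @param surface_gap_days days between surfacing and first transmission
#' @param bathy bathymetry grid
#' @param drift_speed_km_day drift speed (default 20 km/day)
#' @return binary weight matrix
#' @export
popupDriftBuffer <- function(lon, lat, surface_gap_days, bathy,
                             drift_speed_km_day = 20) {
  stopifnot(surface_gap_days >= 0)
  radius_km <- surface_gap_days * drift_speed_km_day
  cc <- cellCentres(bathy)
  d <- gcDistKm(lon, lat, cc$lon, cc$lat)
  diag_km <- gcDistKm(min(bathy@lon), min(bathy@lat),
                      max(bathy@lon), max(bathy@lat))
  if (radius_km >= diag_km) {
    warning("drift radius exceeds the grid: uniform water layer")
    return(maskAndScale(matrix(1, nrow(cc$lon), ncol(cc$lon)),
                        waterMask(bathy)))
  }
  w <- matrix(as.numeric(d <= radius_km), nrow = nrow(cc$lon))
  if (!any(w > 0)) {  # radius below cell size: admit the containing cell
    ci <- cellIndex(bathy, lon, lat)
    w[ci["row"], ci["col"]] <- 1
  }
  maskAndScale(w, waterMask(bathy))
}

#' Build the full likelihood stack for a tag
#'
#' Assembles one named layer list per deployment day from the tag's
#' observation streams, the environment fields, acoustic COA known
#' locations, and the tagging / pop-up constraints (including the pop-up
#' drift buffer on the final day). Days with no usable stream carry an empty
#' list (treated as uniform over water downstream).
#'
#' @param series a [TagSeries-class]
#' @param env an [EnvironmentStack-class]
#' @param coas optional data.frame(date, lon, lat) of daily COA positions
#' @param tagging,popup optional c(lon, lat) release / first-transmit
#'   positions
#' @param surface_gap_days gap for the pop-up drift buffer (default 0)
#' @param config a [runConfig()]
#' @param sst_sd,profile_sd,ohc_iso,ohc_sd_fraction layer error constants
#' @param sources which layer codes to build (subset of L,S,H,O,B,K)
#' @return a [LikelihoodStack-class]
#' @export
buildLikelihoodStack <- function(series, env, coas = NULL, tagging = NULL,
                                 popup = NULL, surface_gap_days = 0,
                                 config = runConfig(), sst_sd = 0.5,
                                 profile_sd = 1, ohc_iso = NULL,
                                 ohc_sd_fraction = 0.1,
                                 sources = c("L", "S", "H", "O", "B", "K")) {
  bathy <- env@bathymetry
  dates <- series@dates
  n <- length(dates)
  fieldsFor <- function(date) {
    fl <- lapply(env@depthLevels, function(z) env@tempFun(date, z))
    names(fl) <- env@depthLevels
    fl
  }
  layers <- vector("list", n)
  for (t in seq_len(n)) {
    day <- list()
    if ("L" %in% sources && !is.na(series@lightLon[t])) {
      l <- lightLongitudeLayer(series@lightLon[t], series@lightLonSd, bathy)
      if (!is.null(l)) day$L <- l
    }
    if ("S" %in% sources && length(series@sstSamples[[t]])) {
      f <- env@sstFun(dates[t])
      l <- sstLayer(min(series@sstSamples[[t]]), max(series@sstSamples[[t]]),
                    f, bathy, sst_sd)
      if (!is.null(l)) day$S <- l
    }
    prof <- series@profiles[[t]]
    if (!is.null(prof) && nrow(prof) >= 2) {
      tf <- fieldsFor(dates[t])
      if ("H" %in% sources) {
        l <- profileLayer(prof, tf, bathy, profile_sd)
        if (!is.null(l)) day$H <- l
      }
      if ("O" %in% sources) {
        iso <- if (is.null(ohc_iso)) min((prof$tmin + prof$tmax) / 2) - 1
               else ohc_iso
        l <- tryCatch(ohcLayer(prof, tf, bathy, iso, ohc_sd_fraction),
                      error = function(e) NULL)
        if (!is.null(l)) day$O <- l
      }
    }
    if ("B" %in% sources) {
      l <- bathyLayer(series@maxDepth[t], bathy, config$depth_band_m,
                      config$max_seafloor_m)
      if (!is.null(l)) day$B <- l
    }
    if ("K" %in% sources) {
      if (!is.null(coas)) {
        hit <- which(coas$date == dates[t])
        if (length(hit))
          day$K <- knownLocationLayer(coas$lon[hit[1]], coas$lat[hit[1]],
                                      "coa", bathy)
      }
      if (t == 1 && !is.null(tagging))
        day$K <- knownLocationLayer(tagging[1], tagging[2], "tagging", bathy)
      if (t == n && !is.null(popup)) {
        day$K <- if (surface_gap_days > 0)
          popupDriftBuffer(popup[1], popup[2], surface_gap_days, bathy,
                           config$drift_speed_km_day)
        else knownLocationLayer(popup[1], popup[2], "popup", bathy)
      }
    }
    layers[[t]] <- day
  }
  new("LikelihoodStack", grid = bathy, dates = dates, layers = layers)
}

#' Combine one day's layers into a single surface
#'
#' Pointwise product of the day's layers, except that a known-location layer
#' (`K`) replaces the support of the others: they are first masked to the
#' smallest set of top-weight K cells holding 99% of the K mass, then
#' multiplied by K. A day with no layers returns the uniform water surface.
#' A degenerate product falls back through (K alone, then uniform water) and
#' reports which fallback applied.
#'
#' @param day named list of layer matrices
#' @param water logical water mask
#' @return list(surface, degenerate) -- surface has max 1
#' @export
combineDay <- function(day, water) {
  uniform <- matrix(as.numeric(water), nrow = nrow(water))
  if (length(day) == 0) return(list(surface = uniform, degenerate = FALSE))
  K <- day$K
  others <- day[setdiff(names(day), "K")]
  if (!is.null(K)) {
    o <- order(K, decreasing = TRUE)
    cum <- cumsum(K[o]) / sum(K)
    keep <- o[seq_len(which(cum >= 0.99)[1])]
    region <- matrix(FALSE, nrow(K), ncol(K))
    region[keep] <- TRUE
    others <- lapply(others, function(m) { m[!region] <- 0; m })
  }
  w <- Reduce(`*`, c(others, list(if (is.null(K)) 1 else K)))
  if (is.matrix(w)) w[!water] <- 0
  if (!is.matrix(w) || max(w) <= 0) {
    if (!is.null(K)) return(list(surface = K, degenerate = TRUE))
    return(list(surface = uniform, degenerate = TRUE))
  }
  list(surface = w / max(w), degenerate = FALSE)
}
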