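#' Specification of the synthetic coastal shelf world
#'
#' Bundles every constant of the synthetic world: domain and grid, coastline
#' shape, shelf slope, seasonal SST cycle, vertical temperature structure,
#' receiver placement, observation-model constants (detection range,
#' transmission delay, tag sampling rate, sensor noise/quantisation) and the
#' two-state correlated-random-walk movement parameters. Defaults emulate a
#' temperate eastern-boundary shelf: SST 13-23 degC over the year, shelf
#' reaching ~300 m at the offshore edge, ~800 m acoustic detection range,
#' 60-120 s transmission delay, 0.05 degC / 0.5 m sensor resolution, and
#' PSAT summary streams available on 85% (light), 5% (SST), 85% (profile)
#' and 100% (max depth) of days.
#'
#' @param lon_range,lat_range domain bounds, degrees
#' @param resolution_deg grid cell size
#' @param coast_base_lat,coast_amp_deg,coast_wavelength_deg coastline shape:
#'   land lies north of `coast_base_lat + coast_amp_deg *
#'   sin(2*pi*(lon - lon_range[1]) / coast_wavelength_deg)`
#' @param shelf_slope_m_per_km linear seaward deepening of the seafloor
#' @param sst_mean,sst_amplitude,sst_peak_doy seasonal SST cycle (degC, degC,
#'   day of year of the maximum)
#' @param sst_lat_gradient,sst_lon_gradient degC per degree northward /
#'   eastward
#' @param lapse_rate_c_per_m,lapse_noise_sd vertical temperature decrease and
#'   optional noise on the temperature-at-depth field
#' @param n_receivers,receiver_offshore_deg coastal receiver line placement
#' @param detection_halfrange_m,detection_scale_m logistic detection curve:
#'   p(d) = 1 / (1 + exp((d - halfrange) / scale))
#' @param transmit_delay_s min/max uniform transmitter delay
#' @param sampling_seconds archival sampling interval
#' @param light_lon_sd,light_frac light-based longitude noise sd (deg) and
#'   fraction of days carrying an estimate
#' @param sst_frac,pdt_frac,depth_frac per-day availability of SST samples,
#'   depth-temperature profiles and maximum depth
#' @param depth_noise_sd_m depth sensor noise (before 0.5 m quantisation)
#' @param seafloor_offset_sd_m sd of the gap between daily max depth and the
#'   local seafloor (the fish touches bottom daily)
#' @param transit_step_km,transit_rho,ar_step_km,ar_rho mean daily step (km)
#'   and wrapped-Cauchy turning concentration for the transiting and
#'   area-restricted states
#' @param step_shape gamma shape of the daily step distribution
#' @param accel_base_mean_g,accel_base_sd_g baseline acceleration magnitude
#' @param burst_rate_per_day,burst_magnitude_g,burst_len_samples,
#'   burst_monthly burst-event injection: Poisson daily rate scaled by a
#'   12-value monthly curve
#' @param start_date first track day
#' @param seed integer seed; the whole world and every observation stream are
#'   reproducible from it
#' @return a list of class `WorldSpec`
#' @export
worldSpec <- function(lon_range = c(-10, -7), lat_range = c(36, 38),
                      resolution_deg = 0.03,
                      coast_base_lat = 37.65, coast_amp_deg = 0.25,
                      coast_wavelength_deg = 1.2,
                      shelf_slope_m_per_km = 1.5,
                      sst_mean = 18, sst_amplitude = 5, sst_peak_doy = 227,
                      sst_lat_gradient = -1.0, sst_lon_gradient = 0.3,
                      lapse_rate_c_per_m = 0.05, lapse_noise_sd = 0,
                      n_receivers = 40, receiver_offshore_deg = 0.08,
                      detection_halfrange_m = 800, detection_scale_m = 150,
                      transmit_delay_s = c(60, 120), sampling_seconds = 5,
                      light_lon_sd = 0.3, light_frac = 0.85,
                      sst_frac = 0.05, pdt_frac = 0.85, depth_frac = 1,
                      depth_noise_sd_m = 0.5, seafloor_offset_sd_m = 2,
                      transit_step_km = 25, transit_rho = 0.8,
                      ar_step_km = 4, ar_rho = 0.1, step_shape = 4,
                      accel_base_mean_g = 1, accel_base_sd_g = 0.08,
                      burst_rate_per_day = 30, burst_magnitude_g = 1,
                      burst_len_samples = 3,
                      burst_monthly = 1 + 0.8 * cos(2 * pi * (1:12 - 7) / 12),
                      start_date = as.Date("2019-01-01"), seed = 1L) {
  spec <- as.list(environment())
  if (spec$resolution_deg <= 0) stop("resolution must be positive")
  if (spec$detection_halfrange_m <= 0) stop("detection half-range must be positive")
  sds <- c(spec$light_lon_sd, spec$depth_noise_sd_m, spec$lapse_noise_sd)
  if (any(sds < 0)) stop("noise sds must be >= 0")
  if (length(spec$burst_monthly) != 12) stop("burst_monthly needs 12 values")
  class(spec) <- "WorldSpec"
  spec
}

## latitude of the coastline at a given longitude
coastLat <- function(spec, lon) {
  spec$coast_base_lat + spec$coast_amp_deg *
    sin(2 * pi * (lon - spec$lon_range[1]) / spec$coast_wavelength_deg)
}

#' Build the synthetic world
#'
#' Constructs the bathymetry (land margin along the sinuous northern
#' coastline, seafloor deepening linearly offshore), the seasonal SST and
#' temperature-at-depth fields, and a line of acoustic receivers on water
#' cells just off the coast. Fully deterministic given `spec$seed`.
#'
#' @param spec a [worldSpec()]
#' @return list with `env` ([EnvironmentStack-class]), `receivers`
#'   (data.frame as [readReceivers()]) and `spec`
#' @export
makeWorld <- function(spec) {
  res <- spec$resolution_deg
  lon <- seq(spec$lon_range[1] + res / 2, spec$lon_range[2] - res / 2, by = res)
  lat <- seq(spec$lat_range[1] + res / 2, spec$lat_range[2] - res / 2, by = res)
  cl <- coastLat(spec, lon)
  if (max(cl) >= max(lat) - res || min(cl) <= min(lat) + res)
    stop("domain too small to contain both coast and shelf")
  distkm <- outer(-lat, rep(1, length(lon))) +
    matrix(cl, nrow = length(lat), ncol = length(lon), byrow = TRUE)
  distkm <- distkm * 111.32  # degrees of latitude offshore -> km
  depth <- spec$shelf_slope_m_per_km * distkm
  depth[depth <= 0] <- -10  # land margin
  bathy <- rasterGrid(lon, lat, depth)

  latm <- matrix(lat, nrow = length(lat), ncol = length(lon))
  lonm <- matrix(lon, nrow = length(lat), ncol = length(lon), byrow = TRUE)
  sstFun <- local({
    spec_ <- spec; latm_ <- latm; lonm_ <- lonm
    function(date) {
      doy <- as.integer(format(as.Date(date), "%j"))
      spec_$sst_mean +
        spec_$sst_amplitude * cos(2 * pi * (doy - spec_$sst_peak_doy) / 365.25) +
        spec_$sst_lat_gradient * (latm_ - mean(spec_$lat_range)) +
        spec_$sst_lon_gradient * (lonm_ - mean(spec_$lon_range))
    }
  })
  tempFun <- local({
    spec_ <- spec; sstFun_ <- sstFun
    function(date, depth_m) {
      f <- sstFun_(date) - spec_$lapse_rate_c_per_m * depth_m
      if (spec_$lapse_noise_sd > 0) {
        # reproducible per (date, level) perturbation field
        set.seed(spec_$seed + as.integer(as.Date(date)) * 997L +
                   as.integer(round(depth_m)))
        f <- f + matrix(rnorm(length(f), 0, spec_$lapse_noise_sd),
                        nrow = nrow(f))
      }
      f
    }
  })
  levels <- c(0, 5, 10, 20, 30, 50, 75, 100, 125, 150, 200, 250, 300)
  env <- new("EnvironmentStack", bathymetry = bathy, sstFun = sstFun,
             tempFun = tempFun, depthLevels = levels)

  set.seed(spec$seed)
  margin <- diff(spec$lon_range) * 0.05
  rlon <- seq(spec$lon_range[1] + margin, spec$lon_range[2] - margin,
              length.out = spec$n_receivers)
  recs <- lapply(seq_along(rlon), function(i) {
    target_lat <- coastLat(spec, rlon[i]) - spec$receiver_offshore_deg
    nc <- nearestWaterCell(bathy, rlon[i], target_lat)
    data.frame(receiver_id = sprintf("R%02d", i), lon = nc$lon, lat = nc$lat,
               site_label = sprintf("site%02d", 1 + (i - 1) %/% 5),
               active_from = spec$start_date - 30,
               active_to = spec$start_date + 3000)
  })
  receivers <- do.call(rbind, recs)
  list(env = env, receivers = receivers, spec = spec)
}

## wrapped-Cauchy turning angle draw, concentration rho around 0
rwrappedcauchy <- function(n, rho) {
  if (rho <= 0) return(runif(n, -pi, pi))
  # inverse-CDF sampling via the standard relation with the Cauchy
  ang <- 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (runif(n) - 0.5)))
  ang
}

#' Simulate a ground-truth fish track
#'
#' Two-state correlated random walk on the water cells of the synthetic
#' shelf: the transiting state draws long gamma-distributed daily steps with
#' strong directional persistence, the area-restricted state short steps
#' with weak persistence. Proposals landing on land or outside the domain
#' are rejected and redrawn (with gradual step shrinkage to escape tight
#' coves). The daily maximum depth is the local seafloor depth minus
#' |N(0, seafloor_offset_sd_m)|: the fish touches bottom every day.
#'
#' @param world output of [makeWorld()]
#' @param n_days track length
#' @param state_schedule character vector (`"transiting"` /
#'   `"area-restricted"`) of length `n_days`, or NULL for a persistent
#'   two-state Markov schedule (stay probability 0.95)
#' @param start c(lon, lat) on water; default mid-domain on the shelf
#' @param seed integer; default `world$spec$seed`
#' @return data.frame(date, lon, lat, state, max_depth, seafloor) of class
#'   `TruthTrack`
#' @export
simulateTrack <- function(world, n_days, state_schedule = NULL, start = NULL,
                          seed = world$spec$seed) {
  spec <- world$spec
  bathy <- world$env@bathymetry
  set.seed(seed)
  if (is.null(start)) {
    lon0 <- mean(spec$lon_range)
    start <- c(lon0, coastLat(spec, lon0) - 0.3)
  }
  ci <- cellIndex(bathy, start[1], start[2])
  if (bathy@values[ci["row"], ci["col"]] <= 0)
    stop("start position is on land")
  if (is.null(state_schedule)) {
    state_schedule <- character(n_days)
    state_schedule[1] <- sample(c("transiting", "area-restricted"), 1)
    for (t in seq_len(n_days)[-1])
      state_schedule[t] <- if (runif(1) < 0.95) state_schedule[t - 1] else
        setdiff(c("transiting", "area-restricted"), state_schedule[t - 1])
  }
  stopifnot(length(state_schedule) == n_days)
  maxstep <- spec$transit_step_km  # speed-bound cap applied below
  cap_km <- 86.4 * 2  # hard daily bound at 2 m/s
  lon <- lat <- numeric(n_days)
  lon[1] <- start[1]; lat[1] <- start[2]
  heading <- runif(1, 0, 360)
  onWater <- function(p) {
    if (p[1] < min(bathy@lon) || p[1] > max(bathy@lon) ||
        p[2] < min(bathy@lat) || p[2] > max(bathy@lat)) return(FALSE)
    ci <- cellIndex(bathy, p[1], p[2])
    bathy@values[ci["row"], ci["col"]] > 0
  }
  for (t in seq_len(n_days)[-1]) {
    st <- state_schedule[t]
    meanstep <- if (st == "transiting") spec$transit_step_km else spec$ar_step_km
    rho <- if (st == "transiting") spec$transit_rho else spec$ar_rho
    shrink <- 1
    for (try in 1:500) {
      step <- min(rgamma(1, shape = spec$step_shape,
                         scale = meanstep * shrink / spec$step_shape), cap_km)
      turn <- rwrappedcauchy(1, rho) * 180 / pi
      hd <- (heading + turn) %% 360
      p <- geosphere::destPoint(c(lon[t - 1], lat[t - 1]), hd, step * 1000)
      if (onWater(p)) { lon[t] <- p[1]; lat[t] <- p[2]; heading <- hd; break }
      if (try %% 50 == 0) shrink <- shrink * 0.7
      if (try == 500) { lon[t] <- lon[t - 1]; lat[t] <- lat[t - 1] }
    }
  }
  seafloor <- vapply(seq_len(n_days), function(t) {
    ci <- cellIndex(bathy, lon[t], lat[t])
    bathy@values[ci["row"], ci["col"]]
  }, numeric(1))
  max_depth <- pmax(seafloor - abs(rnorm(n_days, 0, spec$seafloor_offset_sd_m)),
                    0.5)
  out <- data.frame(date = spec$start_date + seq_len(n_days) - 1,
                    lon = lon, lat = lat, state = state_schedule,
                    max_depth = max_depth, seafloor = seafloor)
  class(out) <- c("TruthTrack", "data.frame")
  out
}

#' Observe a track through a PSAT
#'
#' Applies the tag observation model to a ground-truth track: daily maximum
#' depth with sensor noise quantised to 0.5 m, SST samples with 0.05 degC
#' quantisation, light-based longitude estimates on a configurable fraction
#' of days, depth-temperature profiles down to the day's maximum depth, and
#' (optionally) a high-rate acceleration-magnitude archive with
#' Poisson-injected burst events following the monthly rate curve. Burst
#' ground truth is carried in the archival `is_burst` column.
#'
#' @param track a `TruthTrack` from [simulateTrack()]
#' @param world output of [makeWorld()]
#' @param accel generate the high-rate archival record (costly)
#' @param seed integer; default derived from the world seed
#' @return a [TagSeries-class]
#' @export
observePsat <- function(track, world, accel = FALSE,
                        seed = world$spec$seed + 1L) {
  spec <- world$spec
  env <- world$env
  set.seed(seed)
  n <- nrow(track)
  maxDepth <- rep(NA_real_, n)
  has_depth <- runif(n) < spec$depth_frac
  maxDepth[has_depth] <- round((track$max_depth[has_depth] +
    rnorm(sum(has_depth), 0, spec$depth_noise_sd_m)) / 0.5) * 0.5
  maxDepth[!is.na(maxDepth) & maxDepth < 0] <- 0

  sstSamples <- vector("list", n)
  has_sst <- runif(n) < spec$sst_frac
  for (t in which(has_sst)) {
    f <- env@sstFun(track$date[t])
    ci <- cellIndex(env@bathymetry, track$lon[t], track$lat[t])
    sstSamples[[t]] <- round((f[ci["row"], ci["col"]] +
      rnorm(3, 0, 0.1)) / 0.05) * 0.05
  }

  lightLon <- rep(NA_real_, n)
  has_light <- runif(n) < spec$light_frac
  lightLon[has_light] <- track$lon[has_light] +
    rnorm(sum(has_light), 0, spec$light_lon_sd)

  profiles <- vector("list", n)
  has_pdt <- runif(n) < spec$pdt_frac
  for (t in which(has_pdt)) {
    lv <- env@depthLevels[env@depthLevels <= track$max_depth[t]]
    if (length(lv) < 2) next
    tm <- vapply(lv, function(z) {
      f <- env@tempFun(track$date[t], z)
      ci <- cellIndex(env@bathymetry, track$lon[t], track$lat[t])
      f[ci["row"], ci["col"]]
    }, numeric(1))
    profiles[[t]] <- data.frame(depth = lv,
                                tmin = round((tm - 0.1) / 0.05) * 0.05,
                                tmax = round((tm + 0.1) / 0.05) * 0.05)
  }

  archival <- data.frame(time = as.POSIXct(character(), tz = "UTC"),
                         depth = numeric(), temp = numeric(), ma = numeric(),
                         is_burst = logical())
  if (accel) {
    per_day <- floor(86400 / spec$sampling_seconds)
    archival <- do.call(rbind, lapply(seq_len(n), function(t) {
      tt <- as.POSIXct(paste(track$date[t], "00:00:00"), tz = "UTC") +
        seq_len(per_day) * spec$sampling_seconds
      frac <- seq_len(per_day) / per_day
      depth <- pmax(0.5, track$max_depth[t] *
                      (0.55 + 0.45 * sin(2 * pi * (frac - 0.25))))
      f <- env@sstFun(track$date[t])
      ci <- cellIndex(env@bathymetry, track$lon[t], track$lat[t])
      temp <- f[ci["row"], ci["col"]] - spec$lapse_rate_c_per_m * depth
      ma <- abs(rnorm(per_day, spec$accel_base_mean_g, spec$accel_base_sd_g))
      is_burst <- logical(per_day)
      mon <- as.integer(format(track$date[t], "%m"))
      nb <- rpois(1, spec$burst_rate_per_day * spec$burst_monthly[mon])
      if (nb > 0) {
        starts <- sample.int(per_day - spec$burst_len_samples, nb, replace = TRUE)
        for (s in starts) {
          idx <- s:(s + spec$burst_len_samples - 1)
          ma[idx] <- ma[idx] + spec$burst_magnitude_g
          is_burst[idx] <- TRUE
        }
      }
      data.frame(time = tt, depth = round(depth / 0.5) * 0.5,
                 temp = round(temp / 0.05) * 0.05, ma = ma,
                 is_burst = is_burst)
    }))
  }
  new("TagSeries", tagId = "sim", dates = track$date, maxDepth = maxDepth,
      sstSamples = sstSamples, lightLon = lightLon,
      lightLonSd = spec$light_lon_sd, profiles = profiles,
      archival = archival)
}

#' Observe a track through the acoustic receiver array
#'
#' The tag transmits at uniform random delays in `transmit_delay_s`; every
#' transmission is detected by each receiver independently with logistic
#' probability `p(d) = 1 / (1 + exp((d - halfrange) / scale))` of the
#' transmitter-receiver distance. Detections are time-stamped at the
#' transmission time. Positions are taken at daily resolution.
#'
#' @param track a `TruthTrack`
#' @param receivers receiver metadata
#' @param spec the [worldSpec()]
#' @param seed integer; default derived from the spec seed
#' @return data.frame(tag_id, receiver_id, timestamp), time-sorted
#' @export
observeAcoustics <- function(track, receivers, spec, seed = spec$seed + 2L) {
  if (is.null(receivers) || nrow(receivers) == 0) {
    warning("no receivers: returning empty detection list")
    return(data.frame(tag_id = character(), receiver_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC")))
  }
  set.seed(seed)
  out <- vector("list", nrow(track))
  for (t in seq_len(nrow(track))) {
    dists <- geosphere::distHaversine(cbind(track$lon[t], track$lat[t]),
                                      cbind(receivers$lon, receivers$lat),
                                      r = 6371000)
    p <- 1 / (1 + exp((dists - spec$detection_halfrange_m) /
                        spec$detection_scale_m))
    near <- which(p > 1e-6)
    if (!length(near)) next
    delays <- runif(ceiling(86400 / spec$transmit_delay_s[1]),
                    spec$transmit_delay_s[1], spec$transmit_delay_s[2])
    times <- cumsum(delays)
    times <- times[times < 86400]
    day0 <- as.POSIXct(paste(track$date[t], "00:00:00"), tz = "UTC")
    dd <- lapply(near, function(r) {
      hit <- runif(length(times)) < p[r]
      if (!any(hit)) return(NULL)
      data.frame(tag_id = "sim", receiver_id = receivers$receiver_id[r],
                 timestamp = day0 + times[hit])
    })
    dd <- do.call(rbind, dd[!vapply(dd, is.null, logical(1))])
    out[[t]] <- dd
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(tag_id = character(), receiver_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC")))
  out <- out[order(out$tag_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
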