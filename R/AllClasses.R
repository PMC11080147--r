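#' RasterGrid: a regular lon/lat raster
#'
#' Minimal cell-centre-registered geographic raster. `values` is a matrix
#' with one row per latitude (ascending, south to north) and one column per
#' longitude (ascending, west to east). Used for bathymetry (metres, positive
#' down, land coded <= 0), temperature fields and likelihood surfaces.
#'
#' @slot lon numeric, cell-centre longitudes (ascending, regular spacing)
#' @slot lat numeric, cell-centre latitudes (ascending, regular spacing)
#' @slot values numeric matrix, `length(lat)` x `length(lon)`
#'
#' @export
setClass("RasterGrid",
  representation(lon = "numeric", lat = "numeric", values = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@values) != length(object@lat) ||
        ncol(object@values) != length(object@lon))
      msg <- c(msg, "values must be length(lat) x length(lon)")
    if (length(object@lon) > 1) {
      dl <- diff(object@lon)
      if (any(dl <= 0) || diff(range(dl)) > 1e-6)
        msg <- c(msg, "lon must be ascending and regular")
    }
    if (length(object@lat) > 1) {
      dl <- diff(object@lat)
      if (any(dl <= 0) || diff(range(dl)) > 1e-6)
        msg <- c(msg, "lat must be ascending and regular")
    }
    if (any(object@lon < -180 | object@lon > 180)) msg <- c(msg, "lon out of [-180, 180]")
    if (any(object@lat < -90 | object@lat > 90)) msg <- c(msg, "lat out of [-90, 90]")
    if (length(msg)) msg else TRUE
  })

#' EnvironmentStack: bathymetry plus date-indexed ocean fields on one grid
#'
#' Holds the static bathymetry and closures returning the sea-surface
#' temperature field and the temperature-at-depth field for any date, all on
#' the bathymetry grid. `sstFun(date)` returns a matrix conformable with the
#' bathymetry values; `tempFun(date, depth_m)` likewise for one standard
#' depth level.
#'
#' @slot bathymetry [RasterGrid-class]; seafloor depth m positive down, land <= 0
#' @slot sstFun function(date) -> matrix of SST degC
#' @slot tempFun function(date, depth) -> matrix of temperature degC at depth
#' @slot depthLevels numeric, standard depth levels (m) at which tempFun is valid
#'
#' @export
setClass("EnvironmentStack",
  representation(bathymetry = "RasterGrid", sstFun = "function",
                 tempFun = "function", depthLevels = "numeric"),
  validity = function(object) {
    if (!any(object@bathymetry@values > 0))
      return("bathymetry has no water cells")
    if (any(diff(object@depthLevels) <= 0))
      return("depthLevels must be strictly increasing")
    TRUE
  })

#' TagSeries: observation streams recovered from one PSAT
#'
#' Daily summary streams (maximum depth, SST samples, light-based longitude,
#' depth-temperature profiles) plus the optional high-rate archival record
#' (depth / temperature / acceleration magnitude).
#'
#' @slot tagId character identifier
#' @slot dates Date vector covering the deployment (gapless)
#' @slot maxDepth numeric, daily maximum depth m (NA where not reported)
#' @slot sstSamples list of numeric vectors (degC) per day, possibly empty
#' @slot lightLon numeric daily light-based longitude estimate (NA when absent)
#' @slot lightLonSd numeric, reported standard deviation of the estimate
#' @slot profiles list per day: data.frame(depth, tmin, tmax) or NULL
#' @slot archival data.frame(time, depth, temp, ma) or 0-row data.frame
#'
#' @export
setClass("TagSeries",
  representation(tagId = "character", dates = "Date", maxDepth = "numeric",
                 sstSamples = "list", lightLon = "numeric",
                 lightLonSd = "numeric", profiles = "list",
                 archival = "data.frame"),
  validity = function(object) {
    n <- length(object@dates)
    msg <- character()
    if (n > 1 && any(diff(as.integer(object@dates)) != 1))
      msg <- c(msg, "dates must be consecutive days")
    if (length(object@maxDepth) != n || length(object@lightLon) != n ||
        length(object@sstSamples) != n || length(object@profiles) != n)
      msg <- c(msg, "per-day slots must match length(dates)")
    if (any(object@maxDepth < 0, na.rm = TRUE))
      msg <- c(msg, "maxDepth must be >= 0")
    for (p in object@profiles)
      if (!is.null(p) && nrow(p) > 1 && any(diff(p$depth) <= 0)) {
        msg <- c(msg, "profile depths must be strictly increasing"); break
      }
    if (length(msg)) msg else TRUE
  })

#' LikelihoodStack: per-day observation likelihood rasters
#'
#' One entry per deployment day (gapless from release to pop-up). Each day
#' holds a named list of non-negative weight matrices on the common grid,
#' named by source code: `L` light longitude, `S` SST, `H` depth-temperature
#' profile, `O` ocean heat content, `B` bathymetry, `K` known location.
#' Days with no data carry an empty list and are treated as uniform over
#' water by the smoother.
#'
#' @slot grid [RasterGrid-class] the bathymetry grid (geometry + land mask source)
#' @slot dates Date vector, consecutive
#' @slot layers list (per date) of named lists of matrices
#'
#' @export
setClass("LikelihoodStack",
  representation(grid = "RasterGrid", dates = "Date", layers = "list"),
  validity = function(object) {
    if (length(object@dates) != length(object@layers))
      return("one layer list per date required")
    if (length(object@dates) > 1 && any(diff(as.integer(object@dates)) != 1))
      return("dates must be consecutive days")
    d <- dim(object@grid@values)
    for (day in object@layers) for (m in day) {
      if (!all(dim(m) == d)) return("layer dimensions must match the grid")
      if (any(!is.finite(m)) || any(m < 0)) return("layers must be finite and >= 0")
    }
    TRUE
  })

#' PosteriorTrack: smoothed daily position distributions and point estimates
#'
#' Result of [forwardBackward()]: per-day posterior rasters (states
#' marginalised), the per-day behaviour-state marginal, posterior-mean
#' positions, the model log-likelihood and the layer combination used.
#'
#' @slot grid [RasterGrid-class]
#' @slot dates Date vector
#' @slot posterior list of matrices, each summing to 1
#' @slot stateProb numeric, per-day probability of the migratory state
#' @slot positions data.frame(date, lon, lat) posterior-mean daily positions
#' @slot logLik numeric(1), forward-pass log-likelihood
#' @slot sources character, layer codes used (e.g. c("L","B"))
#' @slot flagged Date, days whose combined likelihood was degenerate
#'
#' @export
setClass("PosteriorTrack",
  representation(grid = "RasterGrid", dates = "Date", posterior = "list",
                 stateProb = "numeric", positions = "data.frame",
                 logLik = "numeric", sources = "character", flagged = "Date"),
  validity = function(object) {
    if (length(object@posterior) != length(object@dates))
      return("one posterior per date required")
    for (p in object@posterior)
      if (abs(sum(p) - 1) > 1e-6) return("each day's posterior must sum to 1")
    TRUE
  })

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d cells, res %.4f deg\n",
              nrow(v), ncol(v), cellSizeDeg(object)))
  cat(sprintf("  lon [%.3f, %.3f]  lat [%.3f, %.3f]\n",
              min(object@lon), max(object@lon), min(object@lat), max(object@lat)))
  cat(sprintf("  values [%.3g, %.3g]\n", min(v), max(v)))
})

setMethod("show", "EnvironmentStack", function(object) {
  cat("EnvironmentStack\n  bathymetry: ")
  show(object@bathymetry)
  cat(sprintf("  water cells: %d / %d\n", sum(object@bathymetry@values > 0),
              length(object@bathymetry@values)))
  cat(sprintf("  depth levels: %s m\n",
              paste(object@depthLevels, collapse = ", ")))
})

setMethod("show", "TagSeries", function(object) {
  cat(sprintf("TagSeries %s: %d days (%s to %s)\n", object@tagId,
              length(object@dates), min(object@dates), max(object@dates)))
  cat(sprintf("  max depth on %d days, light longitude on %d, profiles on %d\n",
              sum(!is.na(object@maxDepth)), sum(!is.na(object@lightLon)),
              sum(!vapply(object@profiles, is.null, logical(1)))))
  cat(sprintf("  archival samples: %d\n", nrow(object@archival)))
})

setMethod("show", "LikelihoodStack", function(object) {
  src <- sort(unique(unlist(lapply(object@layers, names))))
  cat(sprintf("LikelihoodStack: %d days, sources {%s}\n",
              length(object@dates), paste(src, collapse = ",")))
})

setMethod("show", "PosteriorTrack", function(object) {
  cat(sprintf("PosteriorTrack: %d days, sources {%s}, logLik %.2f\n",
              length(object@dates), paste(object@sources, collapse = ","),
              object@logLik))
})
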