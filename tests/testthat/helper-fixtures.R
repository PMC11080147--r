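## Shared fixture builders. Everything is generated in code; no binary data.

## a small flat-bottomed bathymetry raster centred near 37N, 8.5W
flatBathy <- function(nr = 10, nc = 10, depth = 50, res = 0.03,
                      lon0 = -8.5, lat0 = 37) {
  rasterGrid(lon0 + (seq_len(nc) - 1) * res,
             lat0 + (seq_len(nr) - 1) * res,
             matrix(depth, nr, nc))
}

## bathymetry from an explicit matrix (rows south to north)
bathyFrom <- function(m, res = 0.03, lon0 = -8.5, lat0 = 37) {
  rasterGrid(lon0 + (seq_len(ncol(m)) - 1) * res,
             lat0 + (seq_len(nrow(m)) - 1) * res, m)
}

## a small shared synthetic world (memoised per session)
tinyWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeWorld(worldSpec(seed = 42))
    cache
  }
})

## detections data.frame shorthand
det <- function(tag, receiver, times) {
  data.frame(tag_id = tag, receiver_id = receiver,
             timestamp = as.POSIXct(times, tz = "UTC"))
}

## receivers data.frame shorthand
recv <- function(id, lon, lat) {
  data.frame(receiver_id = id, lon = lon, lat = lat,
             site_label = "s", active_from = as.Date("2018-01-01"),
             active_to = as.Date("2025-01-01"))
}
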