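#' Construct a RasterGrid
#'
#' @param lon,lat cell-centre coordinate vectors (ascending, regular)
#' @param values matrix `length(lat)` x `length(lon)`
#' @return a [RasterGrid-class]
#' @export
rasterGrid <- function(lon, lat, values) {
  new("RasterGrid", lon = as.numeric(lon), lat = as.numeric(lat),
      values = values)
}

#' Accessors for RasterGrid geometry
#'
#' @param x a [RasterGrid-class]
#' @return `gridLon`/`gridLat` return cell-centre coordinates, `gridValues`
#'   the value matrix, `cellSizeDeg` the cell size in degrees.
#' @export
gridLon <- function(x) x@lon

#' @rdname gridLon
#' @export
gridLat <- function(x) x@lat

#' @rdname gridLon
#' @export
gridValues <- function(x) x@values

#' @rdname gridLon
#' @export
cellSizeDeg <- function(x) {
  if (length(x@lon) > 1) x@lon[2] - x@lon[1]
  else if (length(x@lat) > 1) x@lat[2] - x@lat[1]
  else stop("degenerate 1x1 grid has no defined cell size")
}

#' Water mask of a bathymetry raster
#'
#' Water is seafloor depth strictly positive (depth positive down, land
#' coded <= 0).
#'
#' @param bathy a [RasterGrid-class] of seafloor depths
#' @return logical matrix, TRUE on water cells
#' @export
waterMask <- function(bathy) bathy@values > 0

## row/col index of the cell whose centre is nearest to (lon, lat)
cellIndex <- function(grid, lon, lat) {
  i <- which.min(abs(grid@lat - lat))
  j <- which.min(abs(grid@lon - lon))
  c(row = i, col = j)
}

## lon/lat of cell centres for a matrix of the grid's shape, as two matrices
cellCentres <- function(grid) {
  list(lon = matrix(grid@lon, nrow = length(grid@lat),
                    ncol = length(grid@lon), byrow = TRUE),
       lat = matrix(grid@lat, nrow = length(grid@lat),
                    ncol = length(grid@lon)))
}

#' Great-circle distance in kilometres
#'
#' Haversine distance with the 6371 km mean Earth radius used throughout the
#' package.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorised)
#' @return distance in km
#' @export
gcDistKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(as.vector(lon1), as.vector(lat1)),
                           cbind(as.vector(lon2), as.vector(lat2)),
                           r = 6371000) / 1000
}

## nearest water cell to (lon, lat), optionally restricted by a predicate
## matrix `ok` (TRUE = admissible). Ties broken by lowest cell index
## (column-major), making the search deterministic.
nearestWaterCell <- function(bathy, lon, lat, ok = NULL) {
  wm <- waterMask(bathy)
  if (!is.null(ok)) wm <- wm & ok
  if (!any(wm)) return(NULL)
  cc <- cellCentres(bathy)
  idx <- which(wm)
  d <- gcDistKm(lon, lat, cc$lon[idx], cc$lat[idx])
  best <- idx[order(d, idx)[1]]
  rc <- arrayInd(best, dim(wm))
  list(row = rc[1], col = rc[2],
       lon = bathy@lon[rc[2]], lat = bathy@lat[rc[1]],
       dist_km = min(d))
}

#' Read an ESRI ASCII grid raster
#'
#' Plain-text single-band raster reader for bathymetry and field inputs.
#' Values are interpreted as seafloor depth in metres positive down; cells
#' with value <= 0 (or NODATA) are land. The CRS is taken to be geographic
#' (WGS84); headers whose extent is incompatible with geographic coordinates
#' (beyond +-180 / +-90) are rejected as projected.
#'
#' @param path path to an `.asc` file (ncols/nrows/xllcorner/yllcorner/
#'   cellsize/NODATA_value header followed by rows north to south)
#' @return a [RasterGrid-class]
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid value count does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(hdr$nrows)), , drop = FALSE]  # file is north-first
  m[m == nodata] <- 0  # NODATA treated as land
  lon <- hdr$xllcorner + (seq_len(hdr$ncols) - 0.5) * hdr$cellsize
  lat <- hdr$yllcorner + (seq_len(hdr$nrows) - 0.5) * hdr$cellsize
  if (max(abs(lon)) > 180 || max(abs(lat)) > 90)
    stop("raster extent is not geographic (projected CRS?): ", path)
  rasterGrid(lon, lat, m)
}

#' @rdname readAsciiGrid
#' @param grid a [RasterGrid-class] to write
#' @export
writeAsciiGrid <- function(grid, path) {
  v <- grid@values
  res <- cellSizeDeg(grid)
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", min(grid@lon) - res / 2),
           sprintf("yllcorner %.10g", min(grid@lat) - res / 2),
           sprintf("cellsize %.10g", res),
           "NODATA_value -9999")
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, digits = 10),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a bathymetry raster
#'
#' Reads a single-band geographic raster (ESRI ASCII grid) as seafloor depth
#' positive down and validates that it contains water.
#'
#' @param path path to the raster file
#' @return a [RasterGrid-class] with land coded <= 0
#' @export
readBathymetry <- function(path) {
  g <- readAsciiGrid(path)
  if (!any(g@values > 0)) stop("no water cells in bathymetry raster ", path)
  g
}
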