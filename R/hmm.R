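#' Movement kernels for the convolution step
#'
#' The migratory kernel is a discretised, truncated 2-D Gaussian: zero
#' beyond the hard daily bound speed x 86400 s (172.8 km at the default
#' 2 m/s), with sd equal to half that radius, normalised to sum 1. The
#' resident kernel has the same shape scaled by `resident_fraction`. Cell
#' sizes in km are evaluated at the grid's central latitude. A kernel whose
#' radius falls below one cell is widened to a minimum 3x3 kernel with a
#' warning.
#'
#' @param grid a [RasterGrid-class]
#' @param speed_mps migratory swimming speed bound (default 2)
#' @param resident_fraction scale of the resident kernel (default 0.1)
#' @return list(resident, migratory) of kernel matrices (odd dimensions,
#'   each summing to 1) with attributes `radius_km`
#' @export
buildKernels <- function(grid, speed_mps = 2.0, resident_fraction = 0.1) {
  stopifnot(speed_mps > 0)
  res <- cellSizeDeg(grid)
  dx_km <- res * 111.32 * cos(mean(grid@lat) * pi / 180)
  dy_km <- res * 111.32
  one <- function(radius_km) {
    if (radius_km < max(dx_km, dy_km)) {
      warning("kernel radius below one cell: using minimum 3x3 kernel")
      radius_eff <- max(dx_km, dy_km) * sqrt(2)
    } else radius_eff <- radius_km
    nx <- ceiling(radius_eff / dx_km)
    ny <- ceiling(radius_eff / dy_km)
    off_x <- (-nx:nx) * dx_km
    off_y <- (-ny:ny) * dy_km
    d2 <- outer(off_y^2, off_x^2, `+`)
    sdk <- radius_eff / 2
    k <- exp(-d2 / (2 * sdk^2))
    k[sqrt(d2) > radius_eff] <- 0
    k <- k / sum(k)
    attr(k, "radius_km") <- radius_km
    k
  }
  radius <- speed_mps * 86400 / 1000
  list(resident = one(radius * resident_fraction), migratory = one(radius))
}

## 2-D "same" convolution via FFT. Returns a closure so the kernel FFT is
## computed once per (kernel, grid-shape) pair.
makeConvolver <- function(k, nr, nc) {
  pr <- stats::nextn(nr + nrow(k) - 1, c(2, 3, 5))
  pc <- stats::nextn(nc + ncol(k) - 1, c(2, 3, 5))
  K <- matrix(0, pr, pc)
  K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  Kf <- fft(K)
  ro <- (nrow(k) - 1) / 2
  co <- (ncol(k) - 1) / 2
  function(x) {
    X <- matrix(0, pr, pc)
    X[seq_len(nr), seq_len(nc)] <- x
    full <- Re(fft(fft(X) * Kf, inverse = TRUE)) / (pr * pc)
    out <- full[(1 + ro):(ro + nr), (1 + co):(co + nc), drop = FALSE]
    out[out < 0] <- 0  # FFT round-off
    out
  }
}

#' Forward-backward smoothing over the likelihood stack
#'
#' Two-state hidden Markov smoother on the grid: the hidden state is the
#' (cell, behaviour) pair, the behaviour switches with a fixed symmetric
#' matrix and the spatial transition is convolution with the behaviour's
#' movement kernel; land cells absorb zero mass. Resident-to-resident moves
#' use the resident kernel; any move involving the migratory behaviour (a
#' switching day is a moving day) uses the migratory kernel, which keeps the
#' joint transition operator exactly symmetric. Per-day joint posteriors
#' are normalised to 1 and the model log-likelihood is the sum of log
#' forward normalisers. Days whose combined likelihood is degenerate are
#' replaced by the uniform water surface and flagged.
#'
#' @param stack a [LikelihoodStack-class]
#' @param kernels output of [buildKernels()]
#' @param state_stay probability of keeping the behaviour state (default 0.9)
#' @param sources layer codes recorded on the result (bookkeeping only)
#' @return a [PosteriorTrack-class]
#' @export
forwardBackward <- function(stack, kernels, state_stay = 0.9,
                            sources = sort(unique(unlist(lapply(stack@layers,
                                                                names))))) {
  grid <- stack@grid
  water <- waterMask(grid)
  nr <- nrow(water); nc <- ncol(water)
  trans <- matrix(c(state_stay, 1 - state_stay, 1 - state_stay, state_stay), 2)
  conv <- list(makeConvolver(kernels$resident, nr, nc),
               makeConvolver(kernels$migratory, nr, nc))
  n <- length(stack@dates)
  L <- vector("list", n)
  flagged <- logical(n)
  for (t in seq_len(n)) {
    cb <- combineDay(stack@layers[[t]], water)
    L[[t]] <- cb$surface
    flagged[t] <- cb$degenerate
  }
  alpha <- vector("list", n)
  logLik <- 0
  a <- list(L[[1]] * 0.5, L[[1]] * 0.5)
  z <- sum(a[[1]]) + sum(a[[2]])
  if (z <= 0) stop("first day's likelihood is identically zero")
  logLik <- log(z)
  alpha[[1]] <- lapply(a, `/`, z)
  for (t in seq_len(n)[-1]) {
    # kernel by (source, destination) pair: resident kernel only for 1->1
    rr <- conv[[1]](alpha[[t - 1]][[1]])
    rm <- conv[[2]](alpha[[t - 1]][[1]])
    mm <- conv[[2]](alpha[[t - 1]][[2]])
    a <- list(L[[t]] * (trans[1, 1] * rr + trans[2, 1] * mm),
              L[[t]] * (trans[1, 2] * rm + trans[2, 2] * mm))
    z <- sum(a[[1]]) + sum(a[[2]])
    if (z <= 0) { # fully blocked transition: reset to uniform water
      a <- list(matrix(as.numeric(water), nr), matrix(as.numeric(water), nr))
      z <- sum(a[[1]]) + sum(a[[2]])
      flagged[t] <- TRUE
    }
    logLik <- logLik + log(z)
    alpha[[t]] <- lapply(a, `/`, z)
  }
  beta <- vector("list", n)
  beta[[n]] <- list(matrix(1, nr, nc), matrix(1, nr, nc))
  for (t in rev(seq_len(n - 1))) {
    bl <- list(L[[t + 1]] * beta[[t + 1]][[1]], L[[t + 1]] * beta[[t + 1]][[2]])
    # mirror of the forward kernel assignment (operator is symmetric)
    b <- list(trans[1, 1] * conv[[1]](bl[[1]]) + trans[1, 2] * conv[[2]](bl[[2]]),
              trans[2, 1] * conv[[2]](bl[[1]]) + trans[2, 2] * conv[[2]](bl[[2]]))
    z <- sum(b[[1]]) + sum(b[[2]])
    beta[[t]] <- if (z > 0) lapply(b, `/`, z) else
      list(matrix(1, nr, nc), matrix(1, nr, nc))
  }
  posterior <- vector("list", n)
  stateProb <- numeric(n)
  for (t in seq_len(n)) {
    p1 <- alpha[[t]][[1]] * beta[[t]][[1]]
    p2 <- alpha[[t]][[2]] * beta[[t]][[2]]
    z <- sum(p1) + sum(p2)
    posterior[[t]] <- (p1 + p2) / z
    stateProb[t] <- sum(p2) / z
  }
  pos <- posteriorMeanFromList(grid, posterior, stack@dates)
  new("PosteriorTrack", grid = grid, dates = stack@dates,
      posterior = posterior, stateProb = stateProb, positions = pos,
      logLik = logLik, sources = as.character(sources),
      flagged = stack@dates[flagged])
}

posteriorMeanFromList <- function(grid, posterior, dates) {
  cc <- cellCentres(grid)
  lon <- vapply(posterior, function(p) sum(p * cc$lon), numeric(1))
  lat <- vapply(posterior, function(p) sum(p * cc$lat), numeric(1))
  data.frame(date = dates, lon = lon, lat = lat)
}

#' Posterior-mean daily positions
#'
#' Per-day average of the posterior distribution grid (states
#' marginalised): the most probable location estimate before depth snapping.
#'
#' @param track a [PosteriorTrack-class]
#' @return data.frame(date, lon, lat)
#' @export
posteriorMeanPositions <- function(track) track@positions

#' Restrict a likelihood stack to a set of observation sources
#'
#' Drops all layers whose source code is not in `sources`. Known-location
#' layers (`K`) are always retained: they constrain every candidate model.
#'
#' @param stack a [LikelihoodStack-class]
#' @param sources character vector of source codes to keep
#' @return the restricted [LikelihoodStack-class]
#' @export
subsetStack <- function(stack, sources) {
  keep <- union(sources, "K")
  layers <- lapply(stack@layers, function(day) day[names(day) %in% keep])
  new("LikelihoodStack", grid = stack@grid, dates = stack@dates,
      layers = layers)
}

#' Select the best layer combination by AIC
#'
#' Fits the smoother on candidate subsets of the available observation
#' sources (every candidate includes the bathymetric layer) and selects the
#' model with the lowest AIC = 2k - 2 logL, where k is the number of
#' likelihood sources plus one state-switch parameter. Ties go to the model
#' with fewer sources.
#'
#' @param stack the full [LikelihoodStack-class]
#' @param kernels output of [buildKernels()]
#' @param candidates list of character vectors of sources; NULL enumerates
#'   all subsets of the observed sources that include `"B"`
#' @param state_stay behaviour-state stay probability
#' @return the best [PosteriorTrack-class]; the per-candidate AIC table is
#'   attached as attribute `aic`
#' @export
selectModel <- function(stack, kernels, candidates = NULL, state_stay = 0.9) {
  avail <- setdiff(sort(unique(unlist(lapply(stack@layers, names)))), "K")
  if (is.null(candidates)) {
    extras <- setdiff(avail, "B")
    candidates <- list(character(0))
    for (e in extras)
      candidates <- c(candidates, lapply(candidates, c, e))
    candidates <- lapply(candidates, function(x) sort(c(x, "B")))
  }
  if (!length(candidates)) stop("no candidate layer combinations")
  fits <- vector("list", length(candidates))
  aic <- nsrc <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    src <- candidates[[i]]
    fit <- tryCatch(forwardBackward(subsetStack(stack, src), kernels,
                                    state_stay, sources = src),
                    error = function(e) NULL)
    fits[[i]] <- fit
    nsrc[i] <- length(src)
    aic[i] <- if (is.null(fit)) Inf else 2 * (length(src) + 1) - 2 * fit@logLik
  }
  if (all(is.infinite(aic))) stop("all candidate models are degenerate")
  best <- order(aic, nsrc)[1]
  out <- fits[[best]]
  attr(out, "aic") <- data.frame(
    sources = vapply(candidates, paste, character(1), collapse = ""),
    k = nsrc + 1, aic = aic)
  out
}
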