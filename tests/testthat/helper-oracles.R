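## Independent oracles, deliberately implemented without reusing the
## package's computation paths.

## -- plain Dijkstra over a water mask with the same 16-neighbour moves,
##    used to check leastCostPath. Distances in km via the haversine.
oracleHaversineKm <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  a <- sin((lat2 - lat1) * rad / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin((lon2 - lon1) * rad / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

oracleDijkstra <- function(bathy, start_cell, end_cell) {
  wm <- gridValues(bathy) > 0
  nr <- nrow(wm); nc <- ncol(wm)
  lons <- gridLon(bathy); lats <- gridLat(bathy)
  offs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1),
                c(1, 2), c(1, -2), c(-1, 2), c(-1, -2),
                c(2, 1), c(2, -1), c(-2, 1), c(-2, -1))
  dist <- matrix(Inf, nr, nc)
  dist[start_cell[1], start_cell[2]] <- 0
  visited <- matrix(FALSE, nr, nc)
  repeat {
    d <- dist; d[visited] <- Inf
    u <- arrayInd(which.min(d), dim(d))
    if (is.infinite(d[u])) break
    visited[u] <- TRUE
    if (all(u == end_cell)) break
    for (k in seq_len(nrow(offs))) {
      v <- u + offs[k, ]
      if (v[1] < 1 || v[1] > nr || v[2] < 1 || v[2] > nc) next
      if (!wm[v[1], v[2]]) next
      w <- oracleHaversineKm(lons[u[2]], lats[u[1]], lons[v[2]], lats[v[1]])
      if (dist[u] + w < dist[v[1], v[2]]) dist[v[1], v[2]] <- dist[u] + w
    }
  }
  dist[end_cell[1], end_cell[2]]
}

## -- dense-matrix forward-backward over the joint (cell, state) space:
##    transition matrices built by explicit offset lookup, no FFT.
oracleForwardBackward <- function(stack, kernels, state_stay = 0.9) {
  grid <- stack@grid
  water <- gridValues(grid) > 0
  nr <- nrow(water); nc <- ncol(water)
  ncell <- nr * nc
  kmat <- function(k) {
    ro <- (nrow(k) - 1) / 2; co <- (ncol(k) - 1) / 2
    T <- matrix(0, ncell, ncell)
    for (src in seq_len(ncell)) {
      rs <- (src - 1) %% nr + 1; cs <- (src - 1) %/% nr + 1
      for (dst in seq_len(ncell)) {
        rd <- (dst - 1) %% nr + 1; cd <- (dst - 1) %/% nr + 1
        dr <- rd - rs; dc <- cd - cs
        if (abs(dr) <= ro && abs(dc) <= co)
          T[dst, src] <- k[ro + 1 + dr, co + 1 + dc]
      }
    }
    T
  }
  Tr <- kmat(kernels$resident); Tm <- kmat(kernels$migratory)
  s <- state_stay
  # joint operator: rows = destination (cell, state), cols = source
  M <- rbind(cbind(s * Tr, (1 - s) * Tm),
             cbind((1 - s) * Tm, s * Tm))
  n <- length(stack@dates)
  L <- lapply(stack@layers, function(day) {
    cb <- combineDay(day, water)
    as.vector(cb$surface)
  })
  alpha <- vector("list", n)
  a <- c(L[[1]] * 0.5, L[[1]] * 0.5)
  logLik <- log(sum(a))
  alpha[[1]] <- a / sum(a)
  for (t in seq_len(n)[-1]) {
    a <- c(L[[t]], L[[t]]) * as.vector(M %*% alpha[[t - 1]])
    logLik <- logLik + log(sum(a))
    alpha[[t]] <- a / sum(a)
  }
  beta <- vector("list", n)
  beta[[n]] <- rep(1, 2 * ncell)
  for (t in rev(seq_len(n - 1))) {
    b <- as.vector(t(M) %*% (c(L[[t + 1]], L[[t + 1]]) * beta[[t + 1]]))
    beta[[t]] <- b / sum(b)
  }
  posterior <- lapply(seq_len(n), function(t) {
    p <- alpha[[t]] * beta[[t]]
    p <- p / sum(p)
    matrix(p[1:ncell] + p[ncell + 1:ncell], nr, nc)
  })
  list(posterior = posterior, logLik = logLik)
}

## -- literal path enumeration over all (cell, state) paths for tiny cases
oraclePathEnum <- function(stack, kernels, state_stay = 0.9) {
  grid <- stack@grid
  water <- gridValues(grid) > 0
  nr <- nrow(water); nc <- ncol(water)
  ncell <- nr * nc
  L <- lapply(stack@layers, function(day)
    as.vector(combineDay(day, water)$surface))
  kval <- function(k, src, dst) {
    ro <- (nrow(k) - 1) / 2; co <- (ncol(k) - 1) / 2
    rs <- (src - 1) %% nr + 1; cs <- (src - 1) %/% nr + 1
    rd <- (dst - 1) %% nr + 1; cd <- (dst - 1) %/% nr + 1
    if (abs(rd - rs) <= ro && abs(cd - cs) <= co)
      k[ro + 1 + rd - rs, co + 1 + cd - cs] else 0
  }
  s <- state_stay
  step <- function(x1, s1, x2, s2) {
    if (s1 == 1 && s2 == 1) s * kval(kernels$resident, x1, x2)
    else if (s1 == s2) s * kval(kernels$migratory, x1, x2)
    else (1 - s) * kval(kernels$migratory, x1, x2)
  }
  n <- length(stack@dates)
  states <- expand.grid(x = seq_len(ncell), s = 1:2)
  nj <- nrow(states)
  paths <- as.matrix(expand.grid(rep(list(seq_len(nj)), n)))
  w <- numeric(nrow(paths))
  for (p in seq_len(nrow(paths))) {
    j1 <- paths[p, 1]
    pr <- 0.5 * L[[1]][states$x[j1]]
    if (n > 1) for (t in 2:n) {
      ja <- paths[p, t - 1]; jb <- paths[p, t]
      if (pr == 0) break
      pr <- pr * step(states$x[ja], states$s[ja],
                      states$x[jb], states$s[jb]) * L[[t]][states$x[jb]]
    }
    w[p] <- pr
  }
  posterior <- lapply(seq_len(n), function(t) {
    m <- numeric(ncell)
    for (x in seq_len(ncell)) {
      sel <- states$x[paths[, t]] == x
      m[x] <- sum(w[sel])
    }
    matrix(m / sum(w), nr, nc)
  })
  list(posterior = posterior, total = sum(w))
}

## -- exact Wilcoxon signed-rank p-value by enumerating all sign patterns
oracleSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  Wobs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- signs %*% r
  mean(abs(W - n * (n + 1) / 4) >= abs(Wobs - n * (n + 1) / 4) - 1e-9)
}

## -- independent Meeus-style low-precision solar position (sunrise/sunset)
oracleSunriseSunset <- function(date, lon, lat) {
  jd <- as.numeric(as.Date(date)) + 2440587.5
  sunAt <- function(jd_ut) {
    T <- (jd_ut - 2451545) / 36525
    L0 <- (280.46646 + 36000.76983 * T) %% 360
    M <- (357.52911 + 35999.05029 * T) %% 360
    Mr <- M * pi / 180
    C <- (1.914602 - 0.004817 * T) * sin(Mr) + 0.019993 * sin(2 * Mr) +
      0.000289 * sin(3 * Mr)
    sunlong <- (L0 + C - 0.00569) * pi / 180  # apparent, ignoring nutation
    eps <- (23.439291 - 0.0130042 * T) * pi / 180
    decl <- asin(sin(eps) * sin(sunlong))
    y <- tan(eps / 2)^2
    L0r <- L0 * pi / 180
    eqt <- 4 * (y * sin(2 * L0r) - 2 * 0.016708 * sin(Mr) +
                  4 * 0.016708 * y * sin(Mr) * cos(2 * L0r)) * 180 / pi
    list(decl = decl, eqt = eqt)
  }
  sp <- sunAt(jd + 0.5)
  latr <- lat * pi / 180
  cosH <- (cos(90.833 * pi / 180) - sin(latr) * sin(sp$decl)) /
    (cos(latr) * cos(sp$decl))
  H <- acos(pmin(1, pmax(-1, cosH))) * 180 / pi
  noon_min <- 720 - 4 * lon - sp$eqt
  day0 <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC")
  list(sunrise = day0 + (noon_min - 4 * H) * 60,
       sunset = day0 + (noon_min + 4 * H) * 60)
}
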