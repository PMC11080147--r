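test_that("light longitude layer is Gaussian in longitude only", {
  b <- flatBathy(11, 11)
  mid <- gridLon(b)[6]
  l <- lightLongitudeLayer(mid, 0.05, b)
  # constant across latitude, symmetric about the estimate
  expect_true(all(apply(l, 2, function(col) diff(range(col)) == 0)))
  expect_equal(l[1, ], rev(l[1, ]))
  expect_equal(which.max(l[1, ]), 6L)
  # small sd concentrates mass on the estimate's longitude column
  l2 <- lightLongitudeLayer(mid, 1e-4, b)
  expect_equal(sum(l2[, -6]), 0, tolerance = 1e-12)
  expect_warning(l3 <- lightLongitudeLayer(mid + 10, 0.05, b), "dropped")
  expect_null(l3)
})

test_that("SST layer follows the integrated-Gaussian form", {
  b <- flatBathy(5, 5)
  field <- matrix(20, 5, 5)
  w <- sstLayer(19.8, 20.2, field, b, tolerance = 0.5)
  expect_equal(max(w), 1)
  # field 5 tolerances outside the range has negligible weight
  field2 <- field; field2[1, 1] <- 20.2 + 0.5 + 5 * 0.5
  w2 <- sstLayer(19.8, 20.2, field2, b, tolerance = 0.5)
  expect_lt(w2[1, 1], 1e-4 * max(w2))
  # latitudinal gradient localises the right latitude
  grad <- matrix(rep(seq(18, 22, length.out = 5), 5), 5, 5)
  w3 <- sstLayer(19.9, 20.1, grad, b, tolerance = 0.5)
  expect_equal(which.max(apply(w3, 1, max)), 3L)
})

test_that("profile layer multiplies per-level evidence in log space", {
  b <- flatBathy(4, 6, depth = 200)
  fields <- list("0" = matrix(20, 4, 6), "50" = matrix(17, 4, 6),
                 "100" = matrix(15, 4, 6))
  prof <- data.frame(depth = c(0, 50, 100), tmin = c(19.9, 16.9, 14.9),
                     tmax = c(20.1, 17.1, 15.1))
  w <- profileLayer(prof, fields, b)
  # field equal to the profile everywhere -> uniform over water
  expect_equal(diff(range(w)), 0, tolerance = 1e-12)

  # +5 degC offset on half the domain suppresses it
  f2 <- lapply(fields, function(m) { m[, 4:6] <- m[, 4:6] + 5; m })
  w2 <- profileLayer(prof, f2, b)
  expect_lt(max(w2[, 4:6]), 1e-3 * max(w2[, 1:3]))

  prof_deep <- rbind(prof, data.frame(depth = 500, tmin = 9, tmax = 10))
  expect_warning(profileLayer(prof_deep, fields, b), "truncat")
})

test_that("OHC layer matches a hand-computed three-level integral", {
  # hand integral: levels 0/50/100 m, midpoint edges 0|25|75|100
  depths <- c(0, 50, 100); temps <- c(20, 17, 15); iso <- 14
  hand <- 1025 * 3993 * ((20 - 14) * 25 + (17 - 14) * 50 + (15 - 14) * 25)
  expect_equal(shelftrack:::ohcIntegral(depths, temps, iso), hand,
               tolerance = 1e-6)

  b <- flatBathy(4, 6, depth = 200)
  fields <- list("0" = matrix(20, 4, 6), "50" = matrix(17, 4, 6),
                 "100" = matrix(15, 4, 6))
  # add a gradient so the field OHC range is non-degenerate
  fields <- lapply(fields, function(m) m + outer(rep(0, 4), seq(0, 2, length.out = 6), `+`))
  prof <- data.frame(depth = depths, tmin = temps - 0.1, tmax = temps + 0.1)
  w <- ohcLayer(prof, fields, b, iso_temp = 14)
  # maximal where the field equals the profile (first column)
  expect_equal(max(w[, 1]), 1)
  expect_error(ohcLayer(prof, fields, b, iso_temp = 30), "below")
})

test_that("bathymetric layer implements the two-sided demersal band", {
  m <- matrix(c(95, 120, 85, -5, 400, 299), 2, 3)
  b <- bathyFrom(m)
  w <- bathyLayer(90, b, band = 10)
  expect_equal(w[1, 1], 1)  # |95 - 90| <= 10
  expect_equal(w[2, 1], 0)  # |120 - 90| > 10
  expect_equal(w[2, 2], 0)  # land stays excluded
  # without depth data: admit water above the 300 m cap
  w2 <- bathyLayer(NA, b, cap = 300)
  expect_equal(w2[1, 3], 0)  # 400 m deeper than cap
  expect_equal(w2[2, 3], 1)  # 299 m admitted
  expect_equal(w2[2, 2], 0)
  # band -> Inf reduces to the water mask
  w3 <- bathyLayer(90, b, band = 1e9)
  expect_equal(w3 > 0, gridValues(b) > 0)
  # empty two-sided band falls back to the one-sided rule
  expect_warning(w4 <- bathyLayer(350, b), "one-sided")
  expect_equal(w4[1, 3], 1)   # 400 m >= 350 - 10 under the one-sided rule
  expect_equal(sum(w4 > 0), 1)
})

test_that("known locations and drift buffers behave geometrically", {
  b <- flatBathy(21, 21)
  lon <- gridLon(b)[11]; lat <- gridLat(b)[11]
  k <- knownLocationLayer(lon, lat, "tagging", b)
  expect_equal(which(k == max(k)), which(outer(gridLat(b) == lat,
                                               gridLon(b) == lon, `&`)))
  # a land position is snapped with a warning
  m <- gridValues(b); m[1, 1] <- -5
  b2 <- rasterGrid(gridLon(b), gridLat(b), m)
  expect_warning(knownLocationLayer(gridLon(b)[1], gridLat(b)[1], "coa", b2),
                 "snapped")

  # drift disk radius = gap x speed (haversine-checked boundary)
  buf <- popupDriftBuffer(lon, lat, 1.5, b, drift_speed_km_day = 20)
  cc <- shelftrack:::cellCentres(b)
  d <- matrix(gcDistKm(lon, lat, cc$lon, cc$lat), nrow = 21)
  expect_true(all(buf[d <= 29] == 1))
  expect_true(all(buf[d >= 31] == 0))
  # zero gap -> just the transmit cell
  buf0 <- popupDriftBuffer(lon, lat, 0, b)
  expect_equal(sum(buf0 > 0), 1)
  expect_warning(popupDriftBuffer(lon, lat, 1e5, b), "uniform")
})

test_that("layers are scale-invariant inputs to the smoother", {
  w <- tinyWorld()
  tr <- simulateTrack(w, 8, rep("area-restricted", 8), seed = 20)
  ts <- observePsat(tr, w, seed = 21)
  st <- buildLikelihoodStack(ts, w$env)
  ker <- buildKernels(w$env@bathymetry)
  p1 <- forwardBackward(st, ker)
  # rescaling any layer changes nothing downstream
  st2 <- st
  st2@layers <- lapply(st2@layers, function(day) lapply(day, `*`, 7.3))
  p2 <- forwardBackward(st2, ker)
  expect_equal(p1@positions$lon, p2@positions$lon, tolerance = 1e-9)
  expect_equal(p1@posterior[[4]], p2@posterior[[4]], tolerance = 1e-9)

  # every layer is finite, non-negative and land-masked
  land <- !waterMask(w$env@bathymetry)
  for (day in st@layers) for (l in day) {
    expect_true(all(is.finite(l)) && all(l >= 0))
    expect_true(all(l[land] == 0))
  }
  # days with data contain at least one informative layer
  has_data <- !is.na(ts@maxDepth) | !is.na(ts@lightLon)
  expect_true(all(lengths(st@layers)[has_data] >= 1))
})

test_that("light layer argmax covers the true longitude at the stated rate", {
  w <- tinyWorld()
  tr <- simulateTrack(w, 120, seed = 22)
  ts <- observePsat(tr, w, seed = 23)
  b <- w$env@bathymetry
  ok <- 0; tot <- 0
  for (t in which(!is.na(ts@lightLon))) {
    l <- lightLongitudeLayer(ts@lightLon[t], ts@lightLonSd, b)
    if (is.null(l)) next
    am_lon <- gridLon(b)[which.max(apply(l, 2, max))]
    tot <- tot + 1
    if (abs(am_lon - tr$lon[t]) <= ts@lightLonSd) ok <- ok + 1
  }
  expect_gte(ok / tot, 0.68 * 0.9)  # binomial slack below the Gaussian rate
})
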