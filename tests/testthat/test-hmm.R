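## random small likelihood stack on a given bathymetry
randomStack <- function(bathy, n_days, seed) {
  set.seed(seed)
  layers <- lapply(seq_len(n_days), function(t) {
    l <- matrix(runif(length(gridValues(bathy))), nrow(gridValues(bathy)))
    list(X = shelftrack:::maskAndScale(l, waterMask(bathy)))
  })
  new("LikelihoodStack", grid = bathy, dates = as.Date("2019-01-01") +
        seq_len(n_days) - 1, layers = layers)
}

smallKernels <- function() {
  k1 <- matrix(c(0, 0.15, 0, 0.15, 0.4, 0.15, 0, 0.15, 0), 3, 3)
  k2 <- matrix(1 / 25, 5, 5)
  list(resident = k1, migratory = k2)
}

test_that("movement kernels integrate to one with the stated support", {
  w <- tinyWorld()
  ker <- buildKernels(w$env@bathymetry)
  expect_equal(sum(ker$migratory), 1, tolerance = 1e-9)
  expect_equal(sum(ker$resident), 1, tolerance = 1e-9)
  expect_equal(attr(ker$migratory, "radius_km"), 172.8)
  # zero beyond the support radius
  k <- ker$migratory
  ro <- (nrow(k) - 1) / 2; co <- (ncol(k) - 1) / 2
  res <- cellSizeDeg(w$env@bathymetry)
  dx <- res * 111.32 * cos(mean(gridLat(w$env@bathymetry)) * pi / 180)
  dy <- res * 111.32
  d <- sqrt(outer(((-ro:ro) * dy)^2, ((-co:co) * dx)^2, `+`))
  expect_true(all(k[d > 172.8] == 0))
  expect_true(any(k[d <= 172.8] > 0))
  ww <- testthat::capture_warnings(buildKernels(w$env@bathymetry,
                                                speed_mps = 0.01))
  expect_true(all(grepl("minimum 3x3", ww)) && length(ww) >= 1)
})

test_that("convolving a delta twice equals the two-day kernel on open water", {
  b <- flatBathy(41, 41)
  k <- buildKernels(b, speed_mps = 0.2, resident_fraction = 1)$migratory
  conv <- shelftrack:::makeConvolver(k, 41, 41)
  delta <- matrix(0, 41, 41); delta[21, 21] <- 1
  two_step <- conv(conv(delta))
  # direct two-day kernel: discrete self-convolution of k
  ro <- (nrow(k) - 1) / 2; co <- (ncol(k) - 1) / 2
  k2 <- matrix(0, 4 * ro + 1, 4 * co + 1)
  for (i in -ro:ro) for (j in -co:co)
    k2[(i + 2 * ro + 1) + (-ro:ro), (j + 2 * co + 1) + (-co:co)] <-
      k2[(i + 2 * ro + 1) + (-ro:ro), (j + 2 * co + 1) + (-co:co)] +
      k[i + ro + 1, j + co + 1] * k
  got <- two_step[21 + (-(2 * ro)):(2 * ro), 21 + (-(2 * co)):(2 * co)]
  expect_equal(got, k2[], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("degenerate stacks give the expected closed-form posteriors", {
  b <- flatBathy(7, 7)
  ker <- smallKernels()
  # all-uniform likelihoods + a symmetric kernel whose support spans the
  # whole grid (no boundary truncation) -> uniform posterior every day
  flat <- matrix(1 / 13^2, 13, 13)
  st <- new("LikelihoodStack", grid = b,
            dates = as.Date("2019-01-01") + 0:3,
            layers = rep(list(list()), 4))
  pt <- forwardBackward(st, list(resident = flat, migratory = flat))
  for (p in pt@posterior)
    expect_equal(diff(range(p)), 0, tolerance = 1e-12)
  # delta likelihoods pin the posterior to those cells
  mk <- function(r, c) { m <- matrix(0, 7, 7); m[r, c] <- 1; list(X = m) }
  st2 <- new("LikelihoodStack", grid = b,
             dates = as.Date("2019-01-01") + 0:2,
             layers = list(mk(2, 2), mk(3, 3), mk(4, 3)))
  pt2 <- forwardBackward(st2, ker)
  expect_equal(pt2@posterior[[2]][3, 3], 1, tolerance = 1e-9)
  # and the posterior mean is the pinned cell centre
  expect_equal(pt2@positions$lon[2], gridLon(b)[3])
  expect_equal(pt2@positions$lat[2], gridLat(b)[3])
})

test_that("smoothing matches the dense path-sum oracle on random instances", {
  set.seed(99)
  for (i in 1:6) {
    m <- matrix(60, 5, 5)
    m[sample(25, 4)] <- -5  # some land
    b <- bathyFrom(m)
    st <- randomStack(b, 4, seed = 100 + i)
    ker <- smallKernels()
    got <- forwardBackward(st, ker)
    ref <- oracleForwardBackward(st, ker)
    expect_equal(got@logLik, ref$logLik, tolerance = 1e-10)
    for (t in 1:4)
      expect_equal(got@posterior[[t]], ref$posterior[[t]], tolerance = 1e-10)
  }
})

test_that("smoothing matches literal path enumeration on a tiny instance", {
  b <- bathyFrom(matrix(c(50, 60, -5, 40), 2, 2))
  st <- randomStack(b, 3, seed = 7)
  ker <- list(resident = matrix(c(0, .2, 0, .2, .2, .2, 0, .2, 0), 3, 3),
              migratory = matrix(1 / 9, 3, 3))
  got <- forwardBackward(st, ker)
  ref <- oraclePathEnum(st, ker)
  for (t in 1:3)
    expect_equal(got@posterior[[t]], ref$posterior[[t]], tolerance = 1e-10)
})

test_that("per-day posterior mass is one and never touches land", {
  w <- tinyWorld()
  tr <- simulateTrack(w, 12, seed = 31)
  ts <- observePsat(tr, w, seed = 32)
  st <- buildLikelihoodStack(ts, w$env)
  pt <- forwardBackward(st, buildKernels(w$env@bathymetry))
  land <- !waterMask(w$env@bathymetry)
  for (p in pt@posterior) {
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(sum(p[land]), 0, tolerance = 1e-12)
  }
  expect_true(all(pt@stateProb >= 0 & pt@stateProb <= 1))
})

test_that("time reversal yields the reversed posterior sequence", {
  m <- matrix(60, 6, 6); m[c(3, 14, 22)] <- -5
  b <- bathyFrom(m)
  st <- randomStack(b, 5, seed = 55)
  ker <- smallKernels()
  fwd <- forwardBackward(st, ker)
  rev_st <- new("LikelihoodStack", grid = b, dates = st@dates,
                layers = rev(st@layers))
  bwd <- forwardBackward(rev_st, ker)
  for (t in 1:5)
    expect_equal(fwd@posterior[[t]], bwd@posterior[[6 - t]], tolerance = 1e-9)
})

test_that("AIC selection penalises sources and prefers informative ones", {
  b <- flatBathy(9, 9)
  st <- randomStack(b, 4, seed = 8)
  st@layers <- lapply(st@layers, function(day) list(B = day$X))
  ker <- smallKernels()
  # single candidate returned unchanged
  one <- selectModel(st, ker, candidates = list("B"))
  expect_equal(one@sources, "B")
  # equal logL: the smaller model wins the tie
  st2 <- st
  st2@layers <- lapply(st2@layers, function(day)
    list(B = day$B, S = matrix(1, 9, 9) * (gridValues(b) > 0)))
  sel <- selectModel(st2, ker, candidates = list("B", c("B", "S")))
  # the uniform S layer adds no information -> same logL, fewer sources win
  expect_equal(sel@sources, "B")
  aic <- attr(sel, "aic")
  expect_equal(nrow(aic), 2)
  expect_lt(abs(diff(2 * aic$k - aic$aic)), 1e-6)  # logL equal
})

test_that("adding an informative layer does not worsen recovery", {
  w <- tinyWorld()
  tr <- simulateTrack(w, 25, seed = 61)
  ts <- observePsat(tr, w, seed = 62)
  ker <- buildKernels(w$env@bathymetry)
  full <- forwardBackward(buildLikelihoodStack(ts, w$env), ker)
  bare <- forwardBackward(buildLikelihoodStack(ts, w$env,
                                               sources = c("L")), ker)
  err <- function(pt) median(gcDistKm(pt@positions$lon, pt@positions$lat,
                                      tr$lon, tr$lat))
  expect_lte(err(full), err(bare))
})
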