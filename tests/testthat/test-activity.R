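test_that("acceleration magnitude is the Euclidean norm", {
  expect_equal(accelMagnitude(0, 0, 0), 0)
  expect_equal(accelMagnitude(1, 2, 2), 3)
  set.seed(29)
  x <- rnorm(1000); y <- rnorm(1000); z <- rnorm(1000)
  ref <- apply(cbind(x, y, z), 1, function(v) sqrt(sum(v * v)))
  expect_equal(accelMagnitude(x, y, z), ref, tolerance = 1e-12)
})

test_that("high-activity threshold uses the interpolated 95th percentile", {
  t0 <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC")
  ev <- highActivityEvents(t0 + seq_len(100) * 5, as.numeric(1:100))
  expect_equal(ev$threshold, 95.05)
  expect_equal(sum(ev$is_event), 5L)
  # strictly-above convention: never more than 5% overall
  set.seed(31)
  ma <- rgamma(5000, 2, 2)
  ev2 <- highActivityEvents(t0 + seq_len(5000) * 5, ma)
  expect_lte(ev2$overall_rate_pct, 5)
  # constant series: threshold equals the constant, zero events
  expect_warning(ev3 <- highActivityEvents(t0 + seq_len(200) * 5,
                                           rep(1, 200)), "constant")
  expect_equal(ev3$threshold, 1)
  expect_equal(sum(ev3$is_event), 0L)
  expect_error(highActivityEvents(t0 + 1:10, 1:10), "100 samples")
})

test_that("injected bursts are recovered at the default noise level", {
  w <- tinyWorld()
  tr <- simulateTrack(w, 4, rep("area-restricted", 4), seed = 401)
  ts <- observePsat(tr, w, accel = TRUE, seed = 402)
  ev <- highActivityEvents(ts@archival$time, ts@archival$ma)
  truth <- ts@archival$is_burst
  recall <- sum(ev$is_event & truth) / sum(truth)
  expect_gte(recall, 0.9)
  expect_lte(ev$overall_rate_pct, 5)
})

test_that("per-individual thresholds differ from pooled thresholds", {
  t0 <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC")
  set.seed(33)
  quiet <- abs(rnorm(1000, 1, 0.05))
  lively <- abs(rnorm(1000, 1, 0.5))
  thr_q <- highActivityEvents(t0 + seq_len(1000) * 5, quiet)$threshold
  thr_l <- highActivityEvents(t0 + seq_len(1000) * 5, lively)$threshold
  pooled <- as.numeric(quantile(c(quiet, lively), 0.95))
  expect_gt(thr_l, pooled)
  expect_lt(thr_q, pooled)
  # pooling would flag almost nothing on the quiet fish
  expect_lt(mean(quiet > pooled), 0.01)
})

test_that("Wilcoxon monthly comparison matches exact enumeration for n = 8", {
  set.seed(37)
  d <- c(1.3, -0.4, 2.2, 0.9, -1.7, 3.1, 0.6, -2.5)
  a <- rnorm(8, 10, 1)
  monthly <- rbind(
    data.frame(tag_id = sprintf("f%d", 1:8), month = 6, mean_pct = a),
    data.frame(tag_id = sprintf("f%d", 1:8), month = 7, mean_pct = a - d))
  res <- monthlyActivityTest(monthly)
  expect_equal(res$p_raw[1, 2], oracleSignedRankP(d), tolerance = 1e-12)
  # single pair: adjusted equals raw
  expect_equal(res$p_adj[1, 2], res$p_raw[1, 2])
})

test_that("Bonferroni and letter groups behave consistently", {
  set.seed(41)
  base <- rnorm(10, 5, 0.3)
  monthly <- do.call(rbind, lapply(1:4, function(m)
    data.frame(tag_id = sprintf("f%d", 1:10), month = m,
               mean_pct = base + (m == 4) * 10 + rnorm(10, 0, 0.2))))
  res <- monthlyActivityTest(monthly)
  ut <- upper.tri(res$p_raw)
  expect_true(all(res$p_adj[ut] >= res$p_raw[ut], na.rm = TRUE))
  expect_true(all(res$p_adj[ut] <= 1, na.rm = TRUE))
  # months 1-3 share a letter; month 4 does not share with any of them
  l <- res$letters
  shared <- function(a, b) any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  expect_true(shared(l["1"], l["2"]) && shared(l["2"], l["3"]))
  expect_false(shared(l["1"], l["4"]))
  # letter sharing reflects the adjusted matrix at alpha = 0.05
  for (i in 1:3) for (j in (i + 1):4) {
    sig <- res$p_adj[i, j] < 0.05
    expect_equal(!shared(l[as.character(i)], l[as.character(j)]), sig)
  }

  # identical values across months: all adjusted p = 1, one letter group
  same <- do.call(rbind, lapply(1:3, function(m)
    data.frame(tag_id = sprintf("f%d", 1:6), month = m,
               mean_pct = rep(c(1, 2, 3, 4, 5, 6)))))
  res2 <- monthlyActivityTest(same)
  expect_true(all(res2$p_adj[upper.tri(res2$p_adj)] == 1))
  expect_equal(length(unique(res2$letters)), 1L)

  # months without shared individuals are skipped and reported
  sparse <- rbind(data.frame(tag_id = "a", month = 1, mean_pct = 1),
                  data.frame(tag_id = "b", month = 2, mean_pct = 2),
                  data.frame(tag_id = c("a", "b"), month = 3,
                             mean_pct = c(2, 3)))
  res3 <- monthlyActivityTest(sparse)
  expect_true("1-2" %in% res3$skipped)
})

test_that("seasonal activity contrast separates summer from winter", {
  w <- tinyWorld()
  # two short archival windows per fish: one winter, one summer month
  monthly <- do.call(rbind, lapply(1:6, function(i) {
    trw <- simulateTrack(w, 3, rep("area-restricted", 3), seed = 500 + i)
    trs <- trw
    trs$date <- as.Date("2019-07-01") + 0:2
    tsw <- observePsat(trw, w, accel = TRUE, seed = 600 + i)
    tss <- observePsat(trs, w, accel = TRUE, seed = 700 + i)
    # one threshold per individual over its full archival record
    ev <- highActivityEvents(c(tsw@archival$time, tss@archival$time),
                             c(tsw@archival$ma, tss@archival$ma))
    cbind(tag_id = sprintf("f%d", i), ev$monthly)
  }))
  res <- monthlyActivityTest(monthly)
  expect_lt(res$p_adj[1, 2], 0.05)
  expect_false(res$letters["1"] == res$letters["7"])
  # truth direction: July busier than January
  expect_gt(mean(monthly$mean_pct[monthly$month == 7]),
            mean(monthly$mean_pct[monthly$month == 1]))
})

test_that("monthly depth densities normalise and rank-order correctly", {
  t0 <- as.POSIXct("2019-01-15 00:00:00", tz = "UTC")
  # winter-deep / summer-shallow schedule
  tt <- c(t0 + seq_len(500) * 60,
          as.POSIXct("2019-07-15", tz = "UTC") + seq_len(500) * 60)
  depth <- c(80 + rnorm(500, 0, 3), 20 + rnorm(500, 0, 3))
  temp <- 20 - 0.05 * depth
  dd <- depthDensityByMonth(tt, depth, temp)
  for (m in unique(dd$month))
    expect_equal(sum(dd$density[dd$month == m]), 1, tolerance = 1e-12)
  med <- function(m) {
    s <- dd[dd$month == m, ]
    s$depth_bin[which.min(abs(cumsum(s$density) - 0.5))]
  }
  expect_gt(med(1), med(7))
  # temperature colouring reflects the lapse rate
  cold <- dd$mean_temp[dd$month == 1]
  warm <- dd$mean_temp[dd$month == 7]
  expect_lt(mean(cold), mean(warm))

  # single constant depth: all mass in one bin
  d1 <- depthDensityByMonth(t0 + 1:10, rep(12.3, 10))
  expect_equal(nrow(d1), 1)
  expect_equal(d1$density, 1)
})
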