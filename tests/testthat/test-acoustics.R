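test_that("spurious filter keeps companioned detections and is idempotent", {
  d <- det("A", "R1", c("2019-06-01 10:00:00", "2019-06-01 11:00:00"))
  expect_equal(nrow(filterSpurious(d)), 2)

  # one detection 30 h from all others is removed
  d2 <- det("A", "R1", c("2019-06-01 10:00:00", "2019-06-01 11:00:00",
                         "2019-06-02 17:00:00"))
  kept <- filterSpurious(d2)
  expect_equal(nrow(kept), 2)
  expect_false(as.POSIXct("2019-06-02 17:00:00", tz = "UTC") %in%
                 kept$timestamp)

  # a gap of exactly 24 h counts as within
  d3 <- det("A", "R1", c("2019-06-01 10:00:00", "2019-06-02 10:00:00"))
  expect_equal(nrow(filterSpurious(d3)), 2)

  # all pairwise > 24 h apart -> all removed (brute-force cross-check)
  times <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC") +
    cumsum(c(0, rep(25 * 3600, 5)))
  d4 <- det("A", sample(c("R1", "R2"), 6, replace = TRUE), times)
  expect_equal(nrow(filterSpurious(d4)), 0)
  pairwise_ok <- sapply(seq_along(times), function(i)
    any(abs(difftime(times[-i], times[i], units = "hours")) <= 24))
  expect_false(any(pairwise_ok))

  # idempotence and neighbour preservation on a random mixed set
  set.seed(11)
  tmix <- as.POSIXct("2019-06-01", tz = "UTC") +
    sort(sample(0:(40 * 86400), 60))
  dm <- det("A", "R1", tmix)
  once <- filterSpurious(dm)
  expect_equal(filterSpurious(once), once)
  has_neighbour <- sapply(seq_along(tmix), function(i)
    any(abs(as.numeric(difftime(tmix[-i], tmix[i], units = "secs"))) <= 86400))
  expect_equal(nrow(once), sum(has_neighbour))
})

test_that("residency index follows the published convention", {
  # fish detected on 443 distinct days over a 570-day inclusive span
  rel <- as.Date("2020-05-28")
  days <- seq(rel, rel + 569, by = "day")[1:443]
  d <- det("22", "R1", as.POSIXct(paste(days, "12:00:00"), tz = "UTC"))
  d$timestamp[1] <- as.POSIXct(paste(rel, "12:00:00"), tz = "UTC")
  d <- rbind(d, det("22", "R1", paste(rel + 569, "12:00:00")))
  d <- d[!duplicated(as.Date(d$timestamp)), ]
  # force exactly 443 distinct days ending at day 570
  r <- residencyIndex(rel, d[1:443, ])
  expect_equal(r$D_D, 443L)

  # direct check of the published ratios
  expect_equal(shelftrack:::roundHalfUp(443 / 570, 2), 0.78)
  expect_equal(shelftrack:::roundHalfUp(287 / 768, 2), 0.37)

  # detections on every day of the span -> full-time resident
  rel2 <- as.Date("2019-01-01")
  d2 <- det("x", "R1", paste(seq(rel2, rel2 + 9, by = "day"), "03:00:00"))
  r2 <- residencyIndex(rel2, d2)
  expect_equal(r2$I_R, 1)
  expect_true(r2$D_D <= r2$T_P)

  r0 <- residencyIndex(rel2, d2[0, ])
  expect_false(r0$detected)
  expect_true(is.na(r0$I_R))
})

test_that("binning is clock-aligned and conserves detections", {
  d <- det("A", "R1", sprintf("2019-06-01 10:%02d:00", c(1, 15, 30, 45, 59)))
  b <- binDetections(d)
  expect_equal(nrow(b), 1)
  expect_equal(b$n, 5L)
  expect_equal(format(b$bin_start, "%H:%M"), "10:00")

  d2 <- det("A", "R1", c("2019-06-01 10:59:00", "2019-06-01 11:01:00"))
  expect_equal(nrow(binDetections(d2)), 2)

  set.seed(5)
  d3 <- det("A", sample(c("R1", "R2"), 200, TRUE),
            as.POSIXct("2019-06-01", tz = "UTC") + sort(runif(200, 0, 86400)))
  b3 <- binDetections(d3)
  expect_equal(sum(b3$n), 200L)
})

test_that("diel phase matches an independent solar computation", {
  # local solar noon is day; local solar midnight is night
  expect_equal(dielPhase(as.POSIXct("2019-06-21 12:32:00", tz = "UTC"),
                         -8, 37), "day")
  expect_equal(dielPhase(as.POSIXct("2019-06-21 00:32:00", tz = "UTC"),
                         -8, 37), "night")
  # sunrise/sunset against the independent ephemeris oracle, +-2 min
  for (date in c("2019-06-21", "2019-12-21", "2019-03-20", "2019-09-23")) {
    got <- sunriseSunset(as.Date(date), -8, 37)
    ref <- oracleSunriseSunset(as.Date(date), -8, 37)
    expect_lt(abs(as.numeric(difftime(got$sunrise, ref$sunrise,
                                      units = "mins"))), 2)
    expect_lt(abs(as.numeric(difftime(got$sunset, ref$sunset,
                                      units = "mins"))), 2)
  }
  expect_error(sunriseSunset(as.Date("2019-06-21"), -8, 70), "polar")
})

test_that("season labels split the year at the spawning months", {
  expect_equal(seasonLabel(as.Date("2019-03-15")), "spawning")
  expect_equal(seasonLabel(as.Date("2019-09-01")), "resting")
  expect_equal(seasonLabel(as.Date("2020-02-29")), "resting")
  expect_equal(seasonLabel(as.Date("2019-08-31")), "spawning")
})

test_that("centre of activity is the detection-weighted receiver mean", {
  rc <- recv(c("A", "B"), lon = c(0, 0), lat = c(0, 1))
  # all detections at one receiver -> that position
  d <- det("t", "A", paste("2019-06-01", sprintf("%02d:00:00", 1:4)))
  coa <- centreOfActivity(d, rc)
  expect_equal(coa$lon, 0)
  expect_equal(coa$lat, 0)
  # equal counts at two receivers -> midpoint
  d2 <- rbind(det("t", "A", c("2019-06-01 01:00:00", "2019-06-01 02:00:00")),
              det("t", "B", c("2019-06-01 03:00:00", "2019-06-01 04:00:00")))
  expect_equal(centreOfActivity(d2, rc)$lat, 0.5)
  # counts 3 at (0,0), 1 at (0,1) -> (0, 0.25)
  d3 <- rbind(det("t", "A", paste("2019-06-01", c("01:00:00", "02:00:00",
                                                  "03:00:00"))),
              det("t", "B", "2019-06-01 04:00:00"))
  c3 <- centreOfActivity(d3, rc)
  expect_equal(c3$lat, 0.25)
  expect_equal(c3$n_detections, 4L)
})

test_that("co-occurrence requires space AND time overlap", {
  rc <- recv(c("R1", "R2"), lon = c(-8.5, -8.4), lat = c(37, 37))
  b <- binDetections(rbind(
    det("A", "R1", "2019-06-01 10:05:00"),
    det("B", "R1", "2019-06-01 10:45:00"),
    det("A", "R2", "2019-06-01 12:05:00"),
    det("B", "R1", "2019-06-01 12:45:00")))
  co <- coOccurrences(b, rc)
  expect_equal(nrow(co$events), 1)
  expect_equal(co$events$group_size, 2L)
  expect_true(co$events$diel %in% c("day", "night"))

  # symmetric under tag relabelling; member slots sum to group sizes
  b2 <- b
  b2$tag_id <- chartr("AB", "BA", b2$tag_id)
  co2 <- coOccurrences(b2, rc)
  expect_equal(co2$events$group_size, co$events$group_size)
  expect_equal(sum(co$events$group_size),
               sum(lengths(strsplit(co$events$members, ";"))))
})

test_that("simulated aggregations yield co-occurrence groups up to the truth", {
  w <- tinyWorld()
  rc <- w$receivers[20, ]
  t0 <- as.POSIXct("2019-07-01 00:00:00", tz = "UTC")
  set.seed(21)
  dets <- do.call(rbind, lapply(1:5, function(i)
    det(sprintf("f%d", i), rc$receiver_id,
        t0 + sort(runif(30, 0, 6 * 3600)))))
  co <- coOccurrences(binDetections(dets), rc)
  expect_equal(max(co$events$group_size), 5L)
  expect_true(all(co$events$group_size >= 2))
})
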