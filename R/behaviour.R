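#' Step lengths and turning angles of a daily track
#'
#' Step length is the great-circle distance between consecutive daily
#' positions; the turning angle is the signed change in bearing, wrapped to
#' (-pi, pi]. The first position carries no step and the first step no
#' turning angle.
#'
#' @param positions data.frame(date, lon, lat) with >= 3 rows
#' @return data.frame(date, step_km, turn_rad) with one row per step (days
#'   2..n); `turn_rad` is NA on the first step
#' @export
stepMetrics <- function(positions) {
  n <- nrow(positions)
  if (n < 3) stop("at least 3 daily positions required")
  p <- cbind(positions$lon, positions$lat)
  step <- gcDistKm(p[-n, 1], p[-n, 2], p[-1, 1], p[-1, 2])
  brg <- geosphere::bearing(p[-n, , drop = FALSE], p[-1, , drop = FALSE],
                            a = 6371000, f = 0)  # same sphere as gcDistKm
  turn <- c(NA, diff(brg)) * pi / 180
  turn <- ((turn + pi) %% (2 * pi)) - pi       # wrap to (-pi, pi]
  turn[!is.na(turn) & turn == -pi] <- pi
  data.frame(date = positions$date[-1], step_km = step, turn_rad = turn)
}

#' Discretise steps and turning angles
#'
#' Step lengths are binned by within-individual quantiles (so each bin holds
#' an equal share of the individual's steps); turning angles are binned
#' uniformly on (-pi, pi] with the half-open convention placing exactly pi
#' in the last bin.
#'
#' @param steps output of [stepMetrics()]
#' @param n_step_bins,n_angle_bins bin counts (>= 2)
#' @return the input with integer columns `step_bin` and `angle_bin`
#'   (`angle_bin` NA where the angle is NA)
#' @export
discretizeSteps <- function(steps, n_step_bins = 5, n_angle_bins = 8) {
  stopifnot(n_step_bins >= 2, n_angle_bins >= 2)
  br <- unique(quantile(steps$step_km, probs = seq(0, 1,
                                                   length.out = n_step_bins + 1)))
  if (length(br) < 3) {
    warning("near-constant step lengths: single occupied step bin")
    steps$step_bin <- 1L
  } else {
    steps$step_bin <- as.integer(cut(steps$step_km, breaks = br,
                                     include.lowest = TRUE, labels = FALSE))
  }
  width <- 2 * pi / n_angle_bins
  ab <- ceiling((steps$turn_rad + pi) / width)
  ab[!is.na(ab) & ab < 1] <- 1L        # angle exactly -pi (should not occur)
  steps$angle_bin <- as.integer(ab)
  attr(steps, "n_step_bins") <- as.integer(n_step_bins)
  attr(steps, "n_angle_bins") <- as.integer(n_angle_bins)
  steps
}

## token vector of one record range: step-bin tokens 1..S, angle-bin tokens
## S+1..S+A; NA angles contribute no token
segTokens <- function(binned, idx, S) {
  tok <- binned$step_bin[idx]
  ang <- binned$angle_bin[idx]
  c(tok, S + ang[!is.na(ang)])
}

multinomLogLik <- function(counts) {
  counts <- counts[counts > 0]
  sum(counts * log(counts / sum(counts)))
}

#' Segment a discretised track by composition change
#'
#' Exact penalised changepoint segmentation on the bin-count composition
#' (step and angle bins pooled into one categorical vocabulary): dynamic
#' programming maximises the summed multinomial log-likelihood of the
#' segments minus a per-changepoint penalty (BIC-style default
#' `(n_bins - 1) * log(n) / 2`), subject to a minimum segment length.
#' Unlike greedy binary splitting, the exact optimum recovers interior
#' blocks whose isolation needs two simultaneous cuts.
#'
#' @param binned output of [discretizeSteps()]
#' @param penalty per-changepoint penalty; NULL for the BIC-style default
#' @param min_len minimum segment length in records (default 3)
#' @return list of class `TrackSegments`: `records` (the input), `segments`
#'   data.frame(seg_id, start, end, start_date, end_date, n, mean_step_km)
#'   and `counts` (segment x vocabulary matrix)
#' @export
segmentTrack <- function(binned, penalty = NULL, min_len = 3) {
  n <- nrow(binned)
  if (n < 10) stop("at least 10 records required for segmentation")
  S <- attr(binned, "n_step_bins")
  A <- attr(binned, "n_angle_bins")
  V <- S + A
  if (is.null(penalty)) penalty <- (V - 1) * log(n) / 2
  # cumulative token counts so any segment's composition is a difference
  cum <- matrix(0L, n + 1, V)
  for (t in seq_len(n)) {
    cum[t + 1, ] <- cum[t, ]
    tok <- segTokens(binned, t, S)
    for (v in tok) cum[t + 1, v] <- cum[t + 1, v] + 1L
  }
  countsOf <- function(i, j) cum[j + 1, ] - cum[i, ]
  segLL <- function(i, j) multinomLogLik(countsOf(i, j))
  # dynamic programme over last-changepoint position
  best <- rep(-Inf, n + 1)
  prev <- integer(n + 1)
  best[1] <- 0  # zero records
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      if (j - i + 1 < min_len) next
      if (i > 1 && i - 1 < min_len) next
      cand <- best[i] + segLL(i, j) - if (i > 1) penalty else 0
      if (cand > best[j + 1]) { best[j + 1] <- cand; prev[j + 1] <- i }
    }
  }
  segs <- list()
  j <- n
  while (j >= 1) {
    i <- prev[j + 1]
    segs <- c(list(c(i, j)), segs)
    j <- i - 1
  }
  segdf <- do.call(rbind, lapply(seq_along(segs), function(i) {
    sg <- segs[[i]]
    data.frame(seg_id = i, start = sg[1], end = sg[2],
               start_date = binned$date[sg[1]], end_date = binned$date[sg[2]],
               n = sg[2] - sg[1] + 1,
               mean_step_km = mean(binned$step_km[sg[1]:sg[2]]))
  }))
  counts <- t(vapply(segs, function(sg) countsOf(sg[1], sg[2]),
                     numeric(V)))
  res <- list(records = binned, segments = segdf, counts = counts)
  class(res) <- "TrackSegments"
  res
}

#' Cluster segments into behavioural states by LDA
#'
#' Latent Dirichlet allocation over the segments' bin-count tables, fitted
#' by collapsed Gibbs sampling (symmetric priors, fixed sweep count and
#' seed) at `max_states` topics. The number of behavioural states is the
#' smallest K whose K largest topics account for more than 90% of the
#' observations; each segment is assigned its dominant topic. States are
#' relabelled deterministically by mean step length: the largest-step state
#' is `"transiting"`, the smallest `"area-restricted"` (any intermediate
#' states keep rank labels).
#'
#' Segments are pooled across individuals before clustering (pass a list of
#' `TrackSegments`): behavioural states are population-level constructs and
#' topic sharing across many segments is what makes the mixed-membership
#' model identifiable.
#'
#' @param segs a `TrackSegments` from [segmentTrack()], or a list of them
#'   (one per individual) to cluster jointly
#' @param max_states maximum number of latent states (default 6; capped at
#'   the number of segments)
#' @param alpha,beta symmetric Dirichlet priors (default 0.1)
#' @param sweeps Gibbs sweeps (default 2000)
#' @param coverage observation share defining the state count (default 0.9)
#' @param seed RNG seed for the sampler
#' @param restarts random restarts; the chain with the highest collapsed
#'   joint likelihood is kept (default 5)
#' @return list: `n_states`, `coverage_by_rank`, `segments` (with `track`
#'   and `state` columns), `days` data.frame(track, date, state, step_km),
#'   `topic_of_segment`
#' @export
clusterSegments <- function(segs, max_states = 6, alpha = 0.1, beta = 0.1,
                            sweeps = 2000, coverage = 0.9, seed = 1L,
                            restarts = 5) {
  if (inherits(segs, "TrackSegments")) segs <- list(segs)
  S <- attr(segs[[1]]$records, "n_step_bins")
  A <- attr(segs[[1]]$records, "n_angle_bins")
  V <- S + A
  segdf <- do.call(rbind, lapply(seq_along(segs), function(tr)
    cbind(track = tr, segs[[tr]]$segments)))
  nseg <- nrow(segdf)
  if (nseg < 2) stop("at least 2 segments required")
  K <- min(max_states, nseg)
  doc <- word <- integer(0)
  for (i in seq_len(nseg)) {
    binned <- segs[[segdf$track[i]]]$records
    tok <- segTokens(binned, segdf$start[i]:segdf$end[i], S)
    doc <- c(doc, rep(i - 1L, length(tok)))
    word <- c(word, tok - 1L)
  }
  # collapsed Gibbs is prone to local modes that split one behaviour over
  # two near-identical topics; run a few restarts and keep the chain with
  # the highest collapsed joint likelihood (deterministic given `seed`)
  logJoint <- function(fit) {
    lw <- sum(lgamma(fit$nkw + beta)) - sum(lgamma(fit$nk + V * beta))
    ld <- sum(lgamma(fit$ndk + alpha)) -
      sum(lgamma(rowSums(fit$ndk) + K * alpha))
    lw + ld
  }
  fit <- NULL
  best_lj <- -Inf
  for (r in 0:(restarts - 1)) {
    set.seed(seed + r)
    cand <- lda_gibbs(doc, word, K, V, alpha, beta, as.integer(sweeps))
    lj <- logJoint(cand)
    if (lj > best_lj) { best_lj <- lj; fit <- cand }
  }
  sizes <- sort(fit$nk, decreasing = TRUE)
  cum <- cumsum(sizes) / sum(sizes)
  n_states <- which(cum > coverage)[1]
  topic <- max.col(fit$ndk, ties.method = "first")
  # deterministic relabel by mean step length of the assigned segments
  used <- sort(unique(topic))
  stepsOf <- function(sel) unlist(lapply(which(sel), function(i)
    segs[[segdf$track[i]]]$records$step_km[segdf$start[i]:segdf$end[i]]))
  mean_step <- vapply(used, function(k) mean(stepsOf(topic == k)), numeric(1))
  ord <- order(mean_step)  # ascending: smallest step first
  lab <- character(length(used))
  lab[ord[1]] <- "area-restricted"
  lab[ord[length(ord)]] <- "transiting"
  if (length(used) > 2)
    lab[ord[-c(1, length(ord))]] <-
      sprintf("intermediate-%d", seq_len(length(used) - 2))
  state <- lab[match(topic, used)]
  segdf$state <- state
  days <- do.call(rbind, lapply(seq_len(nseg), function(i) {
    binned <- segs[[segdf$track[i]]]$records
    idx <- segdf$start[i]:segdf$end[i]
    data.frame(track = segdf$track[i], date = binned$date[idx],
               state = state[i], step_km = binned$step_km[idx])
  }))
  list(n_states = n_states, coverage_by_rank = cum, segments = segdf,
       days = days, topic_of_segment = topic)
}
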