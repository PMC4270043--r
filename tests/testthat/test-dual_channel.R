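test_that("photobleach correction removes a pure double-exponential", {
  t <- (0:999) * 0.18
  b <- 3000 * exp(-t / 40) + 2000 * exp(-t / 250) + 9000
  tr <- fluorescence_trace(b, 0.18)
  cor <- correct_photobleach(tr)
  expect_equal(cor$values, rep(b[1], 1000), tolerance = 0.01 * b[1] / b[1])
  expect_lt(max(abs(cor$values - b[1])), 0.01 * b[1])
  # residual linear trend reduced by >= 90%
  s0 <- abs(coef(lm(b ~ t))[2])
  s1 <- abs(coef(lm(cor$values ~ t))[2])
  expect_lt(s1, 0.1 * s0)
  # constant trace passes through unchanged (zero-amplitude solution)
  flat <- fluorescence_trace(rep(500, 200), 0.18)
  expect_equal(correct_photobleach(flat)$values, rep(500, 200),
               tolerance = 1e-6)
  expect_error(correct_photobleach(fluorescence_trace(1:10, 0.18)), "50")
})

test_that("event amplitudes survive photobleach correction", {
  set.seed(111)
  dt <- 0.18
  n <- 3000
  t <- (0:(n - 1)) * dt
  noise <- rnorm(n, 0, 8)
  signal <- rep(10000, n)
  onsets <- seq(400, 2800, by = 400)
  for (o in onsets) {
    seg <- o:n
    signal[seg] <- signal[seg] + 300 * exp(-(seg - o) * dt / 0.5)
  }
  bleach <- 0.25 * exp(-t / 60) + 0.25 * exp(-t / 500) + 0.5
  bleached <- fluorescence_trace(signal * bleach + noise, dt)
  clean <- fluorescence_trace(signal + noise, dt)
  fixed <- correct_photobleach(bleached)
  ev_clean <- detect_events(clean)
  ev_fixed <- detect_events(fixed)
  # recovery: at least 95% of the events found on the unbleached twin
  expect_gte(nrow(ev_fixed), ceiling(0.95 * nrow(ev_clean)))
  expect_gt(nrow(ev_clean), 3)
  shared <- intersect(ev_clean$onset_frame, ev_fixed$onset_frame)
  a1 <- ev_clean$amplitude[match(shared, ev_clean$onset_frame)]
  a2 <- ev_fixed$amplitude[match(shared, ev_fixed$onset_frame)]
  genuine <- a1 > 100  # exclude threshold-level noise hits
  expect_gt(sum(genuine), 3)
  expect_equal(mean(a2[genuine] / a1[genuine]), 1, tolerance = 0.05)
})

test_that("local baseline correction flattens linear drift", {
  dt <- 0.18
  # pure ramp: corrected segment is flat
  ramp <- fluorescence_trace(100 + 2 * (1:400) * dt, dt)
  ev <- list(onset_frame = 200L)
  cor <- local_baseline_correct(ramp, ev, lookback = 15)
  seg <- 120:400
  expect_lt(abs(coef(lm(cor$values[seg] ~ seg))[2]), 1e-9)
  # the baseline level itself is preserved
  look <- (200 - round(15 / dt)):199
  expect_equal(mean(cor$values[look]), mean(ramp$values[look]),
               tolerance = 1e-9)
  # flat input is untouched
  flat <- fluorescence_trace(rep(42, 400), dt)
  expect_equal(local_baseline_correct(flat, ev)$values, rep(42, 400))
  # ramp + step: step amplitude recovered within 2%
  v <- 100 + 1.5 * (1:400) * dt
  v[200:400] <- v[200:400] + 250
  cs <- local_baseline_correct(fluorescence_trace(v, dt), ev)
  step <- mean(cs$values[200:210]) - mean(cs$values[150:199])
  expect_equal(step, 250, tolerance = 0.02)
  # early onset: usable frames with a warning
  expect_warning(local_baseline_correct(ramp, list(onset_frame = 30L),
                                        lookback = 15), "lookback")
  expect_error(
    suppressWarnings(local_baseline_correct(ramp, list(onset_frame = 2L))),
    "baseline frames")
})

test_that("match_events pairs channels one-to-one inside the window", {
  pre <- data.frame(onset_frame = c(10L, 50L, 90L))
  post <- data.frame(onset_frame = c(10L, 50L, 90L))
  m <- match_events(pre, post, c(-1L, 1L))
  expect_equal(m$fraction_in_window, 1)
  expect_true(all(m$matches$frame_offset == 0L))
  # no post events at all
  expect_equal(match_events(pre, post[0, ], c(-1L, 1L))$fraction_in_window,
               0)
  expect_true(is.na(match_events(pre[0, ], post)$fraction_in_window))
  # each post event matches at most one pre event
  pre2 <- data.frame(onset_frame = c(10L, 11L))
  post2 <- data.frame(onset_frame = 10L)
  m2 <- match_events(pre2, post2, c(-1L, 1L))
  expect_equal(nrow(m2$matches), 1L)
  expect_equal(m2$fraction_in_window, 0.5)
  # offset ties resolve toward the later post frame
  m3 <- match_events(data.frame(onset_frame = 10L),
                     data.frame(onset_frame = c(9L, 11L)), c(-1L, 1L))
  expect_equal(m3$matches$frame_offset, 1L)
})

test_that("matching is symmetric and monotone in the window", {
  set.seed(121)
  pre <- data.frame(onset_frame = sort(sample(1:3000, 120)))
  post <- data.frame(onset_frame = sort(sample(1:3000, 110)))
  m <- match_events(pre, post, c(-2L, 2L))
  swapped <- match_events(post, pre, c(-2L, 2L))
  expect_equal(nrow(m$matches), nrow(swapped$matches))
  # widening the window never lowers the coupled fraction
  fr <- vapply(1:6, function(w) {
    match_events(pre, post, c(-1L, w))$fraction_in_window
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("the generative coupling rate is recovered from matched events", {
  base <- trace_sim_config(duration = 600, frame_interval = 0.18,
                           spont_rate = 5, noise_sd = 5, n_rois = 10,
                           seed = 500)
  cfg <- dual_sim_config(base = base, post_coupling_prob = 0.69,
                         post_frame_jitter = c("-1" = 1 / 3, "0" = 1 / 3,
                                               "1" = 1 / 3))
  truth <- simulate_dual(cfg)$truth
  # event tables straight from the ground truth of each channel
  res <- lapply(split(truth, truth$roi), function(d) {
    pre <- data.frame(onset_frame = event_frame(d$time_s, 0.18))
    cp <- d$coupled
    post <- data.frame(onset_frame = pre$onset_frame[cp] +
                         d$post_offset_frames[cp])
    m <- match_events(pre, post, c(-1L, 1L))
    c(nrow(m$matches), nrow(pre))
  })
  tot <- Reduce(`+`, res)
  n <- tot[2]
  expect_gt(n, 300)
  expect_lt(abs(tot[1] / n - 0.69), 1.96 * sqrt(0.69 * 0.31 / n) + 0.02)
})
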