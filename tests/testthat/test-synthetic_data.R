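test_that("event_waveform samples rise and decay correctly", {
  # hand-derived: exp(-0.12/0.371), exp(-0.24/0.371)
  expect_equal(event_waveform(1, 0.371, 0, c(0, 0.12, 0.24)),
               c(1, exp(-0.12 / 0.371), exp(-0.24 / 0.371)),
               tolerance = 1e-12)
  expect_equal(round(event_waveform(1, 0.371, 0, c(0, 0.12, 0.24)), 4),
               c(1, 0.7236, 0.5237))
  # folimycin: permanent step regardless of tau
  expect_equal(event_waveform(7.5, 123, 0, c(0, 0.12), mode = "folimycin"),
               c(7.5, 7.5))
  # zero amplitude, zero before onset, continuous onset phase
  expect_equal(event_waveform(0, 0.371, 0, c(0, 1, 2)), c(0, 0, 0))
  w <- event_waveform(10, 0.5, 0.25, c(0, 0.1, 0.2, 0.3, 0.4))
  expect_equal(w[1:3], c(0, 0, 0))
  expect_equal(w[4], 10 * exp(-0.05 / 0.5))
  expect_error(event_waveform(1, 0.371, 0, c(0, 0.2, 0.1)), "ascending")
  expect_error(event_waveform(1, -1, 0, c(0, 0.1)), "tau")
})

test_that("config constructors validate their invariants", {
  expect_error(trace_sim_config(duration = -1))
  expect_error(trace_sim_config(evoked_prob = 1.2))
  expect_error(trace_sim_config(bleach = list(fast_amp = 0.2)))
  expect_error(dual_sim_config(post_coupling_prob = 2))
  expect_error(dual_sim_config(post_frame_jitter = c("0" = 0.5)), "sum to 1")
  cfg <- trace_sim_config(mode = "tris")
  expect_s3_class(cfg, "trace_sim_config")
  expect_identical(cfg$mode, "tris")
})

test_that("pure-noise traces have the configured noise SD", {
  cfg <- trace_sim_config(duration = 660, spont_rate = 0, noise_sd = 212,
                          n_rois = 2, seed = 421)
  sim <- simulate_trace(cfg)
  expect_equal(nrow(sim$truth), 0L)
  for (tr in sim$traces) {
    expect_gt(length(tr$values), 5000)
    expect_equal(sd(tr$values), 212, tolerance = 0.05)
    expect_equal(mean(tr$values), cfg$baseline, tolerance = 0.01)
  }
})

test_that("spontaneous event counts follow the Poisson process", {
  cfg <- trace_sim_config(duration = 600, spont_rate = 0.5, noise_sd = 50,
                          n_rois = 100, seed = 2024)
  sim <- simulate_trace(cfg)
  # total ~ Poisson(500); 95% band ~ [456, 544], wider band for one seed
  expect_gt(nrow(sim$truth), 430)
  expect_lt(nrow(sim$truth), 570)
  expect_true(all(sim$truth$time_s >= 0 & sim$truth$time_s < 600))
  expect_true(all(sim$truth$amplitude > 0))
  expect_true(all(sim$truth$class == "spontaneous"))
})

test_that("rate conservation holds in expectation over seeds", {
  n_seeds <- 100
  counts <- vapply(seq_len(n_seeds), function(s) {
    cfg <- trace_sim_config(duration = 120, frame_interval = 0.12,
                            spont_rate = 2, noise_sd = 10, n_rois = 3,
                            stim_times = c(30, 60, 90), evoked_prob = 0.4,
                            seed = 9000 + s)
    nrow(simulate_trace(cfg)$truth)
  }, numeric(1))
  expected <- 2 / 60 * 120 * 3 + 0.4 * 3 * 3  # spont + evoked
  se <- sqrt(expected / n_seeds)  # Poisson-ish SE of the mean
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("evoked events occur only at stimulus times", {
  cfg <- trace_sim_config(duration = 300, spont_rate = 0, noise_sd = 20,
                          stim_times = seq(15, 285, by = 15),
                          evoked_prob = 0.5, n_rois = 20, seed = 77)
  sim <- simulate_trace(cfg)
  ev <- sim$truth[sim$truth$class == "evoked", ]
  expect_identical(nrow(sim$truth), nrow(ev))
  expect_true(all(ev$time_s %in% cfg$stim_times))
  # per-ROI successes ~ Binomial(19, 0.5): loose band on the pooled rate
  p_hat <- nrow(ev) / (20 * length(cfg$stim_times))
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / (20 * 19)))
})

test_that("folimycin mode yields an exact noiseless staircase", {
  cfg <- trace_sim_config(duration = 300, spont_rate = 2, noise_sd = 0,
                          mode = "folimycin", n_rois = 3, seed = 5)
  sim <- simulate_trace(cfg)
  for (tr in sim$traces) {
    v <- tr$values
    expect_true(all(diff(v) >= -1e-12))
    amps <- sim$truth$amplitude[sim$truth$roi == tr$roi_id]
    plateau_amps <- amps[sim$truth$time_s[sim$truth$roi == tr$roi_id] <
                           (length(v) - 1) * tr$frame_interval]
    expect_equal(v[length(v)] - cfg$baseline, sum(plateau_amps),
                 tolerance = 1e-12)
    # running staircase equals the running sum of true amplitudes
    tt <- trace_times(tr)
    onsets <- sim$truth$time_s[sim$truth$roi == tr$roi_id]
    expected <- cfg$baseline +
      vapply(tt, function(t) sum(amps[onsets <= t]), numeric(1))
    expect_equal(v, expected, tolerance = 1e-12)
  }
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- trace_sim_config(duration = 60, spont_rate = 3, n_rois = 2,
                          stim_times = c(20, 40), seed = 314)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$truth, b$truth)
  for (r in 1:2) expect_identical(a$traces[[r]]$values, b$traces[[r]]$values)
  d <- dual_sim_config(base = trace_sim_config(duration = 120,
                                               spont_rate = 4, seed = 15))
  expect_identical(simulate_dual(d)$truth, simulate_dual(d)$truth)
})

test_that("photobleaching multiplies the signal and starts at 1", {
  bl <- list(fast_amp = 0.2, fast_tau = 30, slow_amp = 0.3, slow_tau = 400)
  cfg <- trace_sim_config(duration = 300, spont_rate = 0, noise_sd = 0,
                          bleach = bl, n_rois = 1, seed = 1)
  v <- simulate_trace(cfg)$traces[[1]]$values
  expect_equal(v[1], cfg$baseline, tolerance = 1e-9)
  t <- (seq_along(v) - 1) * cfg$frame_interval
  expect_equal(v, cfg$baseline * (0.2 * exp(-t / 30) + 0.3 * exp(-t / 400)
                                  + 0.5), tolerance = 1e-12)
})

test_that("dual simulation couples pre and post channels as configured", {
  base <- trace_sim_config(duration = 600, frame_interval = 0.18,
                           spont_rate = 1, amp_mean = 303, amp_sd = 92,
                           noise_sd = 10, n_rois = 10, seed = 66)
  # deterministic coupling, no jitter: a post event in the same frame
  cfg <- dual_sim_config(base = base, post_coupling_prob = 1,
                         post_frame_jitter = c("0" = 1),
                         post_amp_sd = 10, post_noise_sd = 0)
  sim <- simulate_dual(cfg)
  expect_true(all(sim$truth$coupled))
  expect_true(all(sim$truth$post_offset_frames == 0L))
  for (tr in sim$post) {
    onsets <- sim$truth$time_s[sim$truth$roi == tr$roi_id]
    f <- event_frame(onsets, 0.18)
    f <- f[f > 1 & f <= length(tr$values)]
    if (length(f)) {
      expect_true(all(tr$values[f] - tr$values[f - 1] > 50))
    }
  }
  # AP-5 suppresses every post event but leaves pre events intact
  ap5 <- dual_sim_config(base = base, ap5_mode = TRUE, post_noise_sd = 0)
  sim5 <- simulate_dual(ap5)
  expect_gt(nrow(sim5$truth), 0)
  expect_true(!any(sim5$truth$coupled))
  for (tr in sim5$post) {
    expect_equal(tr$values, rep(cfg$post_baseline, length(tr$values)),
                 tolerance = 1e-12)
  }
})

test_that("coupling probability is recovered at the binomial scale", {
  base <- trace_sim_config(duration = 600, frame_interval = 0.18,
                           spont_rate = 5, noise_sd = 10, n_rois = 10,
                           seed = 404)
  cfg <- dual_sim_config(base = base, post_coupling_prob = 0.69)
  truth <- simulate_dual(cfg)$truth
  n <- nrow(truth)
  expect_gt(n, 300)
  p_hat <- mean(truth$coupled)
  expect_lt(abs(p_hat - 0.69), 1.96 * sqrt(0.69 * 0.31 / n))
  # jitter offsets drawn only from the configured support
  offs <- truth$post_offset_frames[truth$coupled]
  expect_true(all(offs %in% -1:5))
  # with the default coupling structure, ~69% of ALL pre events get a
  # post partner within +/-1 frame and ~83% within -1..+5
  cfg2 <- dual_sim_config(base = base)
  t2 <- simulate_dual(cfg2)$truth
  in1 <- mean(t2$coupled & t2$post_offset_frames %in% -1:1)
  in5 <- mean(t2$coupled)
  expect_lt(abs(in1 - 0.69), 3 * sqrt(0.69 * 0.31 / nrow(t2)))
  expect_lt(abs(in5 - 0.83), 3 * sqrt(0.83 * 0.17 / nrow(t2)))
})

test_that("sim config round-trips through a YAML file", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("duration: 120", "spont_rate: 1.5", "mode: tris",
               "seed: 12"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$duration, 120)
  expect_equal(cfg$spont_rate, 1.5)
  expect_identical(cfg$mode, "tris")
  writeLines(c("duration: 10", "bogus_key: 1"), path)
  expect_error(read_sim_config(path), "bogus_key")
})
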