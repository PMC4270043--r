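# Shared fixtures and independent oracles, built in code at test time.

# Brute-force reference detector: a frame-by-frame transcription of the
# detection rule using plain mean()/sd(), independent of the package's
# cumulative-sum implementation. Returns onset frames and amplitudes.
brute_force_detect <- function(values, params = detection_params()) {
  n <- length(values)
  L3 <- params$avg_len
  L17 <- params$baseline_len
  S <- params$stability_len
  hit <- logical(n)
  stat <- rep(NA_real_, n)
  bmean <- rep(NA_real_, n)
  bsd <- rep(NA_real_, n)
  for (f in seq_len(n)) {
    if (f < L17 + 1L || f + L3 - 1L > n) next
    b <- values[(f - L17):(f - 1L)]
    bmean[f] <- mean(b)
    bsd[f] <- stats::sd(b)
    stat[f] <- mean(values[f:(f + L3 - 1L)]) - bmean[f]
    hit[f] <- stat[f] > params$k_sd * max(bsd[f], params$sd_floor)
  }
  onsets <- integer(0)
  amps <- numeric(0)
  for (f in which(hit)) {
    if (f <= S) next
    if (any(hit[max(1L, f - S):(f - 1L)])) next
    span <- f:min(f + L3 - 1L, n - L3 + 1L)
    span <- span[!is.na(stat[span])]
    o <- span[which.max(stat[span])]
    thr <- bmean[o] + params$k_sd * max(bsd[o], params$sd_floor)
    j0 <- o + L3
    j1 <- min(o + L3 + params$confirm_span - 1L, n)
    ok <- j0 <= j1 && sum(values[j0:j1] > thr) >= params$confirm_points
    if (!ok) next
    onsets <- c(onsets, o)
    amps <- c(amps, stat[o])
  }
  data.frame(onset_frame = onsets, amplitude = amps)
}

# Draw from a mixture of Gaussians at quantal multiples of (q, sigma_q);
# the constrained family the mixture fit assumes.
rquantal_mix <- function(n, weights, multipliers, q = 623, sigma_q = 122) {
  k <- sample(length(weights), n, replace = TRUE, prob = weights)
  stats::rnorm(n, q * multipliers[k], sigma_q * multipliers[k])
}

# First frame at or after a continuous event time (1-based).
event_frame <- function(time_s, frame_interval) {
  ceiling(time_s / frame_interval) + 1L
}

# Expected ratio of the detected 3-point amplitude to the true amplitude
# for exponential events with uniform sub-frame onset phase:
# E[exp(-u dt/tau)] * mean(exp(-(0:2) dt/tau)).
expected_amp_attenuation <- function(tau, dt) {
  phase <- tau / dt * (1 - exp(-dt / tau))
  phase * mean(exp(-(0:2) * dt / tau))
}

# Match detections to ground truth by ROI and onset frame (+/- tol
# frames); returns per-truth-event logical hits and the matched
# amplitude ratio.
match_detections <- function(truth, events, frame_interval, tol = 2L) {
  truth$frame <- event_frame(truth$time_s, frame_interval)
  hit <- logical(nrow(truth))
  ratio <- rep(NA_real_, nrow(truth))
  used <- rep(FALSE, nrow(events))
  for (i in seq_len(nrow(truth))) {
    j <- which(events$roi_id == truth$roi[i] & !used &
                 abs(events$onset_frame - truth$frame[i]) <= tol)
    if (length(j)) {
      hit[i] <- TRUE
      used[j[1]] <- TRUE
      ratio[i] <- events$amplitude[j[1]] / truth$amplitude[i]
    }
  }
  list(hit = hit, ratio = ratio, n_unmatched_detections = sum(!used))
}

# Per-ROI labeled event tables with independently drawn spontaneous rate
# and evoked probability; exercises classify_events/synapse_summary
# without trace-level simulation.
simulate_summary_population <- function(n_rois, duration = 600,
                                        n_stimuli = 20,
                                        rate_mean = 0.5, prob_mean = 0.15) {
  stim_times <- seq(15, duration - 15, length.out = n_stimuli)
  out <- vector("list", n_rois)
  for (r in seq_len(n_rois)) {
    rate <- stats::rgamma(1, shape = 4, rate = 4 / rate_mean)
    prob <- stats::rbeta(1, prob_mean * 20, (1 - prob_mean) * 20)
    n_sp <- stats::rpois(1, rate * duration / 60)
    t_sp <- stats::runif(n_sp, 0, duration)
    # keep spontaneous times clear of the evoked windows
    for (k in seq_len(5)) {
      bad <- vapply(t_sp, function(t) any(abs(t - stim_times) <= 1),
                    logical(1))
      if (!any(bad)) break
      t_sp[bad] <- stats::runif(sum(bad), 0, duration)
    }
    hit <- stats::runif(n_stimuli) < prob
    times <- c(t_sp, stim_times[hit] + 0.3)
    ev <- data.frame(
      roi_id = rep(paste0("roi", r), length(times)),
      onset_time = times,
      amplitude = stats::rnorm(length(times), 623, 122))
    ev <- classify_events(ev, stim_times, window = 1)
    out[[r]] <- synapse_summary(ev, duration = duration,
                                n_stimuli = n_stimuli,
                                roi_id = paste0("roi", r))
  }
  do.call(rbind, out)
}
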