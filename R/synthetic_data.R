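#' Configuration for synthetic single-channel trace simulation
#'
#' Defines the generative model for ground-truth-labeled pHluorin-like
#' traces: a homogeneous Poisson process of spontaneous quantal fusion
#' events on each ROI, optional stimulus-locked evoked events, Gaussian
#' quantal amplitudes (truncated at 0), single-exponential re-acidification
#' decay, additive white Gaussian baseline noise, and optional
#' multiplicative double-exponential photobleaching.
#'
#' Defaults reproduce the 2 mM Ca2+ spontaneous condition: quantal mean
#' 623 a.u. with SD 122 a.u., decay tau 0.371 s, baseline noise SD
#' 212 a.u., ~0.5 events/bouton/min, frames every 0.12 s (~8 Hz). The
#' baseline of 16400 a.u. puts a quantal event at ~3.8% dF/F. Modes:
#' `"normal"` (decaying events), `"folimycin"` (v-ATPase blocked, no
#' re-acidification: events are permanent steps and the trace is a
#' staircase), `"tris"` (buffered re-acidification: slower decay,
#' `tris_tau`, default 0.55 s).
#'
#' @param duration recording duration in seconds.
#' @param frame_interval frame interval in seconds.
#' @param spont_rate spontaneous event rate, events per minute per ROI.
#' @param amp_mean,amp_sd quantal amplitude mean / SD (a.u.).
#' @param decay_tau spontaneous decay time constant (s).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param baseline resting fluorescence (a.u.); sets dF/F scale.
#' @param mode one of `"normal"`, `"folimycin"`, `"tris"`.
#' @param tris_tau decay tau used in `"tris"` mode (s).
#' @param bleach `NULL` for no photobleaching, else a list/vector with
#'   `fast_amp`, `fast_tau`, `slow_amp`, `slow_tau`; the multiplicative
#'   bleach factor is `fast_amp*exp(-t/fast_tau) + slow_amp*exp(-t/slow_tau)
#'   + (1 - fast_amp - slow_amp)` so it starts at 1.
#' @param stim_times numeric vector of stimulus times (s), sorted.
#' @param evoked_prob per-stimulus probability of an evoked fusion event.
#' @param evoked_tau decay tau of evoked events (s); evoked single-vesicle
#'   events re-acidify more slowly than spontaneous ones.
#' @param n_rois number of ROIs to simulate.
#' @param seed integer seed or `NULL`.
#' @return object of class `trace_sim_config` (a validated list).
#' @export
trace_sim_config <- function(duration = 600,
                             frame_interval = 0.12,
                             spont_rate = 0.5,
                             amp_mean = 623,
                             amp_sd = 122,
                             decay_tau = 0.371,
                             noise_sd = 212,
                             baseline = 16400,
                             mode = c("normal", "folimycin", "tris"),
                             tris_tau = 0.55,
                             bleach = NULL,
                             stim_times = numeric(0),
                             evoked_prob = 0.15,
                             evoked_tau = 0.83,
                             n_rois = 1L,
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(duration > 0, frame_interval > 0, spont_rate >= 0,
            amp_sd >= 0, amp_mean > 0, noise_sd >= 0, baseline >= 0,
            evoked_prob >= 0, evoked_prob <= 1,
            decay_tau > 0, tris_tau > 0, evoked_tau > 0, n_rois >= 1)
  if (length(stim_times)) {
    stopifnot(all(stim_times >= 0), all(stim_times <= duration),
              !is.unsorted(stim_times))
  }
  if (!is.null(bleach)) {
    bleach <- as.list(bleach)
    need <- c("fast_amp", "fast_tau", "slow_amp", "slow_tau")
    if (!all(need %in% names(bleach))) {
      stop("bleach needs fields: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    stopifnot(bleach$fast_tau > 0, bleach$slow_tau > 0,
              bleach$fast_amp >= 0, bleach$slow_amp >= 0,
              bleach$fast_amp + bleach$slow_amp <= 1)
  }
  structure(
    list(duration = duration, frame_interval = frame_interval,
         spont_rate = spont_rate, amp_mean = amp_mean, amp_sd = amp_sd,
         decay_tau = decay_tau, noise_sd = noise_sd, baseline = baseline,
         mode = mode, tris_tau = tris_tau, bleach = bleach,
         stim_times = as.numeric(stim_times), evoked_prob = evoked_prob,
         evoked_tau = evoked_tau, n_rois = as.integer(n_rois),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "trace_sim_config")
}

#' Configuration for dual-channel (pre/post) simulation
#'
#' Wraps a presynaptic [trace_sim_config()] (the pHTomato-like red channel)
#' and adds the postsynaptic GCaMP-like green channel: each presynaptic
#' fusion event triggers a postsynaptic Ca2+ event with probability
#' `post_coupling_prob`, shifted by an integer frame offset drawn from
#' `post_frame_jitter`. `ap5_mode` emulates NMDA-receptor block: all
#' postsynaptic events are suppressed, presynaptic events are untouched.
#'
#' Defaults follow the dual-colour recordings: 0.18 s per interleaved
#' acquisition cycle (both channels share one timestamp per cycle),
#' presynaptic amplitude 303 +/- 92 a.u. and postsynaptic 170 +/-
#' 50 a.u. The default coupling emulates the observed coincidence
#' structure — 69% of presynaptic events answered within +/-1 frame and
#' 83% within -1..+5 frames — as an overall coupling probability of 0.83
#' whose frame jitter places 0.831 of its mass in [-1, 1] and the rest
#' on lags of 2-5 frames.
#'
#' @param base a [trace_sim_config()] for the pre channel.
#' @param post_coupling_prob probability a pre event elicits a post event.
#' @param post_frame_jitter named numeric vector of probabilities over
#'   integer frame offsets, e.g. `c("-1" = 0.25, "0" = 0.5, "1" = 0.25)`.
#'   A fusion event halfway through an acquisition cycle can register one
#'   frame early in the post channel, hence offsets may be negative.
#' @param post_amp_mean,post_amp_sd post-channel amplitude mean / SD (a.u.).
#' @param post_tau post-channel decay tau (s).
#' @param post_noise_sd post-channel additive noise SD (a.u.).
#' @param post_baseline post-channel resting fluorescence (a.u.).
#' @param ap5_mode logical; suppress every post event.
#' @return object of class `dual_sim_config`.
#' @export
dual_sim_config <- function(base = trace_sim_config(frame_interval = 0.18,
                                                    amp_mean = 303,
                                                    amp_sd = 92),
                            post_coupling_prob = 0.83,
                            post_frame_jitter = c("-1" = 0.20, "0" = 0.43,
                                                  "1" = 0.201, "2" = 0.06,
                                                  "3" = 0.05, "4" = 0.03,
                                                  "5" = 0.029),
                            post_amp_mean = 170,
                            post_amp_sd = 50,
                            post_tau = 0.5,
                            post_noise_sd = base$noise_sd,
                            post_baseline = base$baseline,
                            ap5_mode = FALSE) {
  stopifnot(inherits(base, "trace_sim_config"),
            post_coupling_prob >= 0, post_coupling_prob <= 1,
            post_amp_mean > 0, post_amp_sd >= 0, post_tau > 0,
            post_noise_sd >= 0, is.logical(ap5_mode))
  if (is.null(names(post_frame_jitter)) ||
      any(is.na(suppressWarnings(as.integer(names(post_frame_jitter)))))) {
    stop("post_frame_jitter must be named by integer frame offsets",
         call. = FALSE)
  }
  if (any(post_frame_jitter < 0) || abs(sum(post_frame_jitter) - 1) > 1e-8) {
    stop("post_frame_jitter probabilities must be nonnegative and sum to 1",
         call. = FALSE)
  }
  structure(
    list(base = base, post_coupling_prob = post_coupling_prob,
         post_frame_jitter = post_frame_jitter,
         post_amp_mean = post_amp_mean, post_amp_sd = post_amp_sd,
         post_tau = post_tau, post_noise_sd = post_noise_sd,
         post_baseline = post_baseline, ap5_mode = isTRUE(ap5_mode)),
    class = "dual_sim_config")
}

#' Sampled waveform of one fusion event
#'
#' Evaluates a single quantal event at the given frame times: zero before
#' onset; in `"normal"`/`"tris"` mode an instantaneous rise followed by
#' single-exponential re-acidification decay
#' `amplitude * exp(-(t - onset)/tau)`; in `"folimycin"` mode a permanent
#' step of height `amplitude` (no re-acidification, so no decay).
#' Onsets are continuous times: the value at each frame uses the true
#' elapsed time since onset, preserving sub-frame phase.
#'
#' @param amplitude event amplitude (a.u.).
#' @param tau decay time constant (s); ignored in folimycin mode.
#' @param onset onset time (s).
#' @param frame_times ascending numeric vector of frame times (s).
#' @param mode `"normal"`, `"tris"` or `"folimycin"`.
#' @return numeric vector of sampled values, same length as `frame_times`.
#' @export
#' @examples
#' event_waveform(1, 0.371, 0, c(0, 0.12, 0.24))
event_waveform <- function(amplitude, tau, onset, frame_times,
                           mode = c("normal", "tris", "folimycin")) {
  mode <- match.arg(mode)
  if (is.unsorted(frame_times, strictly = TRUE)) {
    stop("frame_times must be strictly ascending", call. = FALSE)
  }
  if (mode != "folimycin" && (!is.finite(tau) || tau <= 0)) {
    stop("tau must be > 0 outside folimycin mode", call. = FALSE)
  }
  dt <- frame_times - onset
  on <- dt >= 0
  out <- numeric(length(frame_times))
  if (mode == "folimycin") {
    out[on] <- amplitude
  } else {
    out[on] <- amplitude * exp(-dt[on] / tau)
  }
  out
}

# Draw from Normal(mean, sd) truncated at 0 by redraw; degenerate sd = 0
# returns the mean. Amplitudes are physically nonnegative; at mean/sd ~ 5
# the truncation is negligible.
truncated_normal <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

bleach_factor <- function(bleach, t) {
  if (is.null(bleach)) return(rep(1, length(t)))
  with(bleach,
       fast_amp * exp(-t / fast_tau) + slow_amp * exp(-t / slow_tau) +
         (1 - fast_amp - slow_amp))
}

empty_truth <- function() {
  data.frame(roi = character(0), time_s = numeric(0),
             amplitude = numeric(0), class = character(0),
             coupled = logical(0), post_offset_frames = integer(0),
             stringsAsFactors = FALSE)
}

# Event times/amplitudes/classes for one ROI under cfg (no noise, no trace).
sim_roi_events <- function(cfg) {
  n_sp <- stats::rpois(1, cfg$spont_rate / 60 * cfg$duration)
  t_sp <- sort(stats::runif(n_sp, 0, cfg$duration))
  a_sp <- truncated_normal(n_sp, cfg$amp_mean, cfg$amp_sd)
  t_ev <- numeric(0); a_ev <- numeric(0)
  if (length(cfg$stim_times)) {
    hit <- stats::runif(length(cfg$stim_times)) < cfg$evoked_prob
    t_ev <- cfg$stim_times[hit]
    a_ev <- truncated_normal(sum(hit), cfg$amp_mean, cfg$amp_sd)
  }
  data.frame(time_s = c(t_sp, t_ev), amplitude = c(a_sp, a_ev),
             class = rep(c("spontaneous", "evoked"),
                         c(length(t_sp), length(t_ev))),
             stringsAsFactors = FALSE)
}

# Render a noiseless signal (baseline + event waveforms) for one ROI.
render_signal <- function(cfg, ev, frame_times) {
  sig <- rep(cfg$baseline, length(frame_times))
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      tau <- switch(cfg$mode,
                    normal = if (ev$class[i] == "evoked") cfg$evoked_tau
                             else cfg$decay_tau,
                    tris = if (ev$class[i] == "evoked") cfg$evoked_tau
                           else cfg$tris_tau,
                    folimycin = Inf)
      sig <- sig + event_waveform(ev$amplitude[i], tau, ev$time_s[i],
                                  frame_times, mode = cfg$mode)
    }
  }
  sig
}

#' Simulate ground-truth-labeled fluorescence traces
#'
#' Generates `cfg$n_rois` traces under the generative model of
#' [trace_sim_config()] together with the ground-truth event log.
#' Spontaneous event times are a homogeneous Poisson process at
#' `spont_rate`; each stimulus in `stim_times` independently produces an
#' evoked event with probability `evoked_prob`; amplitudes are i.i.d.
#' truncated Gaussian; photobleaching (if configured) multiplies the
#' noiseless signal; i.i.d. Gaussian noise is added last. With a non-NULL
#' `cfg$seed` the output is bit-reproducible.
#'
#' @param cfg a [trace_sim_config()].
#' @return list with `traces` (list of [fluorescence_trace()]) and
#'   `truth` (data.frame: `roi`, `time_s`, `amplitude`, `class`,
#'   `coupled`, `post_offset_frames`).
#' @export
simulate_trace <- function(cfg) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_frames <- floor(cfg$duration / cfg$frame_interval)
  frame_times <- (seq_len(n_frames) - 1) * cfg$frame_interval
  bl <- bleach_factor(cfg$bleach, frame_times)
  traces <- vector("list", cfg$n_rois)
  truths <- vector("list", cfg$n_rois)
  for (r in seq_len(cfg$n_rois)) {
    id <- paste0("roi", r)
    ev <- sim_roi_events(cfg)
    sig <- render_signal(cfg, ev, frame_times) * bl
    vals <- sig + stats::rnorm(n_frames, 0, cfg$noise_sd)
    traces[[r]] <- fluorescence_trace(vals, cfg$frame_interval, roi_id = id)
    truths[[r]] <- if (nrow(ev)) {
      data.frame(roi = id, ev, coupled = NA, post_offset_frames = NA,
                 stringsAsFactors = FALSE)
    } else NULL
  }
  truth <- do.call(rbind, c(truths, list(empty_truth())))
  truth <- truth[order(truth$roi, truth$time_s), , drop = FALSE]
  rownames(truth) <- NULL
  list(traces = traces, truth = truth)
}

#' Simulate coupled pre/post dual-channel traces
#'
#' Simulates the presynaptic (red, pHTomato-like) channel from
#' `cfg$base`, then couples each presynaptic event to a postsynaptic
#' (green, GCaMP-like) event with probability `post_coupling_prob`,
#' offset by an integer number of frames drawn from `post_frame_jitter`.
#' In `ap5_mode` no post events are generated (NMDA receptors blocked)
#' while the pre channel is unchanged.
#'
#' @param cfg a [dual_sim_config()].
#' @return list with `pre` and `post` (lists of [fluorescence_trace()])
#'   and `truth` (the pre-channel event log with `coupled` and
#'   `post_offset_frames` filled in).
#' @export
simulate_dual <- function(cfg) {
  stopifnot(inherits(cfg, "dual_sim_config"))
  base <- cfg$base
  if (!is.null(base$seed)) set.seed(base$seed)
  n_frames <- floor(base$duration / base$frame_interval)
  frame_times <- (seq_len(n_frames) - 1) * base$frame_interval
  bl <- bleach_factor(base$bleach, frame_times)
  offs <- as.integer(names(cfg$post_frame_jitter))
  pre <- vector("list", base$n_rois)
  post <- vector("list", base$n_rois)
  truths <- vector("list", base$n_rois)
  for (r in seq_len(base$n_rois)) {
    id <- paste0("roi", r)
    ev <- sim_roi_events(base)
    n_ev <- nrow(ev)
    coupled <- logical(n_ev); poff <- rep(NA_integer_, n_ev)
    post_sig <- rep(cfg$post_baseline, n_frames)
    if (n_ev && !cfg$ap5_mode) {
      coupled <- stats::runif(n_ev) < cfg$post_coupling_prob
      if (any(coupled)) {
        poff[coupled] <- sample(offs, sum(coupled), replace = TRUE,
                                prob = cfg$post_frame_jitter)
        amp_post <- truncated_normal(sum(coupled), cfg$post_amp_mean,
                                     cfg$post_amp_sd)
        t_post <- ev$time_s[coupled] + poff[coupled] * base$frame_interval
        keep <- t_post >= 0 & t_post < base$duration
        for (i in which(keep)) {
          post_sig <- post_sig +
            event_waveform(amp_post[i], cfg$post_tau, t_post[i],
                           frame_times, mode = "normal")
        }
      }
    }
    pre_sig <- render_signal(base, ev, frame_times) * bl
    pre[[r]] <- fluorescence_trace(
      pre_sig + stats::rnorm(n_frames, 0, base$noise_sd),
      base$frame_interval, roi_id = id, channel = "red")
    post[[r]] <- fluorescence_trace(
      post_sig * bl + stats::rnorm(n_frames, 0, cfg$post_noise_sd),
      base$frame_interval, roi_id = id, channel = "green")
    truths[[r]] <- if (n_ev) {
      data.frame(roi = id, ev, coupled = coupled,
                 post_offset_frames = poff, stringsAsFactors = FALSE)
    } else NULL
  }
  truth <- do.call(rbind, c(truths, list(empty_truth())))
  truth <- truth[order(truth$roi, truth$time_s), , drop = FALSE]
  rownames(truth) <- NULL
  list(pre = pre, post = post, truth = truth)
}

#' Read a simulation config from a flat YAML/JSON key-value file
#'
#' Keys match the arguments of [trace_sim_config()]; `bleach` may be a
#' nested mapping with `fast_amp`, `fast_tau`, `slow_amp`, `slow_tau`.
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return a [trace_sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files",
         call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(trace_sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(trace_sim_config, vals)
}

#' Write a ground-truth event log as CSV
#'
#' @param truth ground-truth data.frame from [simulate_trace()] /
#'   [simulate_dual()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
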