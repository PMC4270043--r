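#' Detection parameters for fluorescence transients
#'
#' Parameters of the moving-average threshold criterion used to call
#' fusion events in a fluorescence trace. At ~8 Hz sampling the defaults
#' correspond to: a 3-point rise average compared against 2x the standard
#' deviation of the 17 points (~2.1 s) immediately prior, a stability
#' requirement over the preceding 78 frames (~10 s), and at least one
#' confirming point after the initial rise (excluding isolated single-frame
#' spikes whose decay could not be fit).
#'
#' @param avg_len frames averaged for the rise statistic (default 3).
#' @param baseline_len frames in the trailing baseline window (default 17).
#' @param k_sd threshold multiplier on the baseline SD (default 2).
#' @param stability_len frames of required pre-event stability (default 78).
#' @param confirm_points number of additional supra-threshold points
#'   required after the rise window (default 1).
#' @param confirm_span frames after the rise window searched for confirming
#'   points (default 5).
#' @param sd_floor minimum baseline SD (a.u.) used in the threshold, to
#'   avoid the zero-SD degeneracy on noiseless synthetic traces.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(avg_len = 3L, baseline_len = 17L, k_sd = 2,
                             stability_len = 78L, confirm_points = 1L,
                             confirm_span = 5L, sd_floor = 1e-6) {
  stopifnot(avg_len >= 1, baseline_len >= 2, k_sd > 0,
            stability_len >= baseline_len, confirm_points >= 0,
            confirm_span >= confirm_points, sd_floor >= 0)
  structure(list(avg_len = as.integer(avg_len),
                 baseline_len = as.integer(baseline_len),
                 k_sd = k_sd,
                 stability_len = as.integer(stability_len),
                 confirm_points = as.integer(confirm_points),
                 confirm_span = as.integer(confirm_span),
                 sd_floor = sd_floor),
            class = "detection_params")
}

# Rolling statistics underlying the detection criterion. For frame f
# (1-based candidate onset):
#   baseline: values[(f - baseline_len) .. (f - 1)], mean bmean and sample
#     SD bsd (floored at sd_floor);
#   rise statistic: mean(values[f .. (f + avg_len - 1)]) - bmean;
#   raw hit: statistic > k_sd * bsd (with floored SD).
# Frames without a full baseline or rise window are not hits.
detection_stats <- function(values, params) {
  n <- length(values)
  L3 <- params$avg_len; L17 <- params$baseline_len
  m3 <- rep(NA_real_, n); bmean <- rep(NA_real_, n); bsd <- rep(NA_real_, n)
  if (n >= L3) {
    cs <- c(0, cumsum(values))
    idx <- seq_len(n - L3 + 1L)
    m3[idx] <- (cs[idx + L3] - cs[idx]) / L3
  }
  if (n >= L17 + 1L) {
    cs <- c(0, cumsum(values))
    cs2 <- c(0, cumsum(values^2))
    f <- (L17 + 1L):n
    s <- cs[f] - cs[f - L17]
    s2 <- cs2[f] - cs2[f - L17]
    bmean[f] <- s / L17
    v <- (s2 - s^2 / L17) / (L17 - 1L)
    bsd[f] <- sqrt(pmax(v, 0))
  }
  stat <- m3 - bmean
  bsd_f <- pmax(bsd, params$sd_floor)
  hit <- !is.na(stat) & !is.na(bsd_f) & stat > params$k_sd * bsd_f
  list(m3 = m3, bmean = bmean, bsd = bsd, bsd_floored = bsd_f,
       stat = stat, hit = hit)
}

empty_events <- function() {
  data.frame(roi_id = character(0), onset_frame = integer(0),
             onset_time = numeric(0), amplitude = numeric(0),
             dff = numeric(0), baseline_mean = numeric(0),
             baseline_sd = numeric(0), polarity = integer(0),
             stringsAsFactors = FALSE)
}

detect_core <- function(values, params, frame_interval, t0, roi_id,
                        polarity) {
  n <- length(values)
  L3 <- params$avg_len
  S <- params$stability_len
  if (n <= S + L3) {
    stop("trace too short for detection: need more than stability_len + ",
         "avg_len = ", S + L3, " frames, got ", n, call. = FALSE)
  }
  st <- detection_stats(values, params)
  out <- empty_events()
  cand <- which(st$hit)
  cand <- cand[cand > S & cand + L3 - 1L <= n]
  for (f in cand) {
    lo <- max(1L, f - S)
    if (f > lo && any(st$hit[lo:(f - 1L)])) next  # unstable baseline
    # With a trailing rise window the criterion can first trip while only
    # part of the window covers the event; refine the onset to the frame
    # with the largest rise statistic within the initial avg_len frames,
    # so the reported onset/amplitude reflect the full rise.
    span <- f:min(f + L3 - 1L, n - L3 + 1L)
    span <- span[!is.na(st$stat[span])]
    o <- span[which.max(st$stat[span])]
    thr <- st$bmean[o] + params$k_sd * st$bsd_floored[o]
    j0 <- o + L3
    j1 <- min(o + L3 + params$confirm_span - 1L, n)
    n_confirm <- if (j0 <= j1) sum(values[j0:j1] > thr) else 0L
    if (n_confirm < params$confirm_points) next
    out <- rbind(out, data.frame(
      roi_id = roi_id, onset_frame = o,
      onset_time = t0 + (o - 1L) * frame_interval,
      amplitude = st$stat[o],
      dff = if (st$bmean[o] > 0) st$stat[o] / st$bmean[o] else NA_real_,
      baseline_mean = st$bmean[o], baseline_sd = st$bsd[o],
      polarity = polarity, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Detect spontaneous fluorescence transients
#'
#' Calls fusion events with the moving-average threshold criterion: an
#' event onset is the frame `f` where the mean of the `avg_len` frames
#' starting at `f` exceeds the mean of the `baseline_len` trailing frames
#' by more than `k_sd` times their standard deviation, provided
#'
#' * the preceding `stability_len` frames are stable — no frame in that
#'   window itself satisfies the rise criterion (this also enforces
#'   non-overlap: a new event cannot start within the stability window of
#'   an earlier rise), and
#' * at least `confirm_points` of the `confirm_span` frames following the
#'   rise window also exceed `baseline_mean + k_sd * SD` (rejecting
#'   single-point spikes).
#'
#' The reported amplitude is the rise statistic itself
#' (`mean(rise window) - baseline_mean`); `dff` is amplitude over
#' `baseline_mean`. The baseline mean and SD use the same
#' `baseline_len`-frame window. Because the rise window trails the onset,
#' the criterion can first trip while the window only partly covers the
#' event; the emitted onset is therefore refined to the frame with the
#' largest rise statistic within the first `avg_len` frames of the
#' excursion, so amplitude reflects the fully risen 3-point average.
#'
#' @param trace a [fluorescence_trace()].
#' @param params a [detection_params()].
#' @return data.frame of detected events with columns `roi_id`,
#'   `onset_frame` (1-based), `onset_time` (s), `amplitude` (a.u.),
#'   `dff`, `baseline_mean`, `baseline_sd`, `polarity` (+1).
#' @seealso [detect_negative()] for the sign-flipped false-positive
#'   control, [noise_amplitudes()] for the matched noise statistic.
#' @export
detect_events <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(params, "detection_params"))
  detect_core(trace$values, params, trace$frame_interval, trace$t0,
              trace$roi_id, polarity = 1L)
}

#' Detect negative-going "events" (false-positive control)
#'
#' Applies the identical criterion of [detect_events()] to the negated
#' trace: hits are excursions below the baseline by more than
#' `k_sd` standard deviations. Because baseline noise is symmetric while
#' genuine fusion events are strictly positive, the negative hit rate
#' estimates the false-positive rate of the detector.
#'
#' @inheritParams detect_events
#' @return data.frame as in [detect_events()], with `polarity = -1` and
#'   `amplitude` carrying the magnitude of the negative excursion;
#'   `baseline_mean` and `dff` are reported on the original (unnegated)
#'   scale.
#' @export
detect_negative <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(params, "detection_params"))
  ev <- detect_core(-trace$values, params, trace$frame_interval, trace$t0,
                    trace$roi_id, polarity = -1L)
  if (nrow(ev)) {
    ev$baseline_mean <- -ev$baseline_mean
    ev$dff <- ifelse(ev$baseline_mean > 0,
                     ev$amplitude / ev$baseline_mean, NA_real_)
  }
  ev
}

#' Noise amplitudes from random non-event periods
#'
#' Draws the detection statistic (mean of `avg_len` points minus mean of
#' the `baseline_len` points prior) at `n` uniformly random positions that
#' do not overlap any detected event, giving the amplitude distribution of
#' noise against which event amplitudes are compared.
#'
#' @inheritParams detect_events
#' @param n number of noise amplitudes to draw.
#' @param seed optional integer seed for the random positions.
#' @param events optional precomputed data.frame from [detect_events()];
#'   detected fresh when `NULL`.
#' @return numeric vector of `n` noise amplitudes (a.u.).
#' @export
noise_amplitudes <- function(trace, params = detection_params(), n = 1000L,
                             seed = NULL, events = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (is.null(events)) events <- detect_events(trace, params)
  st <- detection_stats(trace$values, params)
  len <- length(trace$values)
  ok <- which(!is.na(st$stat))
  if (nrow(events)) {
    # exclude windows touching a detected event (baseline through decay)
    excl_lo <- events$onset_frame - params$baseline_len - params$avg_len
    excl_hi <- events$onset_frame + 40L
    for (i in seq_along(excl_lo)) {
      ok <- ok[ok < excl_lo[i] | ok > excl_hi[i]]
    }
  }
  if (length(ok) < n) {
    stop("only ", length(ok), " non-event positions available, need ", n,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pos <- sample(ok, n, replace = FALSE)
  st$stat[pos]
}
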