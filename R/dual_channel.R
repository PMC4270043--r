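#' Photobleach correction by double-exponential detrending
#'
#' Fits a double-exponential bleach model
#' `B(t) = a1*exp(-t/tau1) + a2*exp(-t/tau2) + c` to the full trace by
#' Levenberg-Marquardt least squares and linearizes the recording against
#' it. Needed for probes with high surface expression (pHTomato, GCaMP)
#' whose recordings drift downward over minutes of imaging. Falls back to
#' a single exponential (and finally to a linear trend) when the
#' double-exponential fit does not converge.
#'
#' Photobleaching scales emitted fluorescence, so the default correction
#' is divisive: `values * B(0) / B(t)`, which restores both the baseline
#' level and the amplitudes of transient events riding on the bleached
#' baseline. The additive form `values - B(t) + B(0)` (`method =
#' "subtract"`) flattens the baseline equally well but leaves event
#' amplitudes attenuated by the bleach factor at their onset time.
#'
#' @param trace a [fluorescence_trace()] of >= 50 frames.
#' @param method `"divide"` (default) or `"subtract"`, see above.
#' @return the corrected [fluorescence_trace()], with attributes
#'   `bleach_model` (`"double_exp"`, `"single_exp"` or `"linear"`) and
#'   `bleach_fit` (named coefficients).
#' @export
correct_photobleach <- function(trace, method = c("divide", "subtract")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "fluorescence_trace"))
  y <- trace$values
  n <- length(y)
  if (n < 50L) stop("need at least 50 frames for bleach fitting",
                    call. = FALSE)
  t <- trace_times(trace) - trace$t0
  total <- t[n]
  drop <- max(y[1] - y[n], 0)
  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + c,
      start = list(a1 = drop * 0.5 + 1e-6, tau1 = total / 10,
                   a2 = drop * 0.5 + 1e-6, tau2 = total, c = y[n]),
      lower = c(a1 = 0, tau1 = total * 1e-4, a2 = 0, tau2 = total * 1e-4,
                c = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  model <- "double_exp"
  if (is.null(fit2)) {
    model <- "single_exp"
    fit2 <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-t / tau1) + c,
        start = list(a1 = drop + 1e-6, tau1 = total / 3, c = y[n]),
        lower = c(a1 = 0, tau1 = total * 1e-4, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  }
  if (is.null(fit2)) {
    model <- "linear"
    lf <- stats::lm(y ~ t)
    b <- as.numeric(stats::fitted(lf))
  } else {
    b <- as.numeric(stats::fitted(fit2))
  }
  out <- trace
  out$values <- if (method == "divide" && all(b > 0)) {
    y * b[1] / b
  } else {
    y - b + b[1]
  }
  attr(out, "bleach_model") <- model
  attr(out, "bleach_fit") <- if (model == "linear")
    stats::coef(stats::lm(y ~ t)) else stats::coef(fit2)
  out
}

#' Local linear baseline correction around one event
#'
#' Fits a least-squares line to the `lookback` seconds of baseline
#' preceding the event onset and subtracts the local slope from the trace
#' from the start of that window onward, anchored so the mean of the
#' corrected baseline window equals the mean of the raw one. This removes
#' residual slow drift around an event before amplitude and decay
#' measurements, without disturbing the overall fluorescence level.
#'
#' @param trace a [fluorescence_trace()].
#' @param event one-row data.frame or list with `onset_frame`.
#' @param lookback baseline window length in seconds (default 15). When
#'   the onset is earlier than `lookback`, the available frames are used
#'   (with a warning) as long as at least 3 exist.
#' @return corrected [fluorescence_trace()].
#' @export
local_baseline_correct <- function(trace, event, lookback = 15) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  event <- as.list(event)
  onset <- as.integer(event$onset_frame)
  nb <- round(lookback / trace$frame_interval)
  lo <- onset - nb
  if (lo < 1L) {
    warning("onset earlier than lookback window; using available frames")
    lo <- 1L
  }
  hi <- onset - 1L
  if (hi - lo + 1L < 3L) {
    stop("fewer than 3 baseline frames before the event", call. = FALSE)
  }
  idx <- lo:hi
  tt <- idx * trace$frame_interval
  fit <- stats::lm(trace$values[idx] ~ tt)
  slope <- stats::coef(fit)[2]
  out <- trace
  seg <- lo:length(trace$values)
  tseg <- seg * trace$frame_interval
  line <- slope * (tseg - mean(tt))  # zero-mean over the baseline window
  out$values[seg] <- trace$values[seg] - line
  out
}

#' Match presynaptic and postsynaptic events by frame coincidence
#'
#' Greedy one-to-one matching of pre-channel events (e.g. pHTomato fusion
#' signals) to post-channel events (e.g. GCaMP Ca2+ responses) by onset
#' frame offset. Interleaved dual-channel acquisition assigns both
#' channels of one imaging cycle the same time point, so a fusion event
#' occurring mid-cycle can register one frame early in the post channel —
#' hence windows like `c(-1, 1)` or `c(-1, 5)`.
#'
#' Candidate pairs within the window are matched greedily by smallest
#' absolute offset, ties resolved toward the later post frame; each pre
#' and each post event is used at most once. `fraction_in_window` is the
#' fraction of pre events that found a post partner.
#'
#' @param pre_events,post_events data.frames with `onset_frame` (same
#'   frame clock), e.g. from [detect_events()] on each channel.
#' @param window integer `c(lo, hi)`: allowed `post - pre` frame offsets.
#' @return list of class `coincidence_result`: `matches` (data.frame
#'   `pre_index`, `post_index`, `frame_offset`), `fraction_in_window`,
#'   `n_pre`, `n_post`, `window`.
#' @export
match_events <- function(pre_events, post_events, window = c(-1L, 1L)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  n_pre <- if (is.null(pre_events)) 0L else NROW(pre_events)
  n_post <- if (is.null(post_events)) 0L else NROW(post_events)
  matches <- data.frame(pre_index = integer(0), post_index = integer(0),
                        frame_offset = integer(0))
  if (n_pre > 0L && n_post > 0L) {
    cand <- expand.grid(pre_index = seq_len(n_pre),
                        post_index = seq_len(n_post))
    cand$frame_offset <- post_events$onset_frame[cand$post_index] -
      pre_events$onset_frame[cand$pre_index]
    cand <- cand[cand$frame_offset >= window[1] &
                   cand$frame_offset <= window[2], , drop = FALSE]
    # smallest |offset| first; ties toward the later post frame
    cand <- cand[order(abs(cand$frame_offset), -cand$frame_offset), ,
                 drop = FALSE]
    used_pre <- logical(n_pre); used_post <- logical(n_post)
    for (i in seq_len(nrow(cand))) {
      p <- cand$pre_index[i]; q <- cand$post_index[i]
      if (used_pre[p] || used_post[q]) next
      used_pre[p] <- TRUE; used_post[q] <- TRUE
      matches <- rbind(matches, cand[i, c("pre_index", "post_index",
                                          "frame_offset")])
    }
    rownames(matches) <- NULL
  }
  structure(
    list(matches = matches,
         fraction_in_window = if (n_pre > 0L) nrow(matches) / n_pre
                              else NA_real_,
         n_pre = n_pre, n_post = n_post, window = as.integer(window)),
    class = "coincidence_result")
}

#' @export
print.coincidence_result <- function(x, ...) {
  cat(sprintf(
    "<coincidence_result> %d/%d pre events matched in window [%d, %d] (%.1f%%)\n",
    nrow(x$matches), x$n_pre, x$window[1], x$window[2],
    100 * x$fraction_in_window))
  invisible(x)
}
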