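#' Classify detected events as spontaneous or evoked
#'
#' Labels an event evoked when its onset lies within `window` seconds of
#' the nearest stimulus (closed interval), spontaneous otherwise. Each
#' event is attributed to its nearest stimulus only. Classification is
#' exhaustive and exclusive.
#'
#' @param events data.frame with `onset_time` (s), e.g. from
#'   [detect_events()].
#' @param stim_times sorted numeric stimulus times (s); empty means all
#'   events are spontaneous.
#' @param window half-width of the evoked window in seconds (default 1).
#' @return `events` with added columns `class` (`"spontaneous"` /
#'   `"evoked"`) and `stim_index` (nearest stimulus for evoked events,
#'   `NA` otherwise).
#' @export
classify_events <- function(events, stim_times, window = 1) {
  stopifnot(window >= 0)
  stim_times <- as.numeric(stim_times)
  if (length(stim_times) && is.unsorted(stim_times)) {
    stop("stim_times must be sorted", call. = FALSE)
  }
  events$class <- rep("spontaneous", nrow(events))
  events$stim_index <- rep(NA_integer_, nrow(events))
  if (nrow(events) && length(stim_times)) {
    for (i in seq_len(nrow(events))) {
      d <- abs(events$onset_time[i] - stim_times)
      j <- which.min(d)
      if (d[j] <= window) {
        events$class[i] <- "evoked"
        events$stim_index[i] <- j
      }
    }
  }
  events
}

#' Multivesicular amplitude boundary
#'
#' Amplitude above which an event is counted as more than one vesicle.
#' With a multi-component [fit_quantal_mixture()] the boundary is the
#' posterior-odds crossover between the 1q component and the rest (the
#' amplitude where a single quantum stops being the more likely
#' explanation); with a single-component fit, or plain `q`/`sigma_q`
#' values, the conventional `q + 2*sigma_q` upper bound of the
#' single-quantal Gaussian is used.
#'
#' @param mixture a `quantal_mixture_fit`, or `NULL`.
#' @param q,sigma_q quantal mean and SD used when `mixture` is `NULL`.
#' @return boundary amplitude (a.u.).
#' @export
multivesicular_boundary <- function(mixture = NULL, q = NULL,
                                    sigma_q = NULL) {
  if (!is.null(mixture)) {
    stopifnot(inherits(mixture, "quantal_mixture_fit"))
    if (mixture$n_components >= 2L) {
      dens1 <- function(x) {
        mixture$weights[1] * stats::dnorm(x, mixture$q, mixture$sigma_q)
      }
      densrest <- function(x) {
        out <- 0
        for (j in 2:mixture$n_components) {
          out <- out + mixture$weights[j] *
            stats::dnorm(x, mixture$multipliers[j] * mixture$q,
                         mixture$multipliers[j] * mixture$sigma_q)
        }
        out
      }
      root <- tryCatch(
        stats::uniroot(function(x) dens1(x) - densrest(x),
                       lower = mixture$q,
                       upper = 2 * mixture$q + 4 * mixture$sigma_q)$root,
        error = function(e) NA_real_)
      if (is.finite(root)) return(root)
    }
    return(mixture$q + 2 * mixture$sigma_q)
  }
  stopifnot(!is.null(q), !is.null(sigma_q))
  q + 2 * sigma_q
}

#' Per-synapse event counts, rates and evoked fusion probability
#'
#' Summarises one ROI's labeled events into: the spontaneous rate in
#' events/min; the multivesicular-adjusted rate in which events above the
#' quantal boundary count as two vesicle fusions; and the evoked fusion
#' probability, the fraction of stimuli followed (within the
#' classification window) by at least one evoked event.
#'
#' @param events labeled events for one ROI ([classify_events()] output;
#'   needs `class`, `amplitude`, and `stim_index` when stimuli exist).
#' @param duration recording duration in seconds.
#' @param n_stimuli number of delivered stimuli (0 means evoked
#'   probability is reported `NA`).
#' @param mixture optional `quantal_mixture_fit` defining the
#'   multivesicular boundary.
#' @param q,sigma_q quantal parameters used when `mixture` is `NULL`
#'   (defaults 623 and 122 a.u.).
#' @param roi_id ROI identifier for the output row; taken from `events`
#'   when present.
#' @return one-row data.frame of class `synapse_summary`: `roi_id`,
#'   `n_spont`, `n_evoked`, `n_stimuli`, `spont_rate`,
#'   `spont_rate_mv_adjusted` (events/min), `evoked_prob`.
#' @export
synapse_summary <- function(events, duration, n_stimuli = 0L,
                            mixture = NULL, q = 623, sigma_q = 122,
                            roi_id = NULL) {
  stopifnot(duration > 0)
  if (is.null(roi_id)) {
    roi_id <- if (nrow(events) && "roi_id" %in% names(events))
      events$roi_id[1] else "roi"
  }
  if (!nrow(events)) {
    events$class <- character(0); events$amplitude <- numeric(0)
  }
  boundary <- multivesicular_boundary(mixture, q, sigma_q)
  sp <- events[events$class == "spontaneous", , drop = FALSE]
  ev <- events[events$class == "evoked", , drop = FALSE]
  n_spont <- nrow(sp)
  counts <- ifelse(sp$amplitude > boundary, 2L, 1L)
  evoked_prob <- if (n_stimuli > 0L) {
    hit_stims <- unique(ev$stim_index[!is.na(ev$stim_index)])
    length(hit_stims) / n_stimuli
  } else NA_real_
  out <- data.frame(
    roi_id = roi_id, n_spont = n_spont, n_evoked = nrow(ev),
    n_stimuli = as.integer(n_stimuli),
    spont_rate = n_spont / duration * 60,
    spont_rate_mv_adjusted = sum(counts) / duration * 60,
    evoked_prob = evoked_prob,
    stringsAsFactors = FALSE)
  class(out) <- c("synapse_summary", class(out))
  out
}

#' Correlate spontaneous rate with evoked fusion probability
#'
#' Tests whether synapses with a high spontaneous fusion rate also show a
#' high evoked fusion probability: Pearson R^2 (with two-sided p),
#' Spearman rank correlation, and the least-squares regression slope of
#' spontaneous rate on evoked probability with a test of slope = 0.
#' An absence of correlation (R^2 near 0, flat slope) indicates the two
#' release modes are regulated autonomously.
#'
#' @param summaries data.frame of per-synapse rows (rbind of
#'   [synapse_summary()] outputs) with `spont_rate` and `evoked_prob`,
#'   or any data.frame with those columns. Rows with `NA` are dropped.
#' @param rate_col,prob_col column names to correlate.
#' @return list of class `correlation_result`: `pearson_r2`,
#'   `pearson_p`, `spearman_r`, `spearman_p`, `slope`, `intercept`,
#'   `slope_p`, `n`.
#' @export
correlate_rates <- function(summaries, rate_col = "spont_rate",
                            prob_col = "evoked_prob") {
  x <- summaries[[prob_col]]
  y <- summaries[[rate_col]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 synapses", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in rates or probabilities", call. = FALSE)
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  lf <- stats::lm(y ~ x)
  sm <- summary(lf)$coefficients
  structure(
    list(pearson_r2 = unname(pe$estimate)^2, pearson_p = pe$p.value,
         spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
         slope = unname(stats::coef(lf)[2]),
         intercept = unname(stats::coef(lf)[1]),
         slope_p = sm[2, 4], n = length(x)),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> n = %d: R2 = %.3f (p = %.3g), Spearman r = %.3f (p = %.3g), slope = %.3f (p = %.3g)\n",
    x$n, x$pearson_r2, x$pearson_p, x$spearman_r, x$spearman_p,
    x$slope, x$slope_p))
  invisible(x)
}
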