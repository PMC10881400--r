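# Calcium-imaging quantification: dF/F0 normalization, spike detection,
# per-neuron amplitude/frequency, network synchrony, and the mEPSC
# NMDA/AMPA ratio.

#' Normalize fluorescence traces to baseline (dF/F0)
#'
#' `dF/F0[t] = (F[t] - F0[t]) / F0[t]`. The default baseline is a running
#' 10th percentile over a 30 s window, which tracks slow drift while
#' ignoring transients; a global percentile is also available for short or
#' stationary recordings.
#'
#' @param traces A `trace_set`: `time_s`, `F` (ROI x frame matrix),
#'   `frame_rate_hz`.
#' @param method Baseline estimator: `"running_percentile"` (default) or
#'   `"global_percentile"`.
#' @param percentile Baseline percentile (default 0.10).
#' @param window_s Window width in seconds for the running estimator.
#' @return ROI x frame dF/F0 matrix.
#' @export
compute_dff <- function(traces, method = c("running_percentile",
                                           "global_percentile"),
                        percentile = 0.10, window_s = 30) {
  method <- match.arg(method)
  check_scalar_num(percentile, "percentile", lower = 0, upper = 1)
  check_scalar_num(window_s, "window_s", lower = 0, strict_lower = TRUE)
  FF <- traces$F
  n_frames <- ncol(FF)
  half <- window_s / 2
  t_s <- traces$time_s
  dff <- matrix(0, nrow = nrow(FF), ncol = n_frames, dimnames = dimnames(FF))
  for (i in seq_len(nrow(FF))) {
    f <- FF[i, ]
    f0 <- if (method == "global_percentile") {
      rep(stats::quantile(f, percentile, names = FALSE), n_frames)
    } else {
      vapply(seq_len(n_frames), function(j) {
        win <- f[t_s >= t_s[j] - half & t_s <= t_s[j] + half]
        stats::quantile(win, percentile, names = FALSE)
      }, numeric(1))
    }
    if (any(f0 <= 0)) {
      stop(sprintf("non-positive baseline for ROI '%s'",
                   rownames(FF)[i] %||% i), call. = FALSE)
    }
    dff[i, ] <- (f - f0) / f0
  }
  dff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect calcium spikes in dF/F0 traces
#'
#' The trace is detrended by a running median (window `detrend_window_s`,
#' long relative to the transient decay), which removes any residual
#' baseline offset left by the percentile F0 estimate, then passed
#' through a short forward moving average matched to the sharp-rise /
#' slow-decay transient shape. Events are local maxima of this filtered
#' trace exceeding a hybrid threshold: the larger of an absolute floor
#' (`min_amplitude`) and `threshold_sd` times a robust noise sigma
#' (median absolute deviation, scaled by 1/0.6745, of the filtered
#' trace). Each event must additionally rise by at least the threshold
#' above the minimum of the preceding refractory window, which rejects
#' noise bumps riding on the decay tail of an earlier event. Peaks closer
#' than `refractory_s` are collapsed to the largest; event time and
#' amplitude are then read from the unsmoothed detrended dF/F0 trace at
#' the peak.
#'
#' @param dff ROI x frame dF/F0 matrix from [compute_dff()].
#' @param frame_rate_hz Acquisition rate (frames per second).
#' @param threshold_sd Noise-sigma multiplier (> 0).
#' @param min_amplitude Absolute dF/F0 floor for an event.
#' @param refractory_s Minimum separation between events (> 0).
#' @param detrend_window_s Running-median window (seconds) used for
#'   detrending; should be several times the transient decay constant.
#' @return A `spike_train_set`: per-ROI lists `times` and `amplitudes`,
#'   plus `duration_s`.
#' @export
detect_spikes <- function(dff, frame_rate_hz, threshold_sd = 3,
                          min_amplitude = 0.2, refractory_s = 1.0,
                          detrend_window_s = 10) {
  check_scalar_num(threshold_sd, "threshold_sd", lower = 0,
                   strict_lower = TRUE)
  check_scalar_num(min_amplitude, "min_amplitude", lower = 0)
  check_scalar_num(refractory_s, "refractory_s", lower = 0,
                   strict_lower = TRUE)
  check_scalar_num(detrend_window_s, "detrend_window_s", lower = 0,
                   strict_lower = TRUE)
  n_frames <- ncol(dff)
  t_grid <- (seq_len(n_frames) - 1) / frame_rate_hz
  duration <- n_frames / frame_rate_hz
  # running median with windows clipped at the recording boundaries (a
  # shrinking centered window would let a transient near the edges
  # dominate its own baseline)
  half <- max(1L, round(detrend_window_s * frame_rate_hz / 2))
  run_median <- function(y) {
    vapply(seq_len(n_frames), function(j) {
      stats::median(y[max(1L, j - half):min(n_frames, j + half)])
    }, numeric(1))
  }
  # short forward moving average, matched to the sharp-rise/slow-decay
  # transient shape: averages frame noise while barely attenuating the
  # peak of a decaying transient
  k_sm <- max(1L, round(0.5 * frame_rate_hz))
  smooth_fwd <- function(v) {
    vapply(seq_len(n_frames), function(j) {
      mean(v[j:min(n_frames, j + k_sm - 1L)])
    }, numeric(1))
  }
  times <- vector("list", nrow(dff))
  amps <- vector("list", nrow(dff))
  for (i in seq_len(nrow(dff))) {
    y <- dff[i, ]
    resid <- y - run_median(y)
    sm <- smooth_fwd(resid)
    sigma <- stats::mad(sm)              # = MAD / 0.6745
    thr <- max(min_amplitude, threshold_sd * sigma)
    # strict local maxima above threshold (plateaus: first frame wins;
    # boundary frames are eligible)
    left <- c(-Inf, sm[-n_frames])
    right <- c(sm[-1], -Inf)
    cand <- which(sm >= thr & sm > left & sm >= right)
    # a spike rises instantaneously: require the peak to stand at least
    # `thr` above the minimum of the preceding refractory window, which
    # rejects noise bumps riding on the decay tail of an earlier event
    # (windows clipped by the recording start fall back to baseline 0)
    if (length(cand) > 0) {
      k_ref <- max(1L, round(refractory_s * frame_rate_hz))
      rise <- vapply(cand, function(j) {
        lo <- max(1L, j - k_ref)
        prev <- if (j > 1L) sm[lo:(j - 1L)] else numeric(0)
        if (j - k_ref < 1L) prev <- c(0, prev)
        sm[j] - min(prev)
      }, numeric(1))
      cand <- cand[rise >= thr]
    }
    if (length(cand) > 0) {
      # refine each event on the unsmoothed trace within the kernel span
      cand <- vapply(cand, function(j) {
        win <- j:min(n_frames, j + k_sm - 1L)
        win[which.max(resid[win])]
      }, integer(1))
      cand <- sort(unique(cand))
      # enforce refractory: keep largest peaks greedily
      ord <- cand[order(resid[cand], decreasing = TRUE)]
      kept <- numeric(0)
      for (j in ord) {
        if (all(abs(t_grid[j] - t_grid[kept]) >= refractory_s)) {
          kept <- c(kept, j)
        }
      }
      kept <- sort(kept)
      times[[i]] <- t_grid[kept]
      amps[[i]] <- resid[kept]
    } else {
      times[[i]] <- numeric(0)
      amps[[i]] <- numeric(0)
    }
  }
  names(times) <- rownames(dff)
  names(amps) <- rownames(dff)
  structure(list(times = times, amplitudes = amps, duration_s = duration),
            class = "spike_train_set")
}

#' Per-neuron spike amplitude and frequency
#'
#' Amplitude is the mean dF/F0 of a neuron's detected spikes (reported as
#' `NA` for neurons with no events); frequency is events per minute.
#'
#' @param spikes A `spike_train_set`.
#' @return data.frame: `roi`, `n_events`, `amplitude`, `frequency_per_min`.
#' @export
spike_statistics <- function(spikes) {
  stopifnot(spikes$duration_s > 0)
  n <- lengths(spikes$times)
  data.frame(
    roi = names(spikes$times) %||% as.character(seq_along(spikes$times)),
    n_events = as.integer(n),
    amplitude = vapply(spikes$amplitudes,
                       function(a) if (length(a)) mean(a) else NA_real_,
                       numeric(1)),
    frequency_per_min = 60 * n / spikes$duration_s,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Network synchronous firing rate
#'
#' A synchronous event is a sliding window of width `window_s` in which at
#' least a `participation` fraction of all ROIs fire at least once.
#' Overlapping qualifying windows are merged into one event, timed at the
#' median participant spike time (ties: earliest). The rate is events per
#' minute of recording.
#'
#' @param spikes A `spike_train_set` with >= 2 ROIs.
#' @param window_s Coincidence window in seconds.
#' @param participation Required fraction of ROIs in (0, 1]. 1 demands
#'   every ROI; the default 0.8 tolerates detection misses.
#' @return A `synchrony_result`: `sync_event_times`, `rate_per_min`,
#'   `n_events`, `participation_threshold`, `window_s`, `duration_s`.
#' @export
synchronous_firing_rate <- function(spikes, window_s = 0.5,
                                    participation = 0.8) {
  if (length(spikes$times) < 2) stop("need >= 2 ROIs", call. = FALSE)
  if (!is.numeric(participation) || length(participation) != 1 ||
      participation <= 0 || participation > 1) {
    stop_config("participation", "must be in (0, 1]")
  }
  check_scalar_num(window_s, "window_s", lower = 0, strict_lower = TRUE)
  n_rois <- length(spikes$times)
  need <- ceiling(participation * n_rois - 1e-9)
  all_spikes <- sort(unique(unlist(spikes$times)))
  qualifying <- logical(length(all_spikes))
  for (k in seq_along(all_spikes)) {
    lo <- all_spikes[k] - window_s / 2
    hi <- all_spikes[k] + window_s / 2
    hit <- vapply(spikes$times, function(tt) any(tt >= lo & tt <= hi),
                  logical(1))
    qualifying[k] <- sum(hit) >= need
  }
  q_times <- all_spikes[qualifying]
  events <- numeric(0)
  if (length(q_times) > 0) {
    # merge qualifying windows whose centers are within one window width
    grp <- cumsum(c(TRUE, diff(q_times) > window_s))
    events <- vapply(split(q_times, grp), function(ts) {
      lo <- min(ts) - window_s / 2
      hi <- max(ts) + window_s / 2
      member <- unlist(lapply(spikes$times,
                              function(tt) tt[tt >= lo & tt <= hi]))
      med <- stats::median(member)
      # tie-break: the earliest actual spike at/after the median position
      cand <- sort(member)
      cand[which.min(abs(cand - med))]
    }, numeric(1))
    events <- unname(sort(events))
  }
  structure(list(sync_event_times = events,
                 rate_per_min = 60 * length(events) / spikes$duration_s,
                 n_events = length(events),
                 participation_threshold = participation,
                 window_s = window_s,
                 duration_s = spikes$duration_s),
            class = "synchrony_result")
}

#' NMDA/AMPA current ratio from a paired mEPSC recording
#'
#' The NMDA component is read as the absolute current 20 ms after event
#' onset in the +40 mV trace (where AMPA receptors are desensitized),
#' linearly interpolated between samples; the AMPA component is the peak
#' absolute current in the -70 mV trace within the event window.
#'
#' @param pair List with `trace_plus40` and `trace_minus70`, each a
#'   data.frame with columns `time_s` and `current_pA`, and `onset_s`, the
#'   event onset time. Sampling must cover `onset_s + 20 ms`.
#' @param nmda_delay_s Read-out delay after onset (default 0.020 s).
#' @param ampa_window_s Window after onset searched for the AMPA peak.
#' @return The ratio |I(+40 mV, onset + delay)| / max |I(-70 mV)|.
#' @export
nmda_ampa_ratio <- function(pair, nmda_delay_s = 0.020,
                            ampa_window_s = 0.050) {
  p40 <- pair$trace_plus40
  m70 <- pair$trace_minus70
  onset <- pair$onset_s
  t_read <- onset + nmda_delay_s
  if (t_read > max(p40$time_s) || t_read < min(p40$time_s)) {
    stop("+40 mV trace does not cover onset + 20 ms", call. = FALSE)
  }
  nmda <- abs(stats::approx(p40$time_s, p40$current_pA, xout = t_read)$y)
  win <- m70$time_s >= onset & m70$time_s <= onset + ampa_window_s
  if (!any(win)) stop("-70 mV trace does not cover the event", call. = FALSE)
  ampa <- max(abs(m70$current_pA[win]))
  if (ampa == 0) stop("AMPA peak is zero; ratio undefined", call. = FALSE)
  nmda / ampa
}
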