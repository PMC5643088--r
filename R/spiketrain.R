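# Current-clamp / loose-seal spike analysis: dV/dt threshold detection,
# phase plots, phase-resolved evoked-spike properties, train following and
# soma-axon correspondence.

#' Time derivative of a voltage trace, in V/s
#'
#' Central difference on raw samples: `dVdt[i] = (v[i+1] - v[i-1]) * rate /
#' 2000` for v in mV. First and last samples are NA.
#' @param v voltage samples (mV).
#' @param rate_hz sampling rate.
#' @return numeric vector of derivatives (V/s).
#' @export
dvdt_v_per_s <- function(v, rate_hz) {
  n <- length(v)
  d <- rep(NA_real_, n)
  if (n >= 3)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * rate_hz / 2000
  d
}

#' Detect action potentials by the dV/dt criterion
#'
#' A spike event starts at the first sample where the central-difference
#' dV/dt reaches `dvdt_criterion` (default 5 V/s) after at least
#' `refractory_s` (default 2 ms) of continuously sub-criterion samples.
#' The threshold is the (t, V) pair at that sample; the peak is the maximum
#' voltage within `peak_window_s` after threshold. Truncated spikes (low
#' peaks) still count as events - there is no height cut.
#'
#' @param rec a current-clamp `pb_recording` sampled at >= 10 kHz.
#' @param dvdt_criterion threshold slope in V/s.
#' @param refractory_s required sub-criterion run before an event (s).
#' @param peak_window_s window after threshold searched for the peak (s).
#' @return data.frame with one row per spike: `t_thresh_s`, `v_thresh_mv`,
#'   `t_peak_s`, `v_peak_mv`, `is_evoked` (NA until classified),
#'   `latency_s`, `prev_isi_s`, `i_thresh` (sample index).
#' @export
detect_spikes <- function(rec, dvdt_criterion = 5, refractory_s = 0.002,
                          peak_window_s = 0.005) {
  pb_assert(inherits(rec, "pb_recording") &&
              rec$channel_kind == "cclamp_voltage",
            "detect_spikes needs a current-clamp recording", "pb_input_error")
  pb_assert(rec$rate_hz >= 1e4,
            "sampling rate must be >= 10 kHz for a stable derivative",
            "pb_input_error")
  v <- rec$samples
  n <- length(v)
  d <- dvdt_v_per_s(v, rec$rate_hz)
  above <- !is.na(d) & d >= dvdt_criterion
  n_ref <- ceiling(refractory_s * rec$rate_hz)
  # event = start of an above-run whose preceding n_ref samples all exist
  # and are sub-criterion
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- starts[r$values]
  ok <- vapply(cand, function(i) {
    i > n_ref && !any(above[(i - n_ref):(i - 1L)])
  }, TRUE)
  idx <- cand[ok]
  n_peak <- round(peak_window_s * rec$rate_hz)
  tt <- rec_times(rec)
  rows <- lapply(idx, function(i) {
    j <- i:min(i + n_peak, n)
    ip <- j[which.max(v[j])]
    data.frame(t_thresh_s = tt[i], v_thresh_mv = v[i],
               t_peak_s = tt[ip], v_peak_mv = v[ip],
               i_thresh = i)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t_thresh_s = numeric(0), v_thresh_mv = numeric(0),
               t_peak_s = numeric(0), v_peak_mv = numeric(0),
               i_thresh = integer(0))
  out$is_evoked <- rep(NA, nrow(out))
  out$latency_s <- rep(NA_real_, nrow(out))
  out$stim_index <- rep(NA_integer_, nrow(out))
  out$prev_isi_s <- if (nrow(out)) c(NA, diff(out$t_thresh_s)) else numeric(0)
  out
}

#' Phase plot (dV/dt versus V) over a spike window
#'
#' @param rec a current-clamp `pb_recording`.
#' @param window_s absolute time window `[t1, t2]` covering the spike.
#' @param dvdt_criterion criterion used to mark the threshold point.
#' @return list of class `pb_phase_plot`: `v_mv`, `dvdt_v_per_s` (aligned,
#'   NA at the window edges), `i_thresh` (index of the first sample at or
#'   above criterion, NA if none).
#' @export
phase_plot <- function(rec, window_s, dvdt_criterion = 5) {
  pb_assert(inherits(rec, "pb_recording"), "not a pb_recording", "pb_input_error")
  tt <- rec_times(rec)
  pb_assert(window_s[1] >= tt[1] && window_s[2] <= tt[length(tt)],
            "window outside recording", "pb_range_error")
  sel <- which(tt >= window_s[1] & tt <= window_s[2])
  d_full <- dvdt_v_per_s(rec$samples, rec$rate_hz)
  v <- rec$samples[sel]
  d <- d_full[sel]
  hit <- which(!is.na(d) & d >= dvdt_criterion)
  structure(list(v_mv = v, dvdt_v_per_s = d,
                 i_thresh = if (length(hit)) hit[1] else NA_integer_),
            class = "pb_phase_plot")
}

#' Label spikes as stimulus-evoked or spontaneous
#'
#' A spike is evoked iff its threshold time falls in `(onset, onset +
#' max_latency_s]`; at most one spike is matched per stimulus (the earliest
#' wins) and all others are spontaneous.
#'
#' @param spikes data.frame from [detect_spikes()].
#' @param stim a `pb_protocol` or numeric onset vector.
#' @param max_latency_s evoked window after each pulse (default 10 ms).
#' @return the spike table with `is_evoked`, `latency_s`, `stim_index`
#'   filled in.
#' @export
classify_evoked <- function(spikes, stim, max_latency_s = 0.010) {
  onsets <- if (inherits(stim, "pb_protocol")) stim$pulse_onsets_s else as.numeric(stim)
  if (length(onsets) >= 2L && any(diff(onsets) <= max_latency_s))
    pb_stop("stimulus windows overlap at this latency", "pb_protocol_error")
  spikes$is_evoked <- rep(FALSE, nrow(spikes))
  spikes$latency_s <- NA_real_
  spikes$stim_index <- NA_integer_
  for (k in seq_along(onsets)) {
    lat <- spikes$t_thresh_s - onsets[k]
    cand <- which(lat > 0 & lat <= max_latency_s & !spikes$is_evoked)
    if (length(cand)) {
      i <- cand[which.min(lat[cand])]
      spikes$is_evoked[i] <- TRUE
      spikes$latency_s[i] <- lat[i]
      spikes$stim_index[i] <- k
    }
  }
  spikes
}

#' Normalized pacemaking phase of a stimulus
#'
#' Time from the last preceding spike to the stimulus, normalized by the
#' mean interspike interval of the spikes in the `window_s` (default 4 s)
#' before the stimulus. Requires at least two preceding spikes in the
#' window.
#'
#' @param stim_onset_s stimulus onset time (s).
#' @param spike_times_s spike (threshold) times used as the pacemaking
#'   baseline, usually spontaneous spikes only.
#' @param window_s averaging window (s).
#' @return list with `phase`, `mean_isi_s`, `n_spikes`.
#' @export
normalized_phase <- function(stim_onset_s, spike_times_s, window_s = 4) {
  st <- sort(spike_times_s[spike_times_s >= stim_onset_s - window_s &
                             spike_times_s < stim_onset_s])
  if (length(st) < 2L)
    pb_stop("fewer than 2 spikes precede the stimulus in the averaging window",
            "pb_insufficient_baseline_error")
  mean_isi <- mean(diff(st))
  list(phase = (stim_onset_s - st[length(st)]) / mean_isi,
       mean_isi_s = mean_isi,
       n_spikes = length(st))
}

#' Compare an evoked spike with its spontaneous neighbours
#'
#' For one stimulus with a matched evoked spike: the threshold and peak
#' differences relative to the preceding spontaneous spike and the
#' resetting index, i.e. the interval from the evoked spike to the next
#' spontaneous spike divided by the mean ISI of the 4 s baseline. A
#' resetting index of 1 indicates full resetting of the pacemaking cycle.
#'
#' @param spikes labelled spike table (from [classify_evoked()]).
#' @param stim_onset_s the stimulus onset.
#' @param phase_window_s baseline ISI averaging window (default 4 s).
#' @return one-row data.frame: `phase`, `d_thresh_mv`, `d_peak_mv`,
#'   `reset_ratio`, `latency_s`.
#' @export
evoked_comparison <- function(spikes, stim_onset_s, phase_window_s = 4) {
  ev <- spikes[isTRUE_v(spikes$is_evoked) &
                 !is.na(spikes$latency_s) &
                 spikes$t_thresh_s > stim_onset_s &
                 spikes$t_thresh_s <= stim_onset_s + 0.05, , drop = FALSE]
  if (nrow(ev) == 0L)
    pb_stop("stimulus has no matched evoked spike", "pb_incomplete_cycle_error")
  ev <- ev[1, ]
  spont <- spikes[!isTRUE_v(spikes$is_evoked), , drop = FALSE]
  pre <- spont[spont$t_thresh_s < stim_onset_s, , drop = FALSE]
  post <- spont[spont$t_thresh_s > ev$t_thresh_s, , drop = FALSE]
  if (nrow(pre) == 0L || nrow(post) == 0L)
    pb_stop("missing preceding or following spontaneous spike",
            "pb_incomplete_cycle_error")
  pre <- pre[nrow(pre), ]
  post <- post[1, ]
  ph <- normalized_phase(stim_onset_s, pre_spont_times(spikes, stim_onset_s),
                         phase_window_s)
  data.frame(phase = ph$phase,
             d_thresh_mv = ev$v_thresh_mv - pre$v_thresh_mv,
             d_peak_mv = ev$v_peak_mv - pre$v_peak_mv,
             reset_ratio = (post$t_thresh_s - ev$t_thresh_s) / ph$mean_isi_s,
             latency_s = ev$latency_s)
}

isTRUE_v <- function(x) !is.na(x) & x

pre_spont_times <- function(spikes, stim_onset_s) {
  s <- spikes[!isTRUE_v(spikes$is_evoked), , drop = FALSE]
  s$t_thresh_s[s$t_thresh_s < stim_onset_s]
}

#' Intra-stimulus spike rate for a stimulus train
#'
#' The analysis window runs from the first onset to one median
#' inter-stimulus interval past the last onset (so the last evoked spike is
#' counted); the intra-stimulus rate is the number of spikes with threshold
#' inside the window divided by the window duration. The stimulus
#' "frequency" of a (possibly variable-interval) train is `(n - 1) /
#' (last - first onset)`.
#'
#' @param spikes labelled spike table.
#' @param stim a `pb_protocol` with >= 2 pulses.
#' @return list of class `pb_train_response`: `stim_freq_hz`, `n_stimuli`,
#'   `intra_rate_hz`, `follow_fraction`, `n_spikes_in_window`,
#'   `window_s`.
#' @export
intra_stimulus_rate <- function(spikes, stim) {
  onsets <- if (inherits(stim, "pb_protocol")) stim$pulse_onsets_s else as.numeric(stim)
  if (length(onsets) < 2L)
    pb_stop("train analysis needs >= 2 stimuli", "pb_protocol_error")
  isi_med <- median(diff(onsets))
  w <- c(onsets[1], onsets[length(onsets)] + isi_med)
  n_in <- sum(spikes$t_thresh_s >= w[1] & spikes$t_thresh_s < w[2])
  follow <- length(unique(spikes$stim_index[!is.na(spikes$stim_index)])) /
    length(onsets)
  structure(list(stim_freq_hz = (length(onsets) - 1) / diff(range(onsets)),
                 n_stimuli = length(onsets),
                 intra_rate_hz = n_in / diff(w),
                 follow_fraction = follow,
                 n_spikes_in_window = n_in,
                 window_s = w),
            class = "pb_train_response")
}

#' Spike probability versus stimulus intensity
#'
#' @param trials named list: one element per intensity (name = intensity as
#'   a number), each a logical vector of per-trial evoked outcomes with at
#'   least 3 trials.
#' @return data.frame `intensity`, `p_spike`, `n_trials`.
#' @export
spike_probability <- function(trials) {
  pb_assert(length(trials) >= 1L, "empty trial list", "pb_input_error")
  pb_assert(all(vapply(trials, length, 0L) >= 3L),
            "need >= 3 trials per intensity", "pb_input_error")
  data.frame(intensity = as.numeric(names(trials)),
             p_spike = vapply(trials, mean, 0),
             n_trials = vapply(trials, length, 0L),
             row.names = NULL)
}

#' Match somatic and axonal spike trains
#'
#' Greedy nearest-neighbour matching: candidate pairs within `tolerance_s`
#' are assigned in order of increasing absolute time difference, each event
#' used at most once (symmetric under exchanging the two trains).
#' Instantaneous rates are 1 / ISI relative to the previous event at the
#' same site (backward ISI, primary) with the forward version emitted
#' alongside.
#'
#' @param soma_t,axon_t event times (s), both non-empty.
#' @param tolerance_s matching tolerance (default 3 ms).
#' @return list with `pairs` (data.frame soma_t, axon_t, dt_s, soma_rate_hz,
#'   axon_rate_hz, soma_rate_fwd_hz, axon_rate_fwd_hz), `n_matched`,
#'   `unmatched_soma`, `unmatched_axon`.
#' @export
match_axon_soma <- function(soma_t, axon_t, tolerance_s = 0.003) {
  pb_assert(length(soma_t) > 0L && length(axon_t) > 0L,
            "both trains must be non-empty", "pb_input_error")
  soma_t <- sort(soma_t); axon_t <- sort(axon_t)
  dt <- outer(soma_t, axon_t, function(a, b) abs(a - b))
  cand <- which(dt <= tolerance_s, arr.ind = TRUE)
  pairs <- NULL
  if (nrow(cand)) {
    ord <- order(dt[cand])
    cand <- cand[ord, , drop = FALSE]
    used_s <- logical(length(soma_t)); used_a <- logical(length(axon_t))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!used_s[i] && !used_a[j]) {
        used_s[i] <- used_a[j] <- TRUE
        keep[r] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    rate_bwd <- function(t) c(NA, 1 / diff(t))
    rate_fwd <- function(t) c(1 / diff(t), NA)
    sr <- rate_bwd(soma_t); ar <- rate_bwd(axon_t)
    srf <- rate_fwd(soma_t); arf <- rate_fwd(axon_t)
    ordi <- order(cand[, 1])
    cand <- cand[ordi, , drop = FALSE]
    pairs <- data.frame(soma_t = soma_t[cand[, 1]],
                        axon_t = axon_t[cand[, 2]],
                        dt_s = axon_t[cand[, 2]] - soma_t[cand[, 1]],
                        soma_rate_hz = sr[cand[, 1]],
                        axon_rate_hz = ar[cand[, 2]],
                        soma_rate_fwd_hz = srf[cand[, 1]],
                        axon_rate_fwd_hz = arf[cand[, 2]])
    matched_s <- cand[, 1]; matched_a <- cand[, 2]
  } else {
    pairs <- data.frame(soma_t = numeric(0), axon_t = numeric(0),
                        dt_s = numeric(0), soma_rate_hz = numeric(0),
                        axon_rate_hz = numeric(0),
                        soma_rate_fwd_hz = numeric(0),
                        axon_rate_fwd_hz = numeric(0))
    matched_s <- matched_a <- integer(0)
  }
  list(pairs = pairs,
       n_matched = nrow(pairs),
       unmatched_soma = soma_t[setdiff(seq_along(soma_t), matched_s)],
       unmatched_axon = axon_t[setdiff(seq_along(axon_t), matched_a)])
}

#' Detect events in a loose-seal trace
#'
#' Simple magnitude detector for extracellular spike blips: events are local
#' extrema of the absolute deflection exceeding `k` robust SDs (MAD), with a
#' refractory gap.
#'
#' @param rec a loose-seal `pb_recording`.
#' @param k detection threshold in robust SDs.
#' @param refractory_s minimum event spacing (s).
#' @return numeric vector of event times.
#' @export
detect_loose_seal_events <- function(rec, k = 5, refractory_s = 0.002) {
  pb_assert(inherits(rec, "pb_recording") && rec$channel_kind == "loose_seal",
            "needs a loose-seal recording", "pb_input_error")
  y <- abs(rec$samples - median(rec$samples))
  thr <- k * stats::mad(rec$samples)
  above <- y > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev <- integer(0)
  for (q in which(r$values)) {
    seg <- starts[q]:ends[q]
    ev <- c(ev, seg[which.max(y[seg])])
  }
  tt <- rec_times(rec)
  times <- tt[ev]
  if (length(times) > 1L) {
    keep <- c(TRUE, diff(times) > refractory_s)
    times <- times[keep]
  }
  times
}
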