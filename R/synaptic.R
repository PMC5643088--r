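# Voltage-clamp EPSC quantification and sCRACM distance-resolved mapping.

boxcar <- function(y, k) {
  if (k <= 1L) return(y)
  sm <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  sm
}

#' Measure a baseline-subtracted EPSC peak
#'
#' Baseline is the mean over `[-0.02, 0)` s before the stimulus; the peak is
#' the signed extremum of the baseline-subtracted trace inside the search
#' window (default `[0.002, 0.05)` s, skipping the 1 ms light artifact and
#' covering the slow NMDA rise). An optional boxcar smoother (off by
#' default) is applied before the extremum is taken.
#'
#' @param ep a `pb_epoch` aligned so t = 0 is the stimulus onset, including
#'   at least 20 ms of pre-stimulus baseline.
#' @param window_s half-open search window `[w1, w2)` in seconds.
#' @param polarity `"inward"` (negative peak) or `"outward"`.
#' @param baseline_s half-open baseline window (default `[-0.02, 0)`).
#' @param smooth_ms boxcar width in ms; 0 disables smoothing.
#' @return a `pb_epsc` measurement: `baseline_pa`, `peak_pa` (signed,
#'   baseline-subtracted), `t_peak_s`, `window_s`, `polarity`.
#' @export
measure_epsc <- function(ep, window_s = c(0.002, 0.05),
                         polarity = c("inward", "outward"),
                         baseline_s = c(-0.02, 0), smooth_ms = 0) {
  polarity <- match.arg(polarity)
  pb_assert(inherits(ep, "pb_epoch"), "not a pb_epoch", "pb_input_error")
  pb_assert(window_s[1] < window_s[2], "bad search window", "pb_input_error")
  base_idx <- ep$t >= baseline_s[1] & ep$t < baseline_s[2]
  pb_assert(sum(base_idx) >= round(0.9 * diff(baseline_s) * ep$rate_hz),
            "epoch lacks the pre-stimulus baseline window", "pb_range_error")
  win_idx <- ep$t >= window_s[1] & ep$t < window_s[2]
  if (!any(win_idx) || window_s[2] > max(ep$t) + 1.5 / ep$rate_hz)
    pb_stop("search window outside epoch", "pb_range_error")
  baseline <- mean(ep$y[base_idx])
  k <- max(1L, round(smooth_ms / 1000 * ep$rate_hz))
  y <- boxcar(ep$y, if (smooth_ms > 0) k else 1L) - baseline
  yw <- y[win_idx]; tw <- ep$t[win_idx]
  i <- if (polarity == "inward") which.min(yw) else which.max(yw)
  structure(list(baseline_pa = baseline,
                 peak_pa = yw[i],
                 t_peak_s = tw[i],
                 window_s = window_s,
                 polarity = polarity),
            class = "pb_epsc")
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first EPSC peak; values below one indicate
#' synaptic depression (high release probability). Both measurements must
#' have the same polarity, and when a noise estimate is supplied the first
#' peak must exceed 5x the noise SD for the denominator to be trusted.
#'
#' @param m1,m2 `pb_epsc` measurements for pulses 1 and 2.
#' @param noise_sd_pa optional baseline noise SD (pA).
#' @return the ratio `m2$peak_pa / m1$peak_pa` (positive for same-sign
#'   peaks).
#' @export
compute_ppr <- function(m1, m2, noise_sd_pa = NULL) {
  pb_assert(inherits(m1, "pb_epsc") && inherits(m2, "pb_epsc"),
            "need two pb_epsc measurements", "pb_input_error")
  pb_assert(identical(m1$polarity, m2$polarity),
            "paired pulses must share polarity", "pb_input_error")
  if (!is.null(noise_sd_pa) && abs(m1$peak_pa) <= 5 * noise_sd_pa)
    pb_stop("first-pulse peak is below the noise floor; ratio denominator unreliable",
            "pb_unreliable_denominator_error")
  m2$peak_pa / m1$peak_pa
}

#' AMPA:NMDA ratio with the fixed 40 ms rule
#'
#' The AMPA component is the inward peak at -70 mV; its peak time t* fixes
#' the NMDA measurement point: the baseline-subtracted current of the
#' +40 mV sweep at t* + 40 ms (not the +40 mV extremum). The ratio is
#' |AMPA peak| / |NMDA value|. When the NMDA value does not exceed
#' `noise_k` times the +40 mV baseline noise SD the ratio is flagged
#' unreliable (returned, not raised).
#'
#' @param epoch_minus70 `pb_epoch` recorded at -70 mV.
#' @param epoch_plus40 `pb_epoch` recorded at +40 mV, same alignment.
#' @param window_s AMPA peak search window.
#' @param nmda_latency_s latency after the AMPA peak at which the NMDA
#'   component is read (default 0.040 s).
#' @param noise_k reliability threshold in baseline-noise SDs.
#' @param smooth_ms boxcar width (ms) applied before the AMPA extremum and
#'   the fixed-latency NMDA read; 0 disables smoothing.
#' @return list with `ratio`, `ampa_pa`, `nmda_pa`, `t_ampa_peak_s`,
#'   `reliable`.
#' @export
compute_ampa_nmda <- function(epoch_minus70, epoch_plus40,
                              window_s = c(0.002, 0.05),
                              nmda_latency_s = 0.040, noise_k = 3,
                              smooth_ms = 0) {
  ampa <- measure_epsc(epoch_minus70, window_s, "inward",
                       smooth_ms = smooth_ms)
  ep <- epoch_plus40
  base_idx <- ep$t >= -0.02 & ep$t < 0
  pb_assert(any(base_idx), "+40 mV epoch lacks baseline", "pb_range_error")
  baseline <- mean(ep$y[base_idx])
  noise_sd <- sd(ep$y[base_idx])
  t_nmda <- ampa$t_peak_s + nmda_latency_s
  pb_assert(t_nmda <= max(ep$t), "+40 mV epoch too short for the 40 ms rule",
            "pb_range_error")
  k <- max(1L, round(smooth_ms / 1000 * ep$rate_hz))
  ys <- boxcar(ep$y, if (smooth_ms > 0) k else 1L)
  i <- which.min(abs(ep$t - t_nmda))
  nmda <- ys[i] - baseline
  reliable <- abs(nmda) > noise_k * noise_sd
  list(ratio = abs(ampa$peak_pa) / abs(nmda),
       ampa_pa = ampa$peak_pa,
       nmda_pa = nmda,
       t_ampa_peak_s = ampa$t_peak_s,
       reliable = reliable)
}

#' Normalized current-voltage relation with linear fit
#'
#' Per-cell currents are divided by the current measured at -80 mV for that
#' cell, then an ordinary least-squares line is fitted across holding
#' potentials. Absence of rectification shows up as a linear IV with
#' reversal near 0 mV.
#'
#' @param holding_mv numeric vector of holding potentials.
#' @param peaks_pa matching vector of signed peak currents (pA), or a list
#'   of `pb_epsc` from which peaks are taken.
#' @param noise_sd_pa optional noise floor; the -80 mV normalizer must
#'   exceed 5x this value.
#' @return list with `iv` (data.frame holding_mv, peak_pa, norm) and `fit`
#'   (slope, intercept, reversal_mv, r_squared) or `fit = NULL` when fewer
#'   than two points are available.
#' @export
normalize_iv <- function(holding_mv, peaks_pa, noise_sd_pa = NULL) {
  if (is.list(peaks_pa))
    peaks_pa <- vapply(peaks_pa, function(m) m$peak_pa, 0)
  pb_assert(length(holding_mv) == length(peaks_pa) && length(peaks_pa) >= 1L,
            "holding_mv and peaks_pa must match", "pb_input_error")
  i80 <- which(abs(holding_mv - (-80)) < 1e-6)
  if (length(i80) != 1L)
    pb_stop("normalization requires exactly one -80 mV measurement",
            "pb_normalization_error")
  ref <- peaks_pa[i80]
  if (!is.null(noise_sd_pa) && abs(ref) <= 5 * noise_sd_pa)
    pb_stop("-80 mV reference below noise floor", "pb_normalization_error")
  iv <- data.frame(holding_mv = holding_mv, peak_pa = peaks_pa,
                   norm = peaks_pa / ref)
  fit <- NULL
  if (length(unique(holding_mv)) >= 2L) {
    lmfit <- stats::lm(norm ~ holding_mv, data = iv)
    co <- stats::coef(lmfit)
    r2 <- suppressWarnings(summary(lmfit)$r.squared)  # exact fits warn
    fit <- list(slope = unname(co[2]), intercept = unname(co[1]),
                reversal_mv = unname(-co[1] / co[2]),
                r_squared = r2)
  }
  list(iv = iv, fit = fit)
}

#' Drug effect as percent change from control
#'
#' Per-condition peak is the mean of per-sweep peaks (at least three stable
#' sweeps per condition); the effect is the percent change of the response
#' magnitude, `100 * (|post| - |pre|) / |pre|`, so an antagonist of an
#' inward current gives a negative percent change and a potentiator a
#' positive one. Both conditions are measured at the same polarity.
#'
#' @param pre_epochs,post_epochs lists of `pb_epoch` sweeps for the control
#'   and post-drug conditions.
#' @param window_s,polarity passed to [measure_epsc()].
#' @param noise_sd_pa optional noise floor for the control mean.
#' @param method `"fixed_latency"` (default): the peak latency is located
#'   once on the boxcar-smoothed control-average trace and per-sweep
#'   amplitudes are read at that latency, which keeps the ratio unbiased
#'   under noise; `"per_sweep_peak"`: each sweep contributes its own
#'   extremum (noisier and biased upward in magnitude).
#' @param smooth_ms boxcar width used to locate / read the peak.
#' @return list of class `pb_drug_effect`: `pre_pa`, `post_pa`,
#'   `percent_change`, `t_peak_s`, `method`.
#' @export
drug_effect <- function(pre_epochs, post_epochs, window_s = c(0.002, 0.05),
                        polarity = "inward", noise_sd_pa = NULL,
                        method = c("fixed_latency", "per_sweep_peak"),
                        smooth_ms = 0.5) {
  method <- match.arg(method)
  pb_assert(length(pre_epochs) >= 3L && length(post_epochs) >= 3L,
            "need at least 3 sweeps per condition", "pb_input_error")
  t_peak <- NA_real_
  if (method == "per_sweep_peak") {
    peak <- function(ep) measure_epsc(ep, window_s, polarity,
                                      smooth_ms = smooth_ms)$peak_pa
    pre <- mean(vapply(pre_epochs, peak, 0))
    post <- mean(vapply(post_epochs, peak, 0))
  } else {
    # locate the latency on the pooled grand-average trace with a heavier
    # smoother: pooling keeps the residual selection noise symmetric
    # between conditions and the smoothing keeps it small
    all_ep <- c(pre_epochs, post_epochs)
    avg <- all_ep[[1]]
    avg$y <- rowMeans(vapply(all_ep, function(ep) ep$y,
                             numeric(length(avg$y))))
    t_peak <- measure_epsc(avg, window_s, polarity,
                           smooth_ms = max(smooth_ms, 2))$t_peak_s
    at_latency <- function(ep) {
      base <- mean(ep$y[ep$t >= -0.02 & ep$t < 0])
      k <- max(1L, round(smooth_ms / 1000 * ep$rate_hz))
      ys <- boxcar(ep$y, if (smooth_ms > 0) k else 1L)
      ys[which.min(abs(ep$t - t_peak))] - base
    }
    pre <- mean(vapply(pre_epochs, at_latency, 0))
    post <- mean(vapply(post_epochs, at_latency, 0))
  }
  if (!is.null(noise_sd_pa) && abs(pre) <= 5 * noise_sd_pa)
    pb_stop("control mean below noise floor", "pb_unreliable_denominator_error")
  structure(list(pre_pa = pre, post_pa = post,
                 percent_change = 100 * (abs(post) - abs(pre)) / abs(pre),
                 t_peak_s = t_peak, method = method),
            class = "pb_drug_effect")
}

#' Access-resistance quality control
#'
#' Baseline access resistance is the mean of the first `n_baseline` sweeps;
#' any sweep deviating from baseline by more than `max_dev` (default 20%)
#' marks the cell for discard.
#'
#' @param ra_mohm per-sweep access resistance values (MOhm).
#' @param n_baseline sweeps defining the baseline (default 3).
#' @param max_dev maximum tolerated fractional deviation.
#' @return list with `baseline_mohm`, `keep` (per-sweep logical) and
#'   `verdict` (`"keep"` or `"discard"`).
#' @export
qc_access_resistance <- function(ra_mohm, n_baseline = 3, max_dev = 0.2) {
  pb_assert(is.numeric(ra_mohm) && length(ra_mohm) >= 1L,
            "empty access-resistance series", "pb_input_error")
  baseline <- mean(head(ra_mohm, n_baseline))
  keep <- abs(ra_mohm - baseline) / baseline <= max_dev
  list(baseline_mohm = baseline, keep = keep,
       verdict = if (all(keep)) "keep" else "discard")
}

#' Detect a synaptic response at one sCRACM stimulation spot
#'
#' A spot responds when (a) the magnitude of the mean of the per-repeat
#' inward peaks exceeds `k_mean` times the baseline noise SD and (b) at
#' least `min_repeat_frac` of the repeats individually exceed `k_repeat`
#' noise SDs. Peaks are taken from the boxcar-smoothed (default 0.5 ms)
#' baseline-subtracted trace so a pure-noise extremum does not trip the
#' rule.
#'
#' @param point_epochs list of `pb_epoch` repeats (>= 2) for one spot.
#' @param noise_sd_pa baseline noise SD (pA, > 0).
#' @param k_mean,k_repeat,min_repeat_frac detection thresholds.
#' @param window_s peak search window.
#' @param smooth_ms boxcar width in ms.
#' @return list with `responded`, `mean_peak_pa`, `repeat_peaks_pa`,
#'   `thresholds` (the rule parameters used).
#' @export
scracm_detect <- function(point_epochs, noise_sd_pa,
                          k_mean = 3, k_repeat = 2, min_repeat_frac = 0.5,
                          window_s = c(0.002, 0.05), smooth_ms = 0.5) {
  pb_assert(noise_sd_pa > 0, "noise_sd_pa must be > 0", "pb_input_error")
  pb_assert(length(point_epochs) >= 2L, "need >= 2 repeats per spot",
            "pb_input_error")
  peaks <- vapply(point_epochs, function(ep)
    measure_epsc(ep, window_s, "inward", smooth_ms = smooth_ms)$peak_pa, 0)
  mean_peak <- mean(peaks)
  frac_above <- mean(abs(peaks) > k_repeat * noise_sd_pa)
  responded <- abs(mean_peak) > k_mean * noise_sd_pa &&
    frac_above >= min_repeat_frac
  list(responded = responded,
       mean_peak_pa = mean_peak,
       repeat_peaks_pa = peaks,
       thresholds = list(k_mean = k_mean, k_repeat = k_repeat,
                         min_repeat_frac = min_repeat_frac,
                         smooth_ms = smooth_ms))
}

#' Assemble a per-cell sCRACM map
#'
#' @param cell_id identifier.
#' @param points data.frame with one row per stimulation spot: columns
#'   `path_um`, `responded` (logical), and optionally `mean_peak_pa`,
#'   `euclid_um`.
#' @param noise_sd_pa baseline noise estimate.
#' @return object of class `pb_scracm_map`.
#' @export
scracm_map <- function(cell_id, points, noise_sd_pa) {
  pb_assert(is.data.frame(points) &&
              all(c("path_um", "responded") %in% names(points)),
            "points needs columns path_um, responded", "pb_input_error")
  structure(list(cell_id = cell_id, points = points,
                 noise_sd_pa = noise_sd_pa),
            class = "pb_scracm_map")
}

#' Response frequency versus dendritic distance
#'
#' For each distance bin, the fraction of cells that showed a synaptic
#' response at that distance: the numerator counts cells with at least one
#' responding spot in the bin, the denominator cells with at least one
#' tested spot in the bin. Bins nobody tested are omitted.
#'
#' @param maps list of `pb_scracm_map` (one per cell).
#' @param bin_um bin width in micrometres (default 10, matching the 8-10 um
#'   spot spacing).
#' @return data.frame with `bin_lo_um`, `bin_hi_um`, `bin_center_um`,
#'   `fraction`, `n_cells`.
#' @export
response_frequency_curve <- function(maps, bin_um = 10) {
  pb_assert(length(maps) >= 1L, "empty map list", "pb_input_error")
  pb_assert(bin_um > 0, "bin width must be > 0", "pb_input_error")
  all_d <- unlist(lapply(maps, function(m) m$points$path_um))
  edges <- seq(0, (floor(max(all_d) / bin_um) + 1) * bin_um, by = bin_um)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  tested <- resp <- integer(length(lo))
  for (m in maps) {
    b <- findInterval(m$points$path_um, edges, rightmost.closed = FALSE)
    for (j in unique(b)) {
      tested[j] <- tested[j] + 1L
      if (any(m$points$responded[b == j])) resp[j] <- resp[j] + 1L
    }
  }
  keep <- tested > 0L
  data.frame(bin_lo_um = lo[keep], bin_hi_um = hi[keep],
             bin_center_um = (lo[keep] + hi[keep]) / 2,
             fraction = resp[keep] / tested[keep],
             n_cells = tested[keep])
}
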