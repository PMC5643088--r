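test_that("spike detection by the 5 V/s criterion matches the exhaustive
           per-sample scan and keeps truncated spikes", {
  # sub-criterion ramp: no spikes
  rate <- 2e4
  ramp <- recording(-60 + (0:19999) / rate * 1000 * 1,  # 1 V/s in mV/s
                    rate, "cclamp_voltage")
  expect_equal(nrow(detect_spikes(ramp)), 0)

  # template spikes at known times: detector == oracle, exactly
  times <- c(0.2, 0.5, 0.8, 1.1, 1.4, 1.55, 1.7, 1.8, 1.9, 1.95)
  rec <- make_template_trace(times, duration_s = 2, rate_hz = rate)
  sp <- detect_spikes(rec)
  idx_oracle <- oracle_detect(rec$samples, rate)
  expect_equal(nrow(sp), 10)
  expect_identical(sp$i_thresh, idx_oracle)

  # truncated spikelet (peak -20 mV) is still an event
  rec_tr <- make_template_trace(0.5, v_peak = -20)
  sp_tr <- detect_spikes(rec_tr)
  expect_equal(nrow(sp_tr), 1)
  expect_lt(sp_tr$v_peak_mv, -15)

  # rate precondition
  expect_error(detect_spikes(recording(rnorm(100), 5e3, "cclamp_voltage")),
               class = "pb_input_error")
})

test_that("phase plots are piecewise-constant for triangular spikes,
           translate with voltage offsets, and agree with the brute-force
           derivative maximum", {
  rec <- make_template_trace(0.5, rate_hz = 2e4,
                             rise_v_per_s = 100, fall_v_per_s = 80)
  pp <- phase_plot(rec, c(0.49, 0.52))
  d <- pp$dvdt_v_per_s[!is.na(pp$dvdt_v_per_s)]
  # two plateaus at +100 and -80 V/s (edge samples average the two slopes)
  expect_equal(max(d), 100, tolerance = 0.01)
  expect_equal(min(d), -80, tolerance = 0.01)
  expect_false(is.na(pp$i_thresh))

  # +10 mV translation shifts V, leaves dV/dt untouched
  rec10 <- rec
  rec10$samples <- rec$samples + 10
  pp10 <- phase_plot(rec10, c(0.49, 0.52))
  expect_equal(pp10$v_mv, pp$v_mv + 10)
  expect_equal(pp10$dvdt_v_per_s, pp$dvdt_v_per_s)

  # max dV/dt equals the exhaustive finite-difference maximum
  brute <- max((rec$samples[3:length(rec$samples)] -
                  rec$samples[1:(length(rec$samples) - 2)]) *
                 rec$rate_hz / 2000)
  expect_equal(max(d), brute)

  expect_error(phase_plot(rec, c(1.9, 2.5)), class = "pb_range_error")
})

test_that("evoked classification uses the latency window with the
           earliest-wins rule", {
  sp <- data.frame(t_thresh_s = c(0.104, 0.108, 0.530),
                   v_thresh_mv = -45, t_peak_s = c(0.105, 0.109, 0.531),
                   v_peak_mv = 10, i_thresh = 1:3)
  out <- classify_evoked(sp, 0.1)
  expect_identical(out$is_evoked, c(TRUE, FALSE, FALSE))
  expect_equal(out$latency_s[1], 0.004)
  # spike 30 ms after the only pulse: spontaneous
  out2 <- classify_evoked(sp[3, ], 0.5)
  expect_identical(out2$is_evoked, FALSE)
  # overlapping stimulus windows
  expect_error(classify_evoked(sp, c(0.1, 0.105)),
               class = "pb_protocol_error")
})

test_that("normalized phase equals the brute-force mean-ISI computation on
           the 4 s window", {
  # regular ISIs of 1 s, last spike 0.5 s before the stimulus
  st <- seq(1.5, 9.5, by = 1)
  ph <- normalized_phase(10, st)
  expect_equal(ph$phase, 0.5)
  # stimulus immediately after a spike
  expect_lt(normalized_phase(9.5001, st)$phase, 0.001)
  # jittered pacemaker vs direct recomputation
  set.seed(104)
  jt <- cumsum(rnorm(30, 0.8, 0.05))
  onset <- max(jt) + 0.3
  ph_j <- normalized_phase(onset, jt)
  in_win <- jt[jt >= onset - 4 & jt < onset]
  expect_equal(ph_j$mean_isi_s, mean(diff(in_win)))
  expect_equal(ph_j$phase, (onset - max(in_win)) / mean(diff(in_win)))
  # insufficient baseline
  expect_error(normalized_phase(2, c(1.9)),
               class = "pb_insufficient_baseline_error")
})

test_that("phase-independent evoked spikes give null threshold/peak
           differences and reset ratios near one", {
  # simulator with no phase dependence of the evoked waveform; the shallow
  # oscillation keeps a phase-independent threshold reachable at every
  # phase without riding the 5 V/s criterion
  ecs <- list()
  for (i in 1:3) {
    cfg <- sim_config(seed = 200 + i,
                      pacemaker = list(ahp_mv = -45),
                      spikelet = list(phase_amp_min_mv = 10,
                                      phase_thresh_shift_mv = 0))
    prot <- stim_protocol(seq(5, 90, by = 5))
    sim <- simulate_pacemaker(cfg, prot, duration_s = 95)
    sp <- classify_evoked(detect_spikes(sim$soma), prot)
    ecs[[i]] <- do.call(rbind, lapply(prot$pulse_onsets_s, function(o)
      tryCatch(evoked_comparison(sp, o), error = function(e) NULL)))
  }
  ec <- do.call(rbind, ecs)
  expect_gt(nrow(ec), 40)
  sem_t <- sd(ec$d_thresh_mv) / sqrt(nrow(ec))
  sem_p <- sd(ec$d_peak_mv) / sqrt(nrow(ec))
  sem_r <- sd(ec$reset_ratio) / sqrt(nrow(ec))
  expect_lt(abs(mean(ec$d_thresh_mv)), 3 * sem_t + 0.05)
  expect_lt(abs(mean(ec$d_peak_mv)), 3 * sem_p + 0.05)
  expect_lt(abs(mean(ec$reset_ratio) - 1), 3 * sem_r + 0.01)
})

test_that("intra-stimulus rate follows the spike-per-stimulus construction
           and Bernoulli thinning", {
  # one spike per stimulus, 10 stimuli at 10 Hz -> 10 spikes/s
  sp <- data.frame(t_thresh_s = seq(0.102, 1.002, by = 0.1),
                   v_thresh_mv = -45,
                   t_peak_s = seq(0.103, 1.003, by = 0.1),
                   v_peak_mv = 10, i_thresh = 1:10)
  prot <- stim_protocol(seq(0.1, 1.0, by = 0.1))
  spc <- classify_evoked(sp, prot)
  tr <- intra_stimulus_rate(spc, prot)
  expect_equal(tr$intra_rate_hz, 10, tolerance = 1e-9)
  expect_equal(tr$follow_fraction, 1)
  # 5 stimuli at 20 Hz
  prot20 <- stim_protocol(seq(0.1, 0.3, by = 0.05))
  sp20 <- data.frame(t_thresh_s = prot20$pulse_onsets_s + 0.002,
                     v_thresh_mv = -45,
                     t_peak_s = prot20$pulse_onsets_s + 0.003,
                     v_peak_mv = 10, i_thresh = 1:5)
  expect_equal(intra_stimulus_rate(classify_evoked(sp20, prot20),
                                   prot20)$intra_rate_hz,
               20, tolerance = 1e-9)
  # single stimulus
  expect_error(intra_stimulus_rate(sp, stim_protocol(0.1)),
               class = "pb_protocol_error")

  # Bernoulli thinning oracle: failure probability 0.2 over 100 trains
  set.seed(105)
  f <- 10; n_st <- 10
  rates <- replicate(100, {
    keep <- runif(n_st) >= 0.2
    on <- seq(0.1, by = 1 / f, length.out = n_st)
    spx <- data.frame(t_thresh_s = on[keep] + 0.002, v_thresh_mv = -45,
                      t_peak_s = on[keep] + 0.003, v_peak_mv = 10,
                      i_thresh = seq_len(sum(keep)))
    if (nrow(spx) == 0) return(0)
    intra_stimulus_rate(classify_evoked(spx, on), on)$intra_rate_hz
  })
  sem <- sd(rates) / sqrt(100)
  expect_lt(abs(mean(rates) - 0.8 * f), 3 * sem)
})

test_that("spike probability per intensity is the fraction of evoking
           trials and respects the binomial envelope", {
  expect_equal(spike_probability(list(`0.5` = rep(TRUE, 10)))$p_spike, 1)
  # sigmoidal truth within the binomial 95% envelope at each intensity
  set.seed(106)
  intens <- seq(0, 1, by = 0.2)
  p_true <- 1 / (1 + exp(-(intens - 0.4) / 0.08))
  trials <- setNames(lapply(seq_along(intens), function(i)
    runif(50) < p_true[i]), intens)
  curve <- spike_probability(trials)
  for (i in seq_along(intens)) {
    ci <- qbinom(c(0.025, 0.975), 50, p_true[i]) / 50
    expect_gte(curve$p_spike[i], ci[1])
    expect_lte(curve$p_spike[i], ci[2])
  }
  expect_error(spike_probability(list()), class = "pb_input_error")
  expect_error(spike_probability(list(`1` = TRUE)), class = "pb_input_error")
})

test_that("soma-axon matching is one-to-one, symmetric, and puts faithful
           propagation on the identity line", {
  soma <- cumsum(runif(20, 0.05, 0.2))
  axon <- soma + 0.001
  mm <- match_axon_soma(soma, axon)
  expect_equal(mm$n_matched, 20)
  expect_length(mm$unmatched_soma, 0)
  ok <- !is.na(mm$pairs$soma_rate_hz) & !is.na(mm$pairs$axon_rate_hz)
  expect_equal(mm$pairs$axon_rate_hz[ok], mm$pairs$soma_rate_hz[ok],
               tolerance = 1e-9)

  # axon missing every 2nd event: half matched, pairs below identity
  axon_half <- axon[seq(1, 20, by = 2)]
  mm2 <- match_axon_soma(soma, axon_half)
  expect_equal(mm2$n_matched, 10)
  ok2 <- !is.na(mm2$pairs$soma_rate_hz) & !is.na(mm2$pairs$axon_rate_hz)
  expect_true(all(mm2$pairs$axon_rate_hz[ok2] <=
                    mm2$pairs$soma_rate_hz[ok2] + 1e-9))

  # symmetry under exchanging trains
  mm_sw <- match_axon_soma(axon, soma)
  expect_equal(mm_sw$n_matched, mm$n_matched)
  expect_equal(mm_sw$pairs$soma_t, mm$pairs$axon_t)

  # zero tolerance with jitter: no matches
  expect_equal(match_axon_soma(soma, soma + 1e-4, tolerance_s = 0)$n_matched,
               0)
})
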