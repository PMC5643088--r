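test_that("EPSC peak measurement is baseline-subtracted and recovers
           generative amplitudes", {
  # noiseless square pulse of -100 pA inside the window
  rate <- 1e4
  t <- seq(-0.05, 0.1 - 1 / rate, by = 1 / rate)
  y <- ifelse(t >= 0.005 & t < 0.02, -100, 0)
  m <- measure_epsc(epoch(t, y))
  expect_equal(m$peak_pa, -100)
  expect_true(m$t_peak_s >= 0.005 && m$t_peak_s < 0.02)

  # baseline offset leaves the measurement unchanged
  m_off <- measure_epsc(epoch(t, y + 50))
  expect_equal(m_off$peak_pa, -100)
  expect_equal(m_off$baseline_pa, 50)

  # window outside the epoch
  expect_error(measure_epsc(epoch(t, y), window_s = c(0.2, 0.3)),
               class = "pb_range_error")

  # Monte-Carlo recovery of a biexponential amplitude under noise; the
  # 0.5 ms boxcar keeps the extremum-of-noise bias below ~1 pA at this SNR
  set.seed(101)
  peaks <- replicate(100, {
    ep <- make_epsc_epoch(-80, noise_sd = 2)
    measure_epsc(ep, smooth_ms = 0.5)$peak_pa
  })
  sem <- sd(peaks) / sqrt(length(peaks))
  expect_lt(abs(mean(peaks) - (-80)), 3 * sem + 1)
})

test_that("paired-pulse ratio is offset- and gain-invariant and recovers the
           generative release fraction", {
  ep1 <- make_epsc_epoch(-200)
  ep2 <- make_epsc_epoch(-166)
  r <- compute_ppr(measure_epsc(ep1), measure_epsc(ep2))
  expect_equal(r, 0.83)
  # identity
  expect_equal(compute_ppr(measure_epsc(ep1), measure_epsc(ep1)), 1.0)
  # offset and gain invariance
  for (gain in c(0.5, 2)) {
    ra <- compute_ppr(measure_epsc(epoch(ep1$t, gain * ep1$y + 30)),
                      measure_epsc(epoch(ep2$t, gain * ep2$y + 30)))
    expect_equal(ra, 0.83, tolerance = 1e-12)
  }
  # unreliable denominator
  expect_error(compute_ppr(measure_epsc(make_epsc_epoch(-5)),
                           measure_epsc(make_epsc_epoch(-4)),
                           noise_sd_pa = 2),
               class = "pb_unreliable_denominator_error")

  # generative recovery: depletion model with second-release fraction 0.7
  set.seed(102)
  prot <- stim_protocol(c(0.1, 0.15))
  pprs <- vapply(1:50, function(i) {
    cfg <- sim_config(seed = 1000 + i,
                      synapse = list(release_fraction_2nd = 0.7, g_nmda = 0))
    sim <- simulate_epsc(cfg, prot, holding_mv = -70)
    eps <- extract_epochs(sim$rec, prot, 0.02, 0.05)
    compute_ppr(measure_epsc(eps[[1]], smooth_ms = 0.5),
                measure_epsc(eps[[2]], smooth_ms = 0.5))
  }, 0)
  sem <- sd(pprs) / sqrt(50)
  expect_lt(abs(mean(pprs) - 0.7), 3 * sem + 0.01)

  # noiseless loop closure: measured PPR equals the release fraction up to
  # the first pulse's residual decay under the second baseline window
  cfg0 <- sim_config(synapse = list(release_fraction_2nd = 0.83, g_nmda = 0))
  sim0 <- simulate_epsc(cfg0, prot, holding_mv = -70, noise = FALSE)
  eps0 <- extract_epochs(sim0$rec, prot, 0.02, 0.05)
  expect_equal(compute_ppr(measure_epsc(eps0[[1]]), measure_epsc(eps0[[2]])),
               0.83, tolerance = 2e-3)
})

test_that("AMPA:NMDA ratio follows the fixed-latency rule and matches the
           closed-form value from the generative kinetics", {
  # arithmetic case: AMPA peak -143 pA, +40 mV value +100 pA at t*+40 ms
  rate <- 1e4
  t <- seq(-0.05, 0.15 - 1 / rate, by = 1 / rate)
  y70 <- ifelse(t >= 0.004 & t < 0.006, -143, 0)
  y40 <- ifelse(t >= 0.040 & t < 0.050, 100, 0)
  an <- compute_ampa_nmda(epoch(t, y70), epoch(t, y40 + rnorm(length(t), 0, 1)))
  expect_equal(an$ratio, 1.43, tolerance = 0.02)
  expect_true(an$reliable)

  # degenerate: pure AMPA at both potentials decays away long before
  # t* + 40 ms, so the ratio is flagged unreliable
  ya70 <- make_epsc_epoch(-100, noise_sd = 1)
  ya40 <- make_epsc_epoch(100 * 40 / 70, noise_sd = 1)
  an2 <- compute_ampa_nmda(ya70, ya40)
  expect_false(an2$reliable)

  # closed-form oracle from the generative kinetics: compute the expected
  # ratio analytically from the config, then require the measured ratio to
  # match within 5% over 50 seeds
  syn <- list(g_ampa = 1.2, g_nmda = 0.9)
  cfg0 <- sim_config(synapse = syn)
  sy <- cfg0$synapse
  biexp <- function(ts, tr_ms, td_ms) {
    tr <- tr_ms / 1000; td <- td_ms / 1000
    tpk <- tr * td / (td - tr) * log(td / tr)
    ifelse(ts >= 0, (exp(-ts / td) - exp(-ts / tr)) /
             (exp(-tpk / td) - exp(-tpk / tr)), 0)
  }
  b70 <- mg_block(-70, sy$mg_mm, sy$mg_k0_mm, sy$mg_vc_mv)
  b40 <- mg_block(40, sy$mg_mm, sy$mg_k0_mm, sy$mg_vc_mv)
  # true AMPA-peak time at -70 mV: extremum of the full (AMPA + residual
  # blocked NMDA) current on a fine grid
  tg <- seq(0, 0.05, by = 1e-5)
  i70 <- (sy$g_ampa * biexp(tg, sy$tau_rise_ms, sy$tau_decay_ampa_ms) +
            sy$g_nmda * b70 * biexp(tg, sy$tau_rise_nmda_ms,
                                    sy$tau_decay_nmda_ms)) * (-70)
  t_star <- tg[which.min(i70)]
  amp_peak <- min(i70)
  nmda_val <- (sy$g_ampa * biexp(t_star + 0.04, sy$tau_rise_ms,
                                 sy$tau_decay_ampa_ms) +
                 sy$g_nmda * b40 * biexp(t_star + 0.04, sy$tau_rise_nmda_ms,
                                         sy$tau_decay_nmda_ms)) * 40
  ratio_true <- abs(amp_peak) / abs(nmda_val)
  prot <- stim_protocol(0.1)
  ratios <- vapply(1:50, function(i) {
    lo <- simulate_epsc(sim_config(seed = 3000 + i, synapse = syn),
                        prot, holding_mv = -70)
    hi <- simulate_epsc(sim_config(seed = 4000 + i, synapse = syn),
                        prot, holding_mv = 40)
    compute_ampa_nmda(extract_epochs(lo$rec, prot, 0.02, 0.15)[[1]],
                      extract_epochs(hi$rec, prot, 0.02, 0.15)[[1]])$ratio
  }, 0)
  expect_lt(abs(mean(ratios) - ratio_true) / ratio_true, 0.05)
})

test_that("IV normalization anchors at -80 mV and flags rectification by a
           poorer linear fit", {
  holds <- c(-80, -60, -40, 0, 40)
  # ohmic synapse reversing at 0 mV
  peaks <- holds * 1.5
  iv <- normalize_iv(holds, peaks)
  expect_equal(iv$iv$norm[iv$iv$holding_mv == -80], 1.0)
  expect_lt(abs(iv$fit$reversal_mv), 1)
  expect_gt(iv$fit$r_squared, 0.999)

  # inward rectification: +40 mV current halved
  peaks_rect <- peaks
  peaks_rect[holds == 40] <- peaks_rect[holds == 40] / 2
  iv_rect <- normalize_iv(holds, peaks_rect)
  expect_lt(iv_rect$fit$r_squared, iv$fit$r_squared)

  # single point: no fit, normalization still returned
  single <- normalize_iv(-80, -120)
  expect_null(single$fit)
  expect_equal(single$iv$norm, 1)

  # no -80 mV point
  expect_error(normalize_iv(c(-70, 40), c(-100, 50)),
               class = "pb_normalization_error")
})

test_that("drug effects are percent change relative to control and recover a
           generative potentiation factor", {
  pre <- lapply(1:3, function(i) make_epsc_epoch(-200))
  post <- lapply(1:3, function(i) make_epsc_epoch(-113.4))
  de <- drug_effect(pre, post)
  expect_equal(de$percent_change, 100 * (113.4 - 200) / 200, tolerance = 1e-9)
  expect_equal(round(de$percent_change, 1), -43.3)
  # identity
  expect_equal(drug_effect(pre, pre)$percent_change, 0)
  # generative recovery of a 1.8622x NMDA potentiation (0-Mg, -60 mV)
  prot <- stim_protocol(0.1)
  pc <- vapply(1:30, function(i) {
    cfg_a <- sim_config(seed = 5000 + i, synapse = list(g_ampa = 0))
    cfg_b <- sim_config(seed = 6000 + i, synapse = list(g_ampa = 0))
    pre_s <- lapply(1:3, function(k) {
      s <- simulate_epsc(sim_config(seed = 5000 + i * 7 + k,
                                    synapse = list(g_ampa = 0)),
                         prot, holding_mv = -60, mg_mm = 0)
      extract_epochs(s$rec, prot, 0.02, 0.15)[[1]]
    })
    post_s <- lapply(1:3, function(k) {
      s <- simulate_epsc(sim_config(seed = 6000 + i * 7 + k,
                                    synapse = list(g_ampa = 0)),
                         prot, holding_mv = -60, mg_mm = 0,
                         nmda_scale = 1.8622)
      extract_epochs(s$rec, prot, 0.02, 0.15)[[1]]
    })
    drug_effect(pre_s, post_s, window_s = c(0.002, 0.1))$percent_change
  }, 0)
  sem <- sd(pc) / sqrt(30)
  expect_lt(abs(mean(pc) - 86.22), 3 * sem + 1)
})

test_that("access-resistance QC applies the 20% deviation rule", {
  expect_equal(qc_access_resistance(c(10, 10, 10, 11.9))$verdict, "keep")
  expect_equal(qc_access_resistance(c(10, 10, 10, 12.5))$verdict, "discard")
  expect_equal(qc_access_resistance(rep(8, 10))$verdict, "keep")
  expect_error(qc_access_resistance(numeric(0)), class = "pb_input_error")
})

test_that("sCRACM response detection separates signal from noise with the
           repeat-consistency rule", {
  rate <- 1e4
  t <- seq(-0.05, 0.1 - 1 / rate, by = 1 / rate)
  # clear response: -30 pA on 2 pA noise
  set.seed(103)
  eps_sig <- lapply(1:3, function(i)
    epoch(t, rnorm(length(t), 0, 2) +
            ifelse(t >= 0.003 & t < 0.02, -30, 0)))
  expect_true(scracm_detect(eps_sig, 2)$responded)

  # mean above threshold but repeats inconsistent: 1 of 4 strong, 3 flat
  eps_mix <- c(lapply(1:1, function(i)
    epoch(t, ifelse(t >= 0.003 & t < 0.02, -28, 0))),
    lapply(1:3, function(i) epoch(t, rep(0, length(t)))))
  det <- scracm_detect(eps_mix, 2)
  expect_false(det$responded)

  expect_error(scracm_detect(eps_sig, 0), class = "pb_input_error")
  expect_error(scracm_detect(eps_sig[1], 2), class = "pb_input_error")
})

test_that("response-frequency curve bookkeeping: numerators and denominators
           are per-cell", {
  mk <- function(id, d, resp) scracm_map(id, data.frame(path_um = d,
                                                        responded = resp), 2)
  # saturation: every tested point responds
  maps <- lapply(1:5, function(i) mk(i, c(5, 15, 25), c(TRUE, TRUE, TRUE)))
  rc <- response_frequency_curve(maps)
  expect_true(all(rc$fraction == 1))
  expect_true(all(rc$n_cells == 5))

  # only cell A tested beyond 100 um, did not respond there
  maps2 <- list(mk("A", c(5, 105), c(TRUE, FALSE)),
                mk("B", 5, TRUE))
  rc2 <- response_frequency_curve(maps2)
  distal <- rc2[rc2$bin_lo_um == 100, ]
  expect_equal(distal$n_cells, 1)
  expect_equal(distal$fraction, 0)
  expect_equal(rc2$n_cells[rc2$bin_lo_um == 0], 2)

  expect_error(response_frequency_curve(list()), class = "pb_input_error")
})
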