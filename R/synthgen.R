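# Seeded synthetic-data generator. Every modality the analysis modules
# consume can be produced here with known ground truth: depressing AMPAR /
# slow NMDAR EPSCs with voltage-dependent Mg block, sCRACM spot grids on a
# morphology, phenomenological pacemaking voltage traces with
# phase-dependent evoked spikelets and faithful axonal propagation, and
# dF/F0 line scans. The pacemaker is deliberately phenomenological (a
# sawtooth oscillator with template spikes), trading biophysical realism
# for analytically known truth.

#' Build a simulation configuration
#'
#' Defaults encode the study conditions: 20 Hz paired pulses with a second
#' release fraction of 0.83, AMPA kinetics (1 ms rise / 5 ms decay) versus
#' slow NMDA kinetics (5 ms rise / 100 ms decay) under a standard Boltzmann
#' Mg block (K0 = 3.57 mM, Vc = 16.13 mV), a ~1.25 Hz pacemaker with 5% ISI
#' CV, evoked-spike latency ~2 ms, a PPN-like synapse density confined to
#' <= 80 um path distance, and 6 ms / 512-pixel line scans. Any field can
#' be overridden per sub-list.
#'
#' @param seed integer RNG seed; identical configurations (including seed)
#'   reproduce bit-identical datasets.
#' @param rate_hz sampling rate for simulated electrophysiology.
#' @param pacemaker,spikelet,synapse,scracm,linescan,noise named lists of
#'   overrides merged into the defaults.
#' @param failure_p per-stimulus probability that no spike is evoked.
#' @param reset_mode `"reset"` (evoked spike restarts the cycle) or
#'   `"delay"` (apamin-like: first post-stimulus ISI scaled by
#'   `delay_factor`).
#' @param delay_factor ISI scale factor used in `"delay"` mode.
#' @return a `pb_sim_config` list.
#' @export
sim_config <- function(seed = 1, rate_hz = 1e4,
                       pacemaker = list(), spikelet = list(),
                       synapse = list(), scracm = list(),
                       linescan = list(), noise = list(),
                       failure_p = 0,
                       reset_mode = c("reset", "delay"),
                       delay_factor = 1.5) {
  reset_mode <- match.arg(reset_mode)
  cfg <- list(
    seed = as.integer(seed),
    rate_hz = rate_hz,
    pacemaker = utils::modifyList(list(
      mean_isi_s = 0.8, isi_cv = 0.05,
      thresh_mv = -40, ahp_mv = -65,
      rise_ms = 0.5, fall_ms = 1.0,
      jitter_mv = 0.2), pacemaker),
    spikelet = utils::modifyList(list(
      phase_amp_min_mv = -20,   # evoked somatic peak at phase 0 (truncated)
      phase_amp_max_mv = 10,    # spontaneous / late-phase peak
      phase_thresh_shift_mv = -10,  # threshold shift at phase 0
      latency_ms_mean = 2, latency_ms_sd = 0.3,
      refractory_s = 0.004), spikelet),
    synapse = utils::modifyList(list(
      g_ampa = 0.63, g_nmda = 1.0,          # nS
      tau_rise_ms = 1, tau_decay_ampa_ms = 5,
      tau_rise_nmda_ms = 5, tau_decay_nmda_ms = 100,
      release_fraction_2nd = 0.83,
      e_rev_mv = 0,
      mg_mm = 1, mg_k0_mm = 3.57, mg_vc_mv = 16.13), synapse),
    scracm = utils::modifyList(list(
      density_profile = "ppn_like",  # or "uniform"
      cutoff_um = 80, spot_spacing_um = 10,
      noise_sd_pa = 2, amp_meanlog = log(30), amp_sdlog = 0.4,
      n_repeats = 3), scracm),
    linescan = utils::modifyList(list(
      n_pixels = 512L, line_period_s = 0.006,
      structure_px = 150:349, background_px = 420:499,
      f_cell = 100, f_bg = 20, read_noise = 1,
      poisson = TRUE), linescan),
    noise = utils::modifyList(list(
      vclamp_pa = 2, cclamp_mv = 0.1, loose_seal = 1), noise),
    failure_p = failure_p,
    reset_mode = reset_mode,
    delay_factor = delay_factor)
  pb_assert(cfg$failure_p >= 0 && cfg$failure_p <= 1,
            "failure_p must be in [0,1]", "pb_input_error")
  taus <- with(cfg$synapse, c(tau_rise_ms, tau_decay_ampa_ms,
                              tau_rise_nmda_ms, tau_decay_nmda_ms))
  pb_assert(all(taus > 0), "time constants must be > 0", "pb_input_error")
  structure(cfg, class = "pb_sim_config")
}

#' Voltage-dependent Mg block of the NMDA conductance
#'
#' Standard Boltzmann form `B(V) = 1 / (1 + (mg/K0) * exp(-V/Vc))`:
#' monotonically increasing in V, equal to 1 in zero Mg.
#'
#' @param v_mv membrane potential (mV).
#' @param mg_mm extracellular Mg concentration (mM).
#' @param k0_mm,vc_mv Boltzmann parameters; lowering the Mg sensitivity
#'   (GluN2D-like receptors) corresponds to raising `k0_mm`.
#' @return unblocked fraction in (0, 1].
#' @export
mg_block <- function(v_mv, mg_mm, k0_mm = 3.57, vc_mv = 16.13) {
  1 / (1 + (mg_mm / k0_mm) * exp(-v_mv / vc_mv))
}

# normalized biexponential waveform, unit peak, 0 for t < 0
biexp_unit <- function(t_s, tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms / 1000; td <- tau_decay_ms / 1000
  tpk <- tr * td / (td - tr) * log(td / tr)
  norm <- exp(-tpk / td) - exp(-tpk / tr)
  w <- ifelse(t_s >= 0, (exp(-t_s / td) - exp(-t_s / tr)) / norm, 0)
  w
}

#' Simulate stimulus-evoked EPSC sweeps
#'
#' Per pulse k the synaptic conductance is `g_ampa * rf^(k-1)` (vesicle
#' depletion with second-release fraction rf) for the fast component plus
#' `g_nmda * B(V)` for the slow component, each shaped by a unit-peak
#' biexponential; the current is `g(t) * (V_hold - E_rev)` plus Gaussian
#' noise. Ground truth carries the noiseless recording, the analytic
#' component peaks and the release fraction.
#'
#' @param cfg a `pb_sim_config`.
#' @param protocol a `pb_protocol` of pulse onsets.
#' @param holding_mv holding potential (mV).
#' @param mg_mm Mg concentration override (e.g. 0 for the nominally
#'   Mg-free NMDA-isolation condition).
#' @param ampa_scale,nmda_scale conductance scale factors (drug effects are
#'   modelled as scaling, e.g. an antagonist < 1, a potentiator > 1).
#' @param noise add recording noise? (FALSE gives the noiseless trace.)
#' @param duration_s sweep length; default covers the last pulse + 0.4 s.
#' @return list with `rec` (a voltage-clamp `pb_recording`, t0 = 0) and
#'   `truth`.
#' @export
simulate_epsc <- function(cfg, protocol, holding_mv,
                          mg_mm = cfg$synapse$mg_mm,
                          ampa_scale = 1, nmda_scale = 1,
                          noise = TRUE, duration_s = NULL) {
  pb_assert(inherits(cfg, "pb_sim_config"), "not a pb_sim_config",
            "pb_input_error")
  set.seed(cfg$seed)
  sy <- cfg$synapse
  onsets <- protocol$pulse_onsets_s
  pb_assert(length(onsets) >= 1L, "protocol has no pulses", "pb_input_error")
  dur <- duration_s %||% (max(onsets) + 0.4)
  n <- round(dur * cfg$rate_hz)
  t <- (seq_len(n) - 1) / cfg$rate_hz
  drive <- holding_mv - sy$e_rev_mv
  b <- mg_block(holding_mv, mg_mm, sy$mg_k0_mm, sy$mg_vc_mv)
  i <- numeric(n)
  amp_ampa <- numeric(length(onsets))
  for (k in seq_along(onsets)) {
    rel <- t - onsets[k]
    g_a <- sy$g_ampa * ampa_scale * sy$release_fraction_2nd^(k - 1)
    amp_ampa[k] <- g_a * drive
    i <- i + g_a * biexp_unit(rel, sy$tau_rise_ms, sy$tau_decay_ampa_ms) * drive +
      sy$g_nmda * nmda_scale * b *
      biexp_unit(rel, sy$tau_rise_nmda_ms, sy$tau_decay_nmda_ms) * drive
  }
  clean <- i
  if (noise) i <- i + rnorm(n, 0, cfg$noise$vclamp_pa)
  rec <- recording(i, cfg$rate_hz, "vclamp_current",
                   holding_mv = holding_mv, internal_solution = "cesium")
  truth <- list(noiseless = recording(clean, cfg$rate_hz, "vclamp_current",
                                      holding_mv = holding_mv,
                                      internal_solution = "cesium"),
                ampa_component_peak_pa = amp_ampa,
                nmda_peak_conductance_ns = sy$g_nmda * nmda_scale * b,
                release_fraction_2nd = sy$release_fraction_2nd,
                mg_unblocked = b,
                holding_mv = holding_mv)
  list(rec = rec, truth = truth)
}

# ---- pacemaker --------------------------------------------------------------

draw_isi <- function(cfg) {
  m <- cfg$pacemaker$mean_isi_s; cv <- cfg$pacemaker$isi_cv
  if (cv <= 0) return(m)
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(1, log(m) - sdlog^2 / 2, sdlog)
}

#' Simulate a pacemaking SNc neuron with optogenetically evoked spikes
#'
#' Spontaneous spikes arise from a sawtooth oscillator with lognormal ISIs.
#' Each stimulus evokes a spike with probability `1 - failure_p` at a short
#' latency, except under `drug_mode = "nbqx"` (no evoked spikes; AMPAR
#' block) -- `drug_mode = "cpp"` changes nothing by construction (NMDAR
#' independence as a testable null). The evoked somatic waveform
#' interpolates linearly with the oscillation phase between a truncated,
#' hyperpolarized-threshold spikelet at phase 0 and the full spontaneous
#' waveform at phase 1. After an evoked spike the oscillator either resets
#' (`reset_mode = "reset"`) or restarts with its first ISI scaled by
#' `delay_factor` (`"delay"`, the apamin-like mode). Every somatic spike
#' emits an axonal event 1 ms later; the axon is returned as a loose-seal
#' trace. Spike times are snapped to the sample grid so template knots fall
#' on samples.
#'
#' @param cfg a `pb_sim_config`.
#' @param protocol optional `pb_protocol` (NULL for pure pacemaking).
#' @param duration_s trace duration.
#' @param drug_mode one of `"none"`, `"cpp"`, `"nbqx"`.
#' @return list with `soma` (current-clamp `pb_recording`), `axon`
#'   (loose-seal `pb_recording`), and `truth` (spike table with true
#'   thresholds/peaks/phases, stimulus outcomes, axon event times).
#' @export
simulate_pacemaker <- function(cfg, protocol = NULL, duration_s = 10,
                               drug_mode = c("none", "cpp", "nbqx", "apamin")) {
  pb_assert(inherits(cfg, "pb_sim_config"), "not a pb_sim_config",
            "pb_input_error")
  drug_mode <- match.arg(drug_mode)
  if (drug_mode == "apamin") cfg$reset_mode <- "delay"
  set.seed(cfg$seed)
  pm <- cfg$pacemaker; sk <- cfg$spikelet
  dt <- 1 / cfg$rate_hz
  snap <- function(x) round(x / dt) * dt
  onsets <- if (is.null(protocol)) numeric(0) else protocol$pulse_onsets_s
  stim_out <- data.frame(onset_s = onsets,
                         success = rep(FALSE, length(onsets)),
                         t_evoked_s = rep(NA_real_, length(onsets)),
                         phase = rep(NA_real_, length(onsets)))

  spikes <- list()
  add_spike <- function(t_th, phase, evoked, stim_index) {
    frac <- if (evoked) min(max(phase, 0), 1) else 1
    v_th <- pm$thresh_mv + sk$phase_thresh_shift_mv * (1 - frac) +
      rnorm(1, 0, pm$jitter_mv)
    v_pk <- sk$phase_amp_min_mv +
      (sk$phase_amp_max_mv - sk$phase_amp_min_mv) * frac +
      rnorm(1, 0, pm$jitter_mv)
    spikes[[length(spikes) + 1L]] <<- data.frame(
      t_thresh_s = snap(t_th), v_thresh_mv = v_th, v_peak_mv = v_pk,
      evoked = evoked, phase = if (evoked) phase else NA_real_,
      stim_index = stim_index)
  }

  t_last <- snap(0.05 + runif(1) * pm$mean_isi_s)
  add_spike(t_last, NA, FALSE, NA_integer_)
  last_was_evoked <- FALSE
  next_stim <- 1L
  repeat {
    isi <- draw_isi(cfg)
    if (last_was_evoked && cfg$reset_mode == "delay")
      isi <- isi * cfg$delay_factor
    t_next <- t_last + isi
    fired <- FALSE
    # a stimulus arriving up to one refractory period after the scheduled
    # spontaneous spike captures the cycle: the synaptic drive triggers the
    # imminent spike (phase ~ 1) rather than colliding with it
    while (next_stim <= length(onsets) &&
           onsets[next_stim] < t_next + sk$refractory_s) {
      t_s <- onsets[next_stim]
      if (t_s <= t_last + sk$refractory_s) {  # before the trace's first spike
        next_stim <- next_stim + 1L           # or inside the refractory gap
        next
      }
      success <- drug_mode != "nbqx" && runif(1) >= cfg$failure_p
      if (success) {
        lat <- max(rnorm(1, sk$latency_ms_mean, sk$latency_ms_sd), 0.5) / 1000
        t_ev <- snap(t_s + lat)
        phase <- (t_s - t_last) / isi
        add_spike(t_ev, phase, TRUE, next_stim)
        stim_out$success[next_stim] <- TRUE
        stim_out$t_evoked_s[next_stim] <- t_ev
        stim_out$phase[next_stim] <- phase
        t_last <- t_ev
        last_was_evoked <- TRUE
        next_stim <- next_stim + 1L
        fired <- TRUE
        break
      }
      next_stim <- next_stim + 1L
    }
    if (fired) next
    if (t_next > duration_s - 0.01) break
    t_last <- snap(t_next)
    add_spike(t_last, NA, FALSE, NA_integer_)
    last_was_evoked <- FALSE
  }
  sp <- do.call(rbind, spikes)
  sp <- sp[order(sp$t_thresh_s), ]

  # synthesize the somatic voltage from knot points
  rise_s <- pm$rise_ms / 1000; fall_s <- pm$fall_ms / 1000
  kx <- c(0); ky <- c(pm$ahp_mv)
  for (r in seq_len(nrow(sp))) {
    t_th <- sp$t_thresh_s[r]
    kx <- c(kx, t_th, t_th + rise_s, t_th + rise_s + fall_s)
    ky <- c(ky, sp$v_thresh_mv[r], sp$v_peak_mv[r], pm$ahp_mv)
  }
  # ramp toward the next (unrealized) threshold at the end of the trace
  kx <- c(kx, duration_s + 2 * dt)
  end_gap <- kx[length(kx)] - kx[length(kx) - 1]
  ky <- c(ky, pm$ahp_mv + (pm$thresh_mv - pm$ahp_mv) *
            min(1, end_gap / pm$mean_isi_s))
  keep <- !duplicated(kx)
  n <- round(duration_s * cfg$rate_hz)
  tt <- (seq_len(n) - 1) * dt
  v <- approx(kx[keep], ky[keep], xout = tt, rule = 2)$y
  v <- v + rnorm(n, 0, cfg$noise$cclamp_mv)
  soma <- recording(v, cfg$rate_hz, "cclamp_voltage",
                    internal_solution = "perforated")

  # axonal loose-seal trace: every somatic spike propagates at +1 ms
  ax_t <- sp$t_thresh_s + 0.001
  ax <- rnorm(n, 0, cfg$noise$loose_seal)
  blip <- 50 * c(0.5, 1, -0.7, -0.2)
  for (te in ax_t) {
    i0 <- round(te / dt) + 1
    idx <- i0:(i0 + 3)
    ok <- idx <= n
    ax[idx[ok]] <- ax[idx[ok]] + blip[ok]
  }
  axon <- recording(ax, cfg$rate_hz, "loose_seal",
                    internal_solution = "naCl_loose")

  list(soma = soma, axon = axon,
       truth = list(spikes = sp, stim = stim_out,
                    axon_event_times_s = ax_t,
                    mean_isi_s = pm$mean_isi_s,
                    drug_mode = drug_mode,
                    reset_mode = cfg$reset_mode,
                    delay_factor = cfg$delay_factor))
}

# ---- sCRACM -----------------------------------------------------------------

#' A straight test dendrite for mapping simulations
#'
#' Soma at the origin with an unbranched dendrite along +x, nodes every
#' `step_um`.
#' @param length_um dendrite length.
#' @param step_um node spacing.
#' @return a `pb_morphology`.
#' @export
straight_dendrite_morphology <- function(length_um = 160, step_um = 10) {
  xs <- seq(0, length_um, by = step_um)
  n <- length(xs)
  morphology(data.frame(id = seq_len(n),
                        type = c(1L, rep(3L, n - 1)),
                        x = xs, y = 0, z = 0,
                        radius = c(8, rep(1, n - 1)),
                        parent = c(-1L, seq_len(n - 1))))
}

#' Simulate an sCRACM mapping experiment for one cell
#'
#' Spots are registered to the morphology; under the `"ppn_like"` density
#' profile only spots with path distance <= `cutoff_um` (default 80 um) lie
#' over responsive synapses, under `"uniform"` every spot does. Responsive
#' spots produce inward EPSCs with lognormal amplitude; all spots carry
#' baseline noise.
#'
#' @param cfg a `pb_sim_config` (`cfg$scracm` holds the profile, noise and
#'   amplitude parameters).
#' @param morphology a `pb_morphology`; default a straight 160 um dendrite.
#' @param spots matrix / data.frame of spot coordinates (um), one row per
#'   spot; default a grid along the dendrite at the configured spacing.
#' @param cell_id identifier.
#' @return list with `cell_id`, `spots` (coordinates), `epochs` (list per
#'   spot of `pb_epoch` repeats), `noise_sd_pa`, `morphology`, and `truth`
#'   (per-spot path distance and responsiveness).
#' @export
simulate_scracm <- function(cfg, morphology = NULL, spots = NULL,
                            cell_id = "sim_cell") {
  pb_assert(inherits(cfg, "pb_sim_config"), "not a pb_sim_config",
            "pb_input_error")
  set.seed(cfg$seed)
  sc <- cfg$scracm
  m <- morphology %||% straight_dendrite_morphology(160, sc$spot_spacing_um)
  if (is.null(spots)) {
    xs <- seq(sc$spot_spacing_um / 2, max(m$x) - sc$spot_spacing_um / 2,
              by = sc$spot_spacing_um)
    spots <- cbind(x = xs, y = 0, z = 0)
  }
  spots <- as.matrix(spots)
  dists <- apply(spots, 1, function(p) path_distance(m, p))
  responsive <- if (sc$density_profile == "ppn_like")
    dists <= sc$cutoff_um else rep(TRUE, length(dists))
  rate <- cfg$rate_hz
  t <- seq(-0.05, 0.15 - 1 / rate, by = 1 / rate)
  sy <- cfg$synapse
  epochs <- lapply(seq_len(nrow(spots)), function(j) {
    lapply(seq_len(sc$n_repeats), function(r) {
      y <- rnorm(length(t), 0, sc$noise_sd_pa)
      if (responsive[j]) {
        amp <- rlnorm(1, sc$amp_meanlog, sc$amp_sdlog)
        y <- y - amp * biexp_unit(t, sy$tau_rise_ms, sy$tau_decay_ampa_ms)
      }
      epoch(t, y)
    })
  })
  list(cell_id = cell_id, spots = spots, epochs = epochs,
       noise_sd_pa = sc$noise_sd_pa, morphology = m,
       truth = data.frame(path_um = dists, responsive = responsive))
}

#' Assemble an sCRACM map from raw spot recordings
#'
#' Registers each spot to the morphology (path distance, with the Euclidean
#' distance from the soma emitted alongside) and applies the response
#' detection rule.
#'
#' @param cell_id identifier.
#' @param morphology a `pb_morphology`.
#' @param spots spot coordinates (rows).
#' @param epochs list (per spot) of lists of `pb_epoch` repeats.
#' @param noise_sd_pa baseline noise SD.
#' @param ... passed to [scracm_detect()].
#' @return a `pb_scracm_map`.
#' @export
build_scracm_map <- function(cell_id, morphology, spots, epochs,
                             noise_sd_pa, ...) {
  spots <- as.matrix(spots)
  soma <- unlist(morphology[morphology$parent == -1, c("x", "y", "z")])
  rows <- lapply(seq_len(nrow(spots)), function(j) {
    det <- scracm_detect(epochs[[j]], noise_sd_pa, ...)
    data.frame(x = spots[j, 1], y = spots[j, 2], z = spots[j, 3],
               path_um = path_distance(morphology, spots[j, ]),
               euclid_um = sqrt(sum((spots[j, ] - soma)^2)),
               responded = det$responded,
               mean_peak_pa = det$mean_peak_pa)
  })
  scracm_map(cell_id, do.call(rbind, rows), noise_sd_pa)
}

# ---- line scan --------------------------------------------------------------

#' Simulate a line-scan calcium transient
#'
#' Structure pixels carry `f_bg + f_cell * (1 + dff(t))`, background pixels
#' `f_bg`, with per-pixel Poisson noise plus Gaussian read noise. The
#' transient is a single exponential decay from `peak_dff` at `onset_s`;
#' ground truth carries its analytic integral over `[onset, onset +
#' area_window_s]`.
#'
#' @param cfg a `pb_sim_config`.
#' @param peak_dff peak dF/F0 of the transient (0 for a null scan).
#' @param tau_decay_s decay time constant (s).
#' @param onset_s transient onset, snapped to a line time.
#' @param n_lines number of scan lines.
#' @param shutter_lines optional gated-off line indices (values set to 0).
#' @param noise add photon/read noise?
#' @param area_window_s integration horizon used for the analytic area.
#' @return list with `scan` (a `pb_linescan`) and `truth` (`area`,
#'   `peak_dff`, `onset_s`, `tau_decay_s`).
#' @export
simulate_linescan <- function(cfg, peak_dff = 0.5, tau_decay_s = 0.3,
                              onset_s = 0.5, n_lines = 500,
                              shutter_lines = integer(0), noise = TRUE,
                              area_window_s = 2) {
  pb_assert(inherits(cfg, "pb_sim_config"), "not a pb_sim_config",
            "pb_input_error")
  set.seed(cfg$seed)
  ls <- cfg$linescan
  onset_s <- round(onset_s / ls$line_period_s) * ls$line_period_s
  t <- (seq_len(n_lines) - 1) * ls$line_period_s
  dff_true <- ifelse(t >= onset_s,
                     peak_dff * exp(-(t - onset_s) / tau_decay_s), 0)
  fr <- matrix(ls$f_bg, n_lines, ls$n_pixels)
  fr[, ls$structure_px] <- fr[, ls$structure_px] +
    ls$f_cell * (1 + dff_true)
  if (noise) {
    if (ls$poisson)
      fr[] <- rpois(length(fr), lambda = fr)
    fr[] <- fr + rnorm(length(fr), 0, ls$read_noise)
  }
  if (length(shutter_lines)) fr[shutter_lines, ] <- 0
  scan <- linescan(fr, ls$line_period_s, ls$structure_px, ls$background_px,
                   shutter_lines = shutter_lines)
  w <- area_window_s
  truth <- list(area = peak_dff * tau_decay_s * (1 - exp(-w / tau_decay_s)),
                peak_dff = peak_dff, onset_s = onset_s,
                tau_decay_s = tau_decay_s, area_window_s = w)
  list(scan = scan, truth = truth)
}
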