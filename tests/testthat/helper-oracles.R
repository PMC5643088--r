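# Independent oracles used across the suite. These deliberately use plain
# loops / full enumeration so they share no code with the implementation.

# Exhaustive per-sample scan for the dV/dt spike criterion: central
# difference, event at the first at-or-above-criterion sample preceded by a
# full refractory period of sub-criterion samples.
oracle_detect <- function(v, rate_hz, crit = 5, refractory_s = 0.002) {
  n <- length(v)
  n_ref <- ceiling(refractory_s * rate_hz)
  below_run <- 0L
  idx <- integer(0)
  armed <- FALSE
  for (i in seq_len(n)) {
    d <- if (i == 1L || i == n) -Inf else (v[i + 1] - v[i - 1]) * rate_hz / 2000
    if (d >= crit) {
      if (armed) idx <- c(idx, i)
      armed <- FALSE
      below_run <- 0L
    } else {
      below_run <- below_run + 1L
      if (below_run >= n_ref) armed <- TRUE
    }
  }
  idx
}

# Full-enumeration exact two-sided Mann-Whitney p-value (no ties).
oracle_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(na + nb, na)
  ranks <- seq_len(na + nb)
  us <- apply(combs, 2, function(ix) sum(ranks[ix]) - na * (na + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# Full-enumeration exact two-sided Wilcoxon signed-rank p-value
# (zeros already removed, no tied magnitudes).
oracle_wsr_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p <- 2 * min(mean(vs <= v_obs), mean(vs >= v_obs))
  min(p, 1)
}

# Template current-clamp trace: baseline with triangular spikes of known
# rise/fall slopes inserted at given threshold times.
make_template_trace <- function(spike_times_s, duration_s = 2, rate_hz = 2e4,
                                v_rest = -45, v_thresh = -45, v_peak = 10,
                                rise_v_per_s = 100, fall_v_per_s = 80) {
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  v <- rep(v_rest, n)
  for (ts in spike_times_s) {
    rise_dur <- (v_peak - v_thresh) / rise_v_per_s / 1000
    fall_dur <- (v_peak - v_rest) / fall_v_per_s / 1000
    sel_r <- t >= ts & t < ts + rise_dur
    v[sel_r] <- v_thresh + (t[sel_r] - ts) * rise_v_per_s * 1000
    sel_f <- t >= ts + rise_dur & t < ts + rise_dur + fall_dur
    v[sel_f] <- v_peak - (t[sel_f] - ts - rise_dur) * fall_v_per_s * 1000
  }
  recording(v, rate_hz, "cclamp_voltage", internal_solution = "potassium")
}

# Noiseless biexponential EPSC epoch with unit-peak normalization.
make_epsc_epoch <- function(amp_pa, tau_rise_ms = 1, tau_decay_ms = 5,
                            rate_hz = 1e4, pre_s = 0.05, post_s = 0.15,
                            noise_sd = 0, offset = 0) {
  t <- seq(-pre_s, post_s - 1 / rate_hz, by = 1 / rate_hz)
  tr <- tau_rise_ms / 1000; td <- tau_decay_ms / 1000
  tpk <- tr * td / (td - tr) * log(td / tr)
  norm <- exp(-tpk / td) - exp(-tpk / tr)
  w <- ifelse(t >= 0, (exp(-t / td) - exp(-t / tr)) / norm, 0)
  y <- offset + amp_pa * w
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  epoch(t, y)
}
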