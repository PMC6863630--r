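# Shared fixture builders (all synthetic, generated at test time).

fs_default <- 20000

# current-clamp trace with symmetric triangular spikes stamped at known
# peak times; a slow depolarizing ramp (dV/dt < 10 mV/ms) leads from the
# baseline to threshold so that the spike-onset criterion fires exactly
# at v_thr
make_spike_trace <- function(spike_times_s, duration = 2, v_base = -60,
                             v_thr = -40, height = 75, width_ms = 1,
                             fs = fs_default) {
  n <- round(duration * fs)
  v <- rep(v_base, n)
  n_w <- round(width_ms / 1000 * fs)
  n_r <- 50 # ramp samples, 2.5 ms: 20 mV / 2.5 ms = 8 mV/ms
  ramp_up <- seq(v_base, v_thr, length.out = n_r + 1)[-(n_r + 1)]
  tri_up <- seq(v_thr, v_thr + height, length.out = n_w + 1)
  tri_down <- seq(v_thr + height, v_thr, length.out = n_w + 1)[-1]
  ramp_down <- seq(v_thr, v_base, length.out = n_r + 1)[-1]
  stamp <- c(ramp_up, tri_up, tri_down, ramp_down)
  pk_off <- n_r + n_w # 0-based offset of the peak within the stamp
  for (tp in spike_times_s) {
    i_pk <- round(tp * fs) + 1
    i0 <- i_pk - pk_off
    idx <- i0:(i0 + length(stamp) - 1)
    keep <- idx >= 1 & idx <= n
    v[idx[keep]] <- stamp[keep]
  }
  opto_sweep(v, sampling_rate = fs, clamp_mode = "current_clamp")
}

# small light protocol used where full 10x10 trains would be wasteful
short_light_protocol <- function(n_pulses = 2, n_trains = 3) {
  light_stim_protocol(n_pulses = n_pulses, n_trains = n_trains,
                      first_onset = 0.1, tail = 0.12)
}

# voltage-clamp sweep with a known synthetic deflection added at t_on
make_vc_sweep <- function(defl, t_on = 0.1, duration = 0.3, baseline = 0,
                          fs = fs_default, noise_sd = 0, seed = NULL) {
  n <- round(duration * fs)
  x <- rep(baseline, n)
  if (length(defl) > 0) {
    i0 <- round(t_on * fs) + 1
    idx <- i0:min(n, i0 + length(defl) - 1)
    x[idx] <- x[idx] + defl[seq_along(idx)]
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
  }
  opto_sweep(x, sampling_rate = fs, clamp_mode = "voltage_clamp", holding = -60)
}
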