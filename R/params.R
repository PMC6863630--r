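#' Synaptic ground-truth parameters for the oEPSC generator
#'
#' The synthetic oEPSC kernel is a difference of exponentials,
#' peak-normalized so that the configured amplitude is the true
#' baseline-to-peak magnitude of the simulated current:
#' `g(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / g_max`.
#'
#' @param amplitude First-pulse amplitude in pA (scalar), or a vector of
#'   per-pulse amplitudes.
#' @param tau_rise,tau_decay Kernel time constants in ms
#'   (`tau_decay > tau_rise > 0`).
#' @param latency_mean Mean synaptic latency from light onset to current
#'   onset, ms. The recordings this emulates print no numeric latency;
#'   2-4 ms is a plausible monosynaptic value and 3 ms is the default.
#' @param latency_jitter_sd Trial-to-trial latency jitter SD, ms.
#' @param plasticity_factors Per-pulse multiplicative gains realizing
#'   short-term plasticity (default all 1). Recycled/truncated to the
#'   protocol length at simulation time.
#' @param failure_prob Per-pulse probability of transmission failure.
#' @return A `synapse_params` object.
#' @export
synapse_params <- function(amplitude = 50,
                           tau_rise = 0.8,
                           tau_decay = 8,
                           latency_mean = 3,
                           latency_jitter_sd = 0.3,
                           plasticity_factors = NULL,
                           failure_prob = 0) {
  if (!(tau_decay > tau_rise && tau_rise > 0)) {
    stop_validation("need tau_decay > tau_rise > 0")
  }
  if (any(amplitude < 0)) stop_validation("amplitudes must be >= 0")
  if (failure_prob < 0 || failure_prob > 1) {
    stop_validation("failure_prob must be in [0, 1]")
  }
  if (latency_jitter_sd < 0 || latency_mean < 0) {
    stop_validation("latency parameters must be non-negative")
  }
  structure(
    list(amplitude = as.numeric(amplitude), tau_rise = tau_rise,
         tau_decay = tau_decay, latency_mean = latency_mean,
         latency_jitter_sd = latency_jitter_sd,
         plasticity_factors = plasticity_factors,
         failure_prob = failure_prob),
    class = "synapse_params"
  )
}

#' Membrane parameters for the leaky integrate-and-fire generator
#'
#' The neuron model is a leaky integrate-and-fire cell extended with a
#' hyperpolarization-activated (sag) current, two spike-triggered
#' after-currents (fast and slow AHP), a tonic pacemaker drive, and a
#' stereotyped spike waveform stamped at threshold crossings. It is the
#' simplest model whose phenotype (input resistance, time constant, sag,
#' firing rates, spike shape) the extraction functions can recover.
#'
#' `R_in` is interpreted as the *measured* steady-state input
#' resistance. When a sag amplitude is requested, the internal leak
#' resistance is derived so that the steady-state slope of voltage
#' responses still equals `R_in` (the sag current shunts part of the
#' leak response, exactly as in the recordings the phenotype comes
#' from).
#'
#' @param R_in Steady-state input resistance, MOhm.
#' @param tau_m Membrane time constant, ms.
#' @param E_rest Resting potential, mV.
#' @param V_thr Spike threshold, mV (must exceed `V_reset`).
#' @param V_reset Post-spike reset potential, mV.
#' @param pacemaker_current Tonic depolarizing drive, pA (0 = silent).
#' @param sag_mv Target sag amplitude on a -100 pA step, mV (0 disables
#'   the sag current).
#' @param sag_tau_act Sag activation time constant, ms (default 300).
#' @param fahp_amp,fahp_tau Fast after-current increment (pA) and decay
#'   time constant (ms).
#' @param sahp_amp,sahp_tau Slow after-current peak (pA) and decay time
#'   constant (ms).
#' @param sahp_tau_rise Rise time constant of the slow after-current,
#'   ms (alpha-like kinetics delay its trough well beyond the fast
#'   AHP).
#' @param spike_height Spike height threshold-to-peak, mV.
#' @param spike_width Spike full width at half height, ms.
#' @return A `membrane_params` object (with derived internal fields
#'   `R_leak` and `sag_k`).
#' @export
membrane_params <- function(R_in = 232.35,
                            tau_m = 12.94,
                            E_rest = -46.63,
                            V_thr = -37.57,
                            V_reset = -55,
                            pacemaker_current = 0,
                            sag_mv = 0,
                            sag_tau_act = 300,
                            fahp_amp = 80, fahp_tau = 2,
                            sahp_amp = 25, sahp_tau = 20,
                            sahp_tau_rise = 3,
                            spike_height = 74.06,
                            spike_width = 0.95) {
  if (R_in <= 0) stop_validation("R_in must be > 0")
  if (tau_m <= 0) stop_validation("tau_m must be > 0")
  if (!(V_thr > V_reset)) stop_validation("need V_thr > V_reset")
  if (sag_mv < 0 || sag_tau_act <= 0) stop_validation("invalid sag parameters")
  if (spike_height <= 0 || spike_width <= 0) {
    stop_validation("spike stamp parameters must be positive")
  }
  if (sahp_amp > 0 && !(sahp_tau > sahp_tau_rise && sahp_tau_rise > 0)) {
    stop_validation("need sahp_tau > sahp_tau_rise > 0")
  }
  rho_eff <- R_in / 1000 # mV per pA, measured
  # leak resistance compensated so the steady-state slope matches R_in
  # at the -100 pA reference step: sag_mv = |I_ref| * (rho_leak - rho_eff)
  rho_leak <- rho_eff + sag_mv / 100
  sag_k <- if (sag_mv > 0) (rho_leak / rho_eff - 1) / rho_leak else 0
  structure(
    list(R_in = R_in, tau_m = tau_m, E_rest = E_rest, V_thr = V_thr,
         V_reset = V_reset, pacemaker_current = pacemaker_current,
         sag_mv = sag_mv, sag_tau_act = sag_tau_act,
         fahp_amp = fahp_amp, fahp_tau = fahp_tau,
         sahp_amp = sahp_amp, sahp_tau = sahp_tau,
         sahp_tau_rise = sahp_tau_rise,
         spike_height = spike_height, spike_width = spike_width,
         R_leak = rho_leak * 1000, sag_k = sag_k),
    class = "membrane_params"
  )
}

#' Recording-noise model
#'
#' @param gaussian_sd Stationary trace noise SD (pA under voltage clamp,
#'   mV under current clamp).
#' @param drift_slope Linear baseline drift in units per second.
#' @return A `noise_model` object.
#' @export
noise_model <- function(gaussian_sd = 0, drift_slope = 0) {
  if (gaussian_sd < 0) stop_validation("gaussian_sd must be >= 0")
  structure(list(gaussian_sd = gaussian_sd, drift_slope = drift_slope),
            class = "noise_model")
}

#' Pacemaker drive for a target spontaneous rate
#'
#' Closed-form tonic current that makes the passive-core LIF fire
#' periodically at `rate_hz`, from the interspike trajectory
#' `T = t_spike + tau_m * log((V_inf - V_reset) / (V_inf - V_thr))`.
#' After-currents and sag are ignored; use [calibrate_pacemaker()] for
#' a drive that hits the target rate of the full model.
#'
#' @param mp A [membrane_params()] object.
#' @param rate_hz Target firing rate, Hz.
#' @return Tonic current in pA.
#' @export
pacemaker_current_for_rate <- function(mp, rate_hz) {
  stopifnot(inherits(mp, "membrane_params"), rate_hz > 0)
  t_stamp <- 2 * mp$spike_width + 0.3 # stamp + reset ramp, ms
  t_isi <- 1000 / rate_hz - t_stamp
  if (t_isi <= 0) stop_arg("target rate is faster than the spike stamp allows")
  a <- exp(t_isi / mp$tau_m)
  v_inf <- (a * mp$V_thr - mp$V_reset) / (a - 1)
  (v_inf - mp$E_rest) / (mp$R_leak / 1000)
}

#' Numerically calibrate the pacemaker drive of the full model
#'
#' Root-finds the tonic current whose noiseless simulated firing rate
#' equals `rate_hz`, starting from the closed-form passive estimate
#' (which ignores after-currents and sag). The simulation is
#' deterministic, so the calibration is reproducible.
#'
#' @param mp A [membrane_params()] object.
#' @param rate_hz Target spontaneous rate, Hz.
#' @param duration Simulated duration per evaluation, s.
#' @return Tonic current in pA.
#' @export
calibrate_pacemaker <- function(mp, rate_hz, duration = 10) {
  stopifnot(inherits(mp, "membrane_params"), rate_hz > 0)
  i0 <- pacemaker_current_for_rate(mp, rate_hz)
  rate_at <- function(i_pace) {
    m <- mp
    m$pacemaker_current <- i_pace
    sw <- simulate_spontaneous(m, duration + 2, noise = noise_model(0))
    # discard the first 2 s (settling of sag and after-currents)
    spk <- attr(sw, "truth")$spike_peaks_s
    sum(spk > 2) / duration - rate_hz
  }
  lo <- i0
  hi <- i0
  while (rate_at(lo) > 0 && lo > 0.1 * i0) lo <- lo * 0.8
  while (rate_at(hi) < 0 && hi < 10 * abs(i0) + 100) hi <- hi * 1.25 + 1
  stats::uniroot(rate_at, c(lo, hi), tol = 0.05)$root
}

.preset_cache <- new.env(parent = emptyenv())

#' Cell-type presets for the synthetic generator
#'
#' Membrane presets whose phenotypes follow the population means
#' reported for pallidal neurons retrogradely labeled from the STN
#' (`GP_STN`) or striatum (`GP_CPu`), striatal projection neurons
#' (`MSN`) and subthalamic neurons (`STN`). Values not reported for a
#' type (e.g. MSN spike shape) are plausible fill-ins, flagged in the
#' methods vignette.
#'
#' @param type One of `"GP_STN"`, `"GP_CPu"`, `"MSN"`, `"STN"`.
#' @param passive If `TRUE`, disable pacemaker, sag and after-currents
#'   (used for closed-form checks such as the analytic rheobase).
#' @return A [membrane_params()] object.
#' @export
membrane_preset <- function(type = c("GP_STN", "GP_CPu", "MSN", "STN"),
                            passive = FALSE) {
  type <- match.arg(type)
  key <- paste0(type, if (passive) "_passive")
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  base <- switch(type,
    GP_STN = list(R_in = 232.35, tau_m = 12.94, E_rest = -46.63,
                  V_thr = -37.57, V_reset = -55, sag_mv = 7.23,
                  spike_height = 74.06, spike_width = 0.95,
                  rate_hz = 20.79,
                  fahp_amp = 90, fahp_tau = 2,
                  sahp_amp = 10, sahp_tau = 12, sahp_tau_rise = 3),
    GP_CPu = list(R_in = 329.97, tau_m = 21.92, E_rest = -46.36,
                  V_thr = -37.70, V_reset = -54, sag_mv = 8.71,
                  spike_height = 76.55, spike_width = 1.19,
                  rate_hz = 5.47,
                  fahp_amp = 70, fahp_tau = 2.5,
                  sahp_amp = 8, sahp_tau = 25, sahp_tau_rise = 8),
    MSN = list(R_in = 79.17, tau_m = 10, E_rest = -73.45,
               V_thr = -50, V_reset = -80, sag_mv = 0,
               spike_height = 85, spike_width = 1.1,
               rate_hz = 0,
               fahp_amp = 120, fahp_tau = 2,
               sahp_amp = 15, sahp_tau = 30, sahp_tau_rise = 8),
    STN = list(R_in = 253.14, tau_m = 15, E_rest = -45.43,
               V_thr = -38, V_reset = -54, sag_mv = 4,
               spike_height = 70, spike_width = 0.7,
               rate_hz = 10,
               fahp_amp = 90, fahp_tau = 1.5,
               sahp_amp = 10, sahp_tau = 10, sahp_tau_rise = 3)
  )
  mp <- membrane_params(
    R_in = base$R_in, tau_m = base$tau_m, E_rest = base$E_rest,
    V_thr = base$V_thr, V_reset = base$V_reset,
    sag_mv = if (passive) 0 else base$sag_mv,
    fahp_amp = if (passive) 0 else base$fahp_amp, fahp_tau = base$fahp_tau,
    sahp_amp = if (passive) 0 else base$sahp_amp, sahp_tau = base$sahp_tau,
    sahp_tau_rise = base$sahp_tau_rise,
    spike_height = base$spike_height, spike_width = base$spike_width
  )
  if (!passive && base$rate_hz > 0) {
    mp$pacemaker_current <- calibrate_pacemaker(mp, base$rate_hz)
  }
  attr(mp, "preset") <- type
  attr(mp, "target_rate_hz") <- if (passive) 0 else base$rate_hz
  .preset_cache[[key]] <- mp
  mp
}
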