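step_info <- function(sw) {
  st <- attr(sw, "step")
  if (is.null(st)) stop_protocol("sweep carries no step annotation")
  st
}

# mean voltage over the final `tail_ms` of the step
step_steady <- function(sw, tail_ms = 200) {
  st <- step_info(sw)
  fs <- attr(sw, "sampling_rate")
  i_off <- time_to_index(sw, st$onset + st$duration) - 1L
  i_from <- max(time_to_index(sw, st$onset), i_off - ms_to_samples(tail_ms, fs) + 1L)
  mean(sw[i_from:i_off])
}

step_prebaseline <- function(sw) {
  st <- step_info(sw)
  i_on <- time_to_index(sw, st$onset)
  mean(sw[seq_len(i_on - 1L)])
}

#' Input resistance from hyperpolarizing current steps
#'
#' Least-squares slope of the steady-state voltage deflection against
#' the injected current over a family of hyperpolarizing steps (by
#' default the -20 to -100 pA, 20 pA-increment family). The deflection
#' is the mean over the final 200 ms of the step minus the pre-step
#' baseline.
#'
#' @param steps Tibble with `step_pa` and `sweep` (list-column), as
#'   produced by [simulate_cc_steps()].
#' @param amplitudes Step amplitudes to use; default every multiple of
#'   -20 pA present. At least 2 distinct amplitudes are required.
#' @param steady_ms Steady-state window, ms.
#' @return One-row tibble: `r_in_mohm`, `flagged` (TRUE when the slope
#'   is implausibly close to zero).
#' @export
input_resistance <- function(steps, amplitudes = NULL, steady_ms = 200) {
  if (is.null(amplitudes)) {
    amplitudes <- steps$step_pa[steps$step_pa < 0 & steps$step_pa %% 20 == 0]
  }
  use <- steps[steps$step_pa %in% amplitudes, ]
  if (length(unique(use$step_pa)) < 2) {
    stop_arg("need at least 2 distinct step amplitudes")
  }
  dv <- vapply(use$sweep, function(s) step_steady(s, steady_ms) - step_prebaseline(s),
               numeric(1))
  slope <- coef(lm(dv ~ use$step_pa))[[2]] # mV per pA
  r_in <- slope * 1000 # MOhm
  tibble::tibble(r_in_mohm = r_in, flagged = !is.finite(r_in) || r_in < 1)
}

#' Membrane time constant from a -50 pA step
#'
#' Single-exponential fit `V(t) = V_inf + (V0 - V_inf) exp(-t/tau)` to
#' the onset of the voltage response, over the first `5 * tau_hat` of
#' the step with one iteration of the window on the fitted value. A
#' non-monotonic onset (strong sag rebound) restricts the fit to the
#' first 50 ms and flags the result.
#'
#' @param sweep Current-clamp [opto_sweep()] with a `step` attribute
#'   (amplitude conventionally -50 pA).
#' @return One-row tibble: `tau_ms`, `flagged`.
#' @export
time_constant <- function(sweep) {
  st <- step_info(sweep)
  fs <- attr(sweep, "sampling_rate")
  i_on <- time_to_index(sweep, st$onset)
  i_off <- time_to_index(sweep, st$onset + st$duration) - 1L
  v <- as.numeric(sweep)
  v_ss <- step_steady(sweep)
  v0 <- mean(v[seq_len(i_on - 1L)])
  if (abs(v_ss - v0) < 1e-9) {
    return(tibble::tibble(tau_ms = NA_real_, flagged = TRUE))
  }
  # sag rebound makes the onset non-monotonic: trough well before the
  # step end, recovering clearly toward baseline afterwards
  i_min <- i_on - 1L + which.min(if (st$amplitude < 0) v[i_on:i_off] else -v[i_on:i_off])
  rebound <- abs(v_ss - v[i_min])
  nonmono <- (i_min - i_on) / fs < 0.3 * st$duration && rebound > 0.1 * abs(v_ss - v0)
  flagged <- nonmono

  fit_window <- function(win_ms) {
    n_fit <- min(ms_to_samples(win_ms, fs), i_off - i_on + 1L)
    tt <- (seq_len(n_fit) - 1) / fs * 1000
    yy <- v[i_on + seq_len(n_fit) - 1L]
    resid <- (yy - v_ss) / (v0 - v_ss)
    pos <- resid > 0.02
    if (sum(pos) < 3) return(NA_real_)
    tau0 <- -1 / stats::lm.fit(cbind(1, tt[pos]), log(resid[pos]))$coefficients[2]
    if (!is.finite(tau0) || tau0 <= 0) tau0 <- win_ms / 5
    fit <- tryCatch(
      stats::nls(yy ~ vinf + (vz - vinf) * exp(-tt / tau),
                 start = list(vinf = v_ss, vz = v0, tau = tau0)),
      error = function(e) NULL
    )
    if (is.null(fit)) tau0 else coef(fit)[["tau"]]
  }

  if (nonmono) {
    tau <- fit_window(50)
  } else {
    tau <- fit_window(100)                 # initial window
    if (is.finite(tau)) tau <- fit_window(5 * tau) # one iteration at 5 tau-hat
  }
  if (!is.finite(tau) || tau <= 0) {
    return(tibble::tibble(tau_ms = NA_real_, flagged = TRUE))
  }
  tibble::tibble(tau_ms = tau, flagged = flagged)
}

#' Sag amplitude on a hyperpolarizing step
#'
#' Peak hyperpolarization within the first 300 ms of the step minus the
#' steady state over its final 200 ms, reported as a positive mV value.
#'
#' @param sweep Current-clamp [opto_sweep()] with a `step` attribute;
#'   the step must be hyperpolarizing.
#' @return One-row tibble: `sag_mv`, `step_pa`.
#' @export
sag_amplitude <- function(sweep) {
  st <- step_info(sweep)
  if (st$amplitude >= 0) {
    stop_arg("sag is measured on a hyperpolarizing step")
  }
  fs <- attr(sweep, "sampling_rate")
  i_on <- time_to_index(sweep, st$onset)
  i_300 <- min(i_on + ms_to_samples(300, fs) - 1L, length(sweep))
  v_peak <- min(sweep[i_on:i_300])
  v_ss <- step_steady(sweep)
  tibble::tibble(sag_mv = v_ss - v_peak, step_pa = st$amplitude)
}

#' Detect action potentials in a voltage trace
#'
#' A spike onset is the first sample where dV/dt (forward difference)
#' exceeds `dvdt_thresh` and the voltage subsequently exceeds
#' `peak_floor` within `lookahead_ms`; candidates within the refractory
#' merge window belong to one spike. The spike time is the local
#' voltage maximum after the onset.
#'
#' @param v Current-clamp or on-cell [opto_sweep()].
#' @param dvdt_thresh Threshold on dV/dt, mV/ms.
#' @param peak_floor Minimum voltage the spike must reach, mV.
#' @param refractory_ms Merge window, ms.
#' @param lookahead_ms How far after the dV/dt crossing the peak is
#'   sought, ms.
#' @return Tibble with one row per spike: `onset_idx`, `onset_time_s`,
#'   `peak_idx`, `peak_time_s`, `v_thr` (voltage at the dV/dt
#'   crossing), `v_peak`.
#' @export
detect_spikes <- function(v, dvdt_thresh = 10, peak_floor = -20,
                          refractory_ms = 2, lookahead_ms = 3) {
  fs <- attr(v, "sampling_rate")
  x <- as.numeric(v)
  n <- length(x)
  dvdt <- diff(x) * fs / 1000 # mV per ms
  cand <- which(dvdt >= dvdt_thresh)
  if (length(cand) == 0) {
    return(tibble::tibble(onset_idx = integer(), onset_time_s = numeric(),
                          peak_idx = integer(), peak_time_s = numeric(),
                          v_thr = numeric(), v_peak = numeric()))
  }
  gap <- ms_to_samples(refractory_ms, fs)
  look <- ms_to_samples(lookahead_ms, fs)
  starts <- cand[c(TRUE, diff(cand) > gap)]
  rows <- lapply(starts, function(i) {
    j_end <- min(i + look, n)
    win <- x[i:j_end]
    if (max(win) <= peak_floor) return(NULL)
    peak <- i + which.max(win) - 1L
    tibble::tibble(onset_idx = i, onset_time_s = attr(v, "t0") + (i - 1) / fs,
                   peak_idx = peak, peak_time_s = attr(v, "t0") + (peak - 1) / fs,
                   v_thr = x[i], v_peak = x[peak])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 1) {
    # two candidates may map to one peak when the rise is interrupted
    out <- out[!duplicated(out$peak_idx), ]
  }
  out
}

interp_time <- function(x, i0, i1, level, fs) {
  # crossing of `level` between samples i0 and i1 (linear)
  if (x[i1] == x[i0]) return((i0 - 1) / fs)
  ((i0 - 1) + (level - x[i0]) / (x[i1] - x[i0])) / fs
}

#' Waveform features of one action potential
#'
#' Height is threshold-to-peak; the width is the full width at half
#' height (half level between threshold and peak, crossings linearly
#' interpolated). The fast AHP is the most negative voltage within 5 ms
#' after the peak; the slow AHP is the most negative voltage between
#' the fAHP trough and 70 ms after the peak (truncated at the next
#' spike onset). Both AHP amplitudes are measured relative to the spike
#' threshold and their delays from the spike peak.
#'
#' @param v Voltage [opto_sweep()].
#' @param spike One row of [detect_spikes()] output.
#' @param next_onset_idx Optional onset index of the following spike.
#' @return One-row tibble with `v_thr`, `height_mv`, `width_ms`,
#'   `fahp_amp_mv`, `fahp_delay_ms`, `sahp_amp_mv`, `sahp_delay_ms`,
#'   `ahp_flagged`, `sahp_truncated`.
#' @export
spike_features <- function(v, spike, next_onset_idx = NULL) {
  fs <- attr(v, "sampling_rate")
  x <- as.numeric(v)
  n <- length(x)
  v_thr <- spike$v_thr
  peak <- spike$peak_idx
  height <- spike$v_peak - v_thr
  half <- v_thr + height / 2

  i_up <- spike$onset_idx - 1L + first_crossing(x[spike$onset_idx:peak], half)
  t_up <- interp_time(x, i_up - 1L, i_up, half, fs)
  after <- x[peak:min(n, peak + ms_to_samples(10, fs))]
  k_dn <- which(after <= half)
  if (length(k_dn) == 0) {
    width <- NA_real_
  } else {
    i_dn <- peak + k_dn[1] - 1L
    t_dn <- interp_time(x, i_dn - 1L, i_dn, half, fs)
    width <- (t_dn - t_up) * 1000
  }

  lim <- min(n, peak + ms_to_samples(70, fs),
             if (is.null(next_onset_idx)) n else next_onset_idx - 1L)
  f_end <- min(n, peak + ms_to_samples(5, fs))
  fahp_amp <- fahp_delay <- sahp_amp <- sahp_delay <- NA_real_
  flagged <- FALSE
  truncated <- !is.null(next_onset_idx) && (next_onset_idx - 1L) < peak + ms_to_samples(70, fs)
  if (f_end > peak + 1L) {
    seg <- x[(peak + 1L):f_end]
    i_f <- peak + which.min(seg)
    if (x[i_f] < v_thr) {
      fahp_amp <- v_thr - x[i_f]
      fahp_delay <- (i_f - peak) / fs * 1000
    }
  }
  if (!is.na(fahp_delay)) {
    i_from <- peak + ms_to_samples(fahp_delay, fs) + 1L
    if (i_from <= lim) {
      seg <- x[i_from:lim]
      i_s <- i_from + which.min(seg) - 1L
      if (x[i_s] < v_thr) {
        sahp_amp <- v_thr - x[i_s]
        sahp_delay <- (i_s - peak) / fs * 1000
      }
    }
  }
  if (is.na(fahp_amp) && is.na(sahp_amp)) flagged <- TRUE
  tibble::tibble(v_thr = v_thr, height_mv = height, width_ms = width,
                 fahp_amp_mv = fahp_amp, fahp_delay_ms = fahp_delay,
                 sahp_amp_mv = sahp_amp, sahp_delay_ms = sahp_delay,
                 ahp_flagged = flagged, sahp_truncated = truncated)
}

#' Frequency-current metrics from depolarizing steps
#'
#' Firing frequency is the spike count during the step (1 s steps give
#' integer Hz). `f_max` is the maximum over steps and `I_at_fmax` the
#' smallest current achieving it.
#'
#' @param steps Tibble with `step_pa` and `sweep`, depolarizing rows
#'   used.
#' @return One-row tibble: `f_100_hz`, `f_500_hz`, `f_max_hz`,
#'   `i_at_fmax_pa`.
#' @export
f_i_metrics <- function(steps) {
  dep <- steps[steps$step_pa > 0, ]
  if (nrow(dep) == 0) stop_arg("no depolarizing steps")
  freq <- vapply(seq_len(nrow(dep)), function(i) {
    sw <- dep$sweep[[i]]
    st <- step_info(sw)
    sp <- detect_spikes(sw)
    in_step <- sp$onset_time_s >= st$onset &
      sp$onset_time_s < st$onset + st$duration
    sum(in_step) / st$duration
  }, numeric(1))
  at <- function(amp) if (amp %in% dep$step_pa) freq[match(amp, dep$step_pa)] else NA_real_
  f_max <- max(freq)
  tibble::tibble(
    f_100_hz = at(100), f_500_hz = at(500), f_max_hz = f_max,
    i_at_fmax_pa = min(dep$step_pa[freq == f_max])
  )
}

#' Rheobase from a brief-pulse series
#'
#' Smallest pulse amplitude that evokes at least one detected spike,
#' scanning the (ascending) series and stopping at the first success.
#'
#' @param series Tibble with `amplitude_pa` and `sweep`, e.g. from
#'   [simulate_brief_pulse_series()].
#' @return One-row tibble: `rheobase_pa` (`NA` when no amplitude
#'   spiked), `found`.
#' @export
rheobase <- function(series) {
  ord <- order(series$amplitude_pa)
  for (i in ord) {
    if (nrow(detect_spikes(series$sweep[[i]])) > 0) {
      return(tibble::tibble(rheobase_pa = series$amplitude_pa[i], found = TRUE))
    }
  }
  tibble::tibble(rheobase_pa = NA_real_, found = FALSE)
}

#' Spontaneous firing rate
#'
#' Spike count divided by recording duration. Recordings shorter than
#' 30 s are flagged as unreliable.
#'
#' @param sweep On-cell or whole-cell voltage [opto_sweep()].
#' @param mode Recording mode label carried into the output.
#' @return One-row tibble: `rate_hz`, `mode`, `flagged`.
#' @export
spontaneous_rate <- function(sweep, mode = c("on_cell", "whole_cell")) {
  mode <- match.arg(mode)
  dur <- sweep_duration(sweep)
  n_spk <- nrow(detect_spikes(sweep))
  tibble::tibble(rate_hz = n_spk / dur, mode = mode, flagged = dur < 30)
}

#' Advisory flag for putative cholinergic pallidal neurons
#'
#' Large pallidal neurons with little spontaneous activity and wide
#' spikes are likely cholinergic and are excluded from projection-type
#' analyses. The heuristic flags a cell when its on-cell rate is below
#' 3 Hz (strict) and its spike width exceeds 1.5x the prototypic
#' (GP_STN) preset width.
#'
#' @param features Data frame with `rate_oncell_hz` and
#'   `spike_width_ms`.
#' @return Input with a logical `putative_cholinergic` column added.
#' @export
flag_putative_cholinergic <- function(features) {
  ref_width <- membrane_preset("GP_STN")$spike_width
  dplyr::mutate(
    tibble::as_tibble(features),
    putative_cholinergic = .data$rate_oncell_hz < 3 &
      .data$spike_width_ms > 1.5 * ref_width
  )
}

#' Full intrinsic-feature extraction for one simulated cell
#'
#' Convenience driver combining the per-protocol extractors: input
#' resistance and sag from the hyperpolarizing steps, time constant
#' from the -50 pA sweep, f-I metrics from the depolarizing steps,
#' spike waveform features (averaged over detected spikes of the
#' strongest subthreshold-to-moderate step or the spontaneous trace),
#' spontaneous rates, and rheobase when a brief-pulse series is given.
#'
#' @param steps Step-response tibble ([simulate_cc_steps()]).
#' @param spont_wholecell,spont_oncell Optional spontaneous sweeps.
#' @param brief_series Optional brief-pulse series.
#' @return One-row tibble of features.
#' @export
intrinsic_features <- function(steps, spont_wholecell = NULL,
                               spont_oncell = NULL, brief_series = NULL) {
  rin <- input_resistance(steps)
  tau_sweep <- steps$sweep[steps$step_pa == -50]
  tau <- if (length(tau_sweep) == 1) time_constant(tau_sweep[[1]]) else
    tibble::tibble(tau_ms = NA_real_, flagged = NA)
  sag_sweep <- steps$sweep[steps$step_pa == -100]
  sag <- if (length(sag_sweep) == 1) sag_amplitude(sag_sweep[[1]])$sag_mv else NA_real_
  fi <- f_i_metrics(steps)

  # spike waveform source: the spontaneous trace when the cell fires,
  # otherwise the weakest depolarizing step that evokes spikes
  spike_src <- spont_wholecell
  if (is.null(spike_src) || nrow(detect_spikes(spike_src)) == 0) {
    dep <- steps[steps$step_pa > 0, ]
    dep <- dep[order(dep$step_pa), ]
    spike_src <- NULL
    for (i in seq_len(nrow(dep))) {
      if (nrow(detect_spikes(dep$sweep[[i]])) > 0) {
        spike_src <- dep$sweep[[i]]
        break
      }
    }
  }
  feat <- tibble::tibble(v_thr = NA_real_, height_mv = NA_real_,
                         width_ms = NA_real_, fahp_amp_mv = NA_real_,
                         fahp_delay_ms = NA_real_, sahp_amp_mv = NA_real_,
                         sahp_delay_ms = NA_real_)
  v_mean <- if (!is.null(spont_wholecell)) {
    stats::median(as.numeric(spont_wholecell))
  } else {
    NA_real_
  }
  if (!is.null(spike_src)) {
    spikes <- detect_spikes(spike_src)
    if (nrow(spikes) > 0) {
      per <- purrr::map(seq_len(nrow(spikes)), function(i) {
        nxt <- if (i < nrow(spikes)) spikes$onset_idx[i + 1] else NULL
        spike_features(spike_src, spikes[i, ], next_onset_idx = nxt)
      })
      per <- dplyr::bind_rows(per)
      feat <- dplyr::summarise(per, dplyr::across(
        c("v_thr", "height_mv", "width_ms", "fahp_amp_mv", "fahp_delay_ms",
          "sahp_amp_mv", "sahp_delay_ms"),
        ~ mean(.x, na.rm = TRUE)))
    }
  }
  rate_wc <- if (!is.null(spont_wholecell)) {
    spontaneous_rate(spont_wholecell, "whole_cell")$rate_hz
  } else {
    NA_real_
  }
  rate_oc <- if (!is.null(spont_oncell)) {
    spontaneous_rate(spont_oncell, "on_cell")$rate_hz
  } else {
    NA_real_
  }
  rheo <- if (!is.null(brief_series)) rheobase(brief_series)$rheobase_pa else NA_real_

  out <- tibble::tibble(
    v_mean_mv = v_mean,
    r_in_mohm = rin$r_in_mohm,
    tau_ms = tau$tau_ms,
    sag_mv = sag,
    f_100_hz = fi$f_100_hz, f_500_hz = fi$f_500_hz,
    f_max_hz = fi$f_max_hz, i_at_fmax_pa = fi$i_at_fmax_pa,
    spike_thr_mv = feat$v_thr,
    spike_height_mv = feat$height_mv,
    spike_width_ms = feat$width_ms,
    fahp_amp_mv = feat$fahp_amp_mv, fahp_delay_ms = feat$fahp_delay_ms,
    sahp_amp_mv = feat$sahp_amp_mv, sahp_delay_ms = feat$sahp_delay_ms,
    rate_oncell_hz = rate_oc, rate_wholecell_hz = rate_wc,
    rheobase_pa = rheo
  )
  out
}
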