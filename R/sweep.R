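#' Construct a single recorded or simulated sweep
#'
#' A sweep is one uniformly sampled trace: membrane current in pA under
#' voltage clamp, membrane potential in mV under current clamp or in the
#' (loose-seal) on-cell configuration. The clamp mode fixes the unit
#' interpretation and is immutable for the life of the sweep.
#'
#' @param samples Numeric vector of signal values (pA in voltage clamp,
#'   mV otherwise). Must be non-empty and finite.
#' @param sampling_rate Sampling rate in Hz; default 20000 (20 kHz).
#' @param clamp_mode One of `"voltage_clamp"`, `"current_clamp"`,
#'   `"on_cell"`.
#' @param t0 Time of the first sample in seconds.
#' @param holding Holding potential (mV, voltage clamp) or holding
#'   current (pA, current clamp); `NA` when not applicable.
#' @return An object of class `opto_sweep`: the sample vector with the
#'   acquisition metadata stored as attributes.
#' @export
#' @examples
#' sw <- opto_sweep(rnorm(2000), clamp_mode = "voltage_clamp", holding = -60)
#' sweep_duration(sw)
opto_sweep <- function(samples,
                       sampling_rate = 20000,
                       clamp_mode = c("voltage_clamp", "current_clamp", "on_cell"),
                       t0 = 0,
                       holding = NA_real_) {
  clamp_mode <- match.arg(clamp_mode)
  if (!is.numeric(samples) || length(samples) == 0) {
    stop_validation("`samples` must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) {
    stop_validation("all sweep samples must be finite (found NA/NaN/Inf)")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    stop_validation("`sampling_rate` must be a single positive number")
  }
  structure(
    as.numeric(samples),
    sampling_rate = as.numeric(sampling_rate),
    clamp_mode = clamp_mode,
    t0 = as.numeric(t0),
    holding = as.numeric(holding),
    class = "opto_sweep"
  )
}

#' @export
print.opto_sweep <- function(x, ...) {
  unit <- if (attr(x, "clamp_mode") == "voltage_clamp") "pA" else "mV"
  cat(sprintf(
    "<opto_sweep> %s, %d samples @ %g Hz (%.3f s), range [%.3g, %.3g] %s\n",
    attr(x, "clamp_mode"), length(x), attr(x, "sampling_rate"),
    sweep_duration(x), min(x), max(x), unit
  ))
  invisible(x)
}

#' Sweep helpers
#'
#' `sweep_duration()` returns the duration in seconds, `sweep_times()`
#' the sample times in seconds (starting at `t0`), and
#' `sampling_rate()` the rate in Hz.
#'
#' @param x An `opto_sweep`.
#' @return A numeric scalar (duration, rate) or vector (times).
#' @export
sweep_duration <- function(x) length(x) / attr(x, "sampling_rate")

#' @rdname sweep_duration
#' @export
sweep_times <- function(x) {
  attr(x, "t0") + (seq_along(x) - 1) / attr(x, "sampling_rate")
}

#' @rdname sweep_duration
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

#' Tidy a sweep into a two-column tibble
#'
#' @param x An `opto_sweep`.
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `value`.
#' @export
tidy.opto_sweep <- function(x, ...) {
  tibble::tibble(time_s = sweep_times(x), value = as.numeric(x))
}

#' Photostimulation train protocol
#'
#' Timing of a train of brief light pulses used to activate ChR2-expressing
#' cortical terminals: by default 10 five-millisecond pulses at 10 Hz,
#' repeated over 10 trains separated by 1 s (each train is acquired as its
#' own sweep).
#'
#' @param n_pulses Number of pulses per train.
#' @param train_freq Pulse rate within a train, Hz (2-10 in the recordings
#'   this models).
#' @param pulse_duration Light pulse duration in ms.
#' @param first_onset Onset of the first pulse within the sweep, s.
#' @param n_trains Number of repeated trains (sweeps).
#' @param inter_train_interval Interval between trains, s.
#' @param tail Recording time after the last pulse, s.
#' @return A `light_stim_protocol` object with the computed
#'   `pulse_onsets` (s).
#' @export
light_stim_protocol <- function(n_pulses = 10,
                                train_freq = 10,
                                pulse_duration = 5,
                                first_onset = 0.1,
                                n_trains = 10,
                                inter_train_interval = 1,
                                tail = 0.25) {
  stopifnot(n_pulses >= 1, train_freq > 0, pulse_duration > 0,
            first_onset >= 0, n_trains >= 1, tail > 0)
  onsets <- first_onset + (seq_len(n_pulses) - 1) / train_freq
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop_validation("pulse onsets must be strictly increasing")
  }
  structure(
    list(
      pulse_onsets = onsets,
      pulse_duration = pulse_duration,
      n_pulses = as.integer(n_pulses),
      train_freq = train_freq,
      n_trains = as.integer(n_trains),
      inter_train_interval = inter_train_interval,
      sweep_duration = onsets[n_pulses] + tail
    ),
    class = c("light_stim_protocol", "opto_protocol")
  )
}

#' Current-step protocol for firing responses and passive properties
#'
#' One-second square current steps: depolarizing steps from 50 to
#' 1000 pA in 50 pA increments for firing responses, hyperpolarizing
#' steps from -20 to -100 pA in 20 pA increments for the input
#' resistance, plus a dedicated -50 pA step for the membrane time
#' constant.
#'
#' @param step_amplitudes Step amplitudes in pA (unique values).
#' @param step_duration Step duration, s.
#' @param pre_baseline,post_baseline Baseline durations before/after the
#'   step, s.
#' @return A `current_step_protocol` object.
#' @export
current_step_protocol <- function(step_amplitudes = c(seq(-100, -20, by = 20), -50,
                                                      seq(50, 1000, by = 50)),
                                  step_duration = 1,
                                  pre_baseline = 0.2,
                                  post_baseline = 0.2) {
  step_amplitudes <- sort(unique(as.numeric(step_amplitudes)))
  if (anyDuplicated(step_amplitudes)) {
    stop_validation("step amplitudes must be unique")
  }
  stopifnot(step_duration > 0, pre_baseline >= 0, post_baseline >= 0)
  structure(
    list(
      step_amplitudes = step_amplitudes,
      step_duration = step_duration,
      pre_baseline = pre_baseline,
      post_baseline = post_baseline
    ),
    class = c("current_step_protocol", "opto_protocol")
  )
}

#' Brief depolarizing pulse protocol for rheobase measurement
#'
#' Ascending series of brief (default 5 ms) depolarizing current pulses
#' used to find the minimum current that evokes an action potential.
#' The default grid resolution is 5 pA, matching the smallest rheobase
#' observed in pallidal neurons.
#'
#' @param pulse_duration Pulse duration in ms.
#' @param amplitudes Ascending positive grid of pulse amplitudes, pA.
#' @param pre_baseline,post_baseline Baseline before/after the pulse, s.
#' @return A `brief_pulse_protocol` object.
#' @export
brief_pulse_protocol <- function(pulse_duration = 5,
                                 amplitudes = seq(5, 1500, by = 5),
                                 pre_baseline = 0.05,
                                 post_baseline = 0.05) {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) == 0 || any(amplitudes <= 0) ||
      is.unsorted(amplitudes, strictly = TRUE)) {
    stop_validation("`amplitudes` must be a strictly increasing positive grid")
  }
  stopifnot(pulse_duration > 0)
  structure(
    list(
      pulse_duration = pulse_duration,
      amplitudes = amplitudes,
      pre_baseline = pre_baseline,
      post_baseline = post_baseline
    ),
    class = c("brief_pulse_protocol", "opto_protocol")
  )
}

#' @export
print.opto_protocol <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Plot a sweep
#'
#' @param object An `opto_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opto_sweep <- function(object, ...) {
  unit <- if (attr(object, "clamp_mode") == "voltage_clamp") "current (pA)" else "potential (mV)"
  ggplot2::ggplot(tidy.opto_sweep(object), ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = unit) +
    ggplot2::theme_minimal()
}
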