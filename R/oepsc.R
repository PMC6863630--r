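#' Detection and measurement settings for optically evoked EPSCs
#'
#' Defaults implement the analysis this package models: traces smoothed
#' with a 0.2 ms moving average (4 points at 20 kHz), baseline taken
#' over the 50 ms before each light pulse, and an inward deflection
#' accepted as an oEPSC when its baseline-to-peak magnitude exceeds 3
#' times the baseline standard deviation. Baseline statistics are
#' computed on the raw averaged trace; the peak is sought on the
#' smoothed average.
#'
#' @param smoothing_window Boxcar width, ms.
#' @param baseline_window Pre-pulse baseline length, ms.
#' @param threshold_multiplier Detection threshold in baseline SDs.
#' @param search_window Cap on the post-onset peak-search window, ms;
#'   the search always ends at the next pulse onset if that is sooner.
#' @param rise_fit_bounds Fractions of peak amplitude bounding the
#'   rising-phase linear fit (and the rise-time measurement).
#' @param decay_fit_fraction Decay fitted from the peak down to this
#'   fraction of the peak.
#' @param min_baseline Minimum acceptable baseline length, ms.
#' @param artifact_blank Optional light-artifact blanking period after
#'   each pulse onset, ms (0 = off; synthetic data has no artifact).
#' @return A `detection_config` object.
#' @export
detection_config <- function(smoothing_window = 0.2,
                             baseline_window = 50,
                             threshold_multiplier = 3,
                             search_window = 90,
                             rise_fit_bounds = c(0.2, 0.8),
                             decay_fit_fraction = 0.1,
                             min_baseline = 10,
                             artifact_blank = 0) {
  stopifnot(smoothing_window > 0, baseline_window > 0,
            threshold_multiplier > 0, search_window > 0,
            length(rise_fit_bounds) == 2,
            0 < rise_fit_bounds[1], rise_fit_bounds[1] < rise_fit_bounds[2],
            rise_fit_bounds[2] < 1,
            decay_fit_fraction > 0, decay_fit_fraction < 1,
            artifact_blank >= 0)
  structure(
    list(smoothing_window = smoothing_window,
         baseline_window = baseline_window,
         threshold_multiplier = threshold_multiplier,
         search_window = search_window,
         rise_fit_bounds = rise_fit_bounds,
         decay_fit_fraction = decay_fit_fraction,
         min_baseline = min_baseline,
         artifact_blank = artifact_blank),
    class = "detection_config"
  )
}

#' Boxcar-smooth a sweep
#'
#' Trailing-aligned moving average (window samples `t-w+1 ... t`); the
#' leading edge is padded by holding the first sample, so the output has
#' the input's length and interior mass is conserved.
#'
#' @param s An [opto_sweep()] or numeric vector.
#' @param cfg [detection_config()] supplying the window length.
#' @param sampling_rate Required when `s` is a bare numeric vector.
#' @return Smoothed object of the same type as `s`.
#' @export
smooth_trace <- function(s, cfg = detection_config(), sampling_rate = NULL) {
  fs <- if (inherits(s, "opto_sweep")) attr(s, "sampling_rate") else sampling_rate
  if (is.null(fs)) stop_arg("`sampling_rate` is required for bare vectors")
  w <- ms_to_samples(cfg$smoothing_window, fs)
  if (w < 2) stop_arg("smoothing window must span at least 2 samples")
  x <- as.numeric(s)
  if (w > length(x)) stop_arg("smoothing window is longer than the trace")
  xp <- c(rep(x[1], w - 1), x)
  sm <- as.numeric(stats::filter(xp, rep(1 / w, w), sides = 1))[w - 1 + seq_along(x)]
  if (inherits(s, "opto_sweep")) {
    out <- s
    out[] <- sm
    out
  } else {
    sm
  }
}

#' Average repeated trains aligned on the stimulus
#'
#' All sweeps must share length and sampling rate (they are acquired
#' with the same protocol, so alignment on each photostimulation onset
#' reduces to a pointwise mean). Returns the averaged trace together
#' with the per-pulse analysis windows: each window spans from
#' `baseline_window` before the pulse onset to the next pulse onset or
#' the `search_window` cap, whichever comes first.
#'
#' @param sweeps List of voltage-clamp [opto_sweep()] objects.
#' @param prot [light_stim_protocol()] shared by all sweeps.
#' @param cfg [detection_config()].
#' @return An `oepsc_average` list: `avg` (raw averaged sweep),
#'   `smoothed` (smoothed averaged sweep), `windows` (tibble of pulse,
#'   `onset_s`, `search_end_s`), `n_sweeps`.
#' @export
average_aligned <- function(sweeps, prot, cfg = detection_config()) {
  if (length(sweeps) < 1) stop_validation("need at least one sweep")
  lens <- vapply(sweeps, length, integer(1))
  rates <- vapply(sweeps, function(s) attr(s, "sampling_rate"), numeric(1))
  if (length(unique(lens)) != 1 || length(unique(rates)) != 1) {
    stop_validation("sweeps disagree in length or sampling rate (mismatched protocols)")
  }
  avg_samples <- Reduce(`+`, lapply(sweeps, as.numeric)) / length(sweeps)
  tmpl <- sweeps[[1]]
  avg <- opto_sweep(avg_samples, sampling_rate = rates[1],
                    clamp_mode = attr(tmpl, "clamp_mode"),
                    t0 = attr(tmpl, "t0"), holding = attr(tmpl, "holding"))
  onsets <- prot$pulse_onsets
  next_onset <- c(onsets[-1], Inf)
  search_end <- pmin(onsets + cfg$search_window / 1000, next_onset,
                     attr(avg, "t0") + sweep_duration(avg))
  structure(
    list(avg = avg,
         smoothed = smooth_trace(avg, cfg),
         windows = tibble::tibble(pulse = seq_along(onsets),
                                  onset_s = onsets,
                                  search_end_s = search_end),
         n_sweeps = length(sweeps)),
    class = "oepsc_average"
  )
}

# sample index (1-based) of a time in seconds within a sweep
time_to_index <- function(sw, t) {
  s_to_samples(t - attr(sw, "t0"), attr(sw, "sampling_rate")) + 1L
}

#' Baseline statistics before a pulse
#'
#' Mean and sample SD of the raw averaged trace over the
#' `baseline_window` preceding the pulse onset. If fewer pre-onset
#' samples are available the window is shortened with a warning, down to
#' `min_baseline`; below that it is an error.
#'
#' @param avg Averaged [opto_sweep()] (raw, unsmoothed) or an
#'   `oepsc_average`.
#' @param pulse_onset Pulse onset time, s.
#' @param cfg [detection_config()].
#' @return One-row tibble: `baseline_mean`, `baseline_sd`, `n_samples`.
#' @export
baseline_stats <- function(avg, pulse_onset, cfg = detection_config()) {
  if (inherits(avg, "oepsc_average")) avg <- avg$avg
  fs <- attr(avg, "sampling_rate")
  i_on <- time_to_index(avg, pulse_onset)
  want <- ms_to_samples(cfg$baseline_window, fs)
  have <- i_on - 1L
  if (have < ms_to_samples(cfg$min_baseline, fs)) {
    stop_arg("fewer than ", cfg$min_baseline, " ms of pre-pulse baseline available")
  }
  if (have < want) {
    warn(sprintf("baseline window shortened to %.1f ms", have / fs * 1000))
    want <- have
  }
  idx <- (i_on - want):(i_on - 1L)
  tibble::tibble(baseline_mean = mean(avg[idx]),
                 baseline_sd = stats::sd(avg[idx]),
                 n_samples = length(idx))
}

#' Detect an oEPSC and measure its amplitude
#'
#' The peak is the inward (negative) extremum of the smoothed averaged
#' trace, relative to the baseline mean, within the post-onset search
#' window. The deflection is accepted as an oEPSC when its magnitude
#' strictly exceeds `threshold_multiplier` baseline SDs; the amplitude
#' is the baseline-to-peak magnitude. Detection is scale-equivariant:
#' rescaling the whole trace rescales peak and threshold together.
#'
#' @param avg An `oepsc_average` or raw averaged [opto_sweep()].
#' @param pulse_onset Pulse onset, s.
#' @param cfg [detection_config()].
#' @param search_end End of the peak search window, s (defaults to
#'   `search_window` after the onset).
#' @param baseline Optional precomputed [baseline_stats()] row.
#' @return One-row tibble: `pulse_onset`, `detected`, `amplitude` (pA),
#'   `peak_time_s`, `baseline_mean`, `baseline_sd`.
#' @export
detect_and_measure <- function(avg, pulse_onset, cfg = detection_config(),
                               search_end = NULL, baseline = NULL) {
  if (inherits(avg, "oepsc_average")) {
    smoothed <- avg$smoothed
    raw <- avg$avg
  } else {
    raw <- avg
    smoothed <- smooth_trace(avg, cfg)
  }
  if (is.null(baseline)) baseline <- baseline_stats(raw, pulse_onset, cfg)
  fs <- attr(raw, "sampling_rate")
  if (is.null(search_end)) search_end <- pulse_onset + cfg$search_window / 1000
  search_start <- pulse_onset + cfg$artifact_blank / 1000
  i0 <- time_to_index(smoothed, search_start)
  i1 <- min(time_to_index(smoothed, search_end), length(smoothed))
  if (i0 >= i1) stop_arg("empty peak-search window")
  defl <- smoothed[i0:i1] - baseline$baseline_mean
  i_peak <- which.min(defl) # inward = negative
  peak <- defl[i_peak]
  amplitude <- abs(min(peak, 0))
  detected <- amplitude > cfg$threshold_multiplier * baseline$baseline_sd
  tibble::tibble(
    pulse_onset = pulse_onset,
    detected = detected,
    amplitude = if (detected || amplitude > 0) amplitude else 0,
    peak_time_s = (i0 + i_peak - 2L) / fs + attr(smoothed, "t0"),
    baseline_mean = baseline$baseline_mean,
    baseline_sd = baseline$baseline_sd
  )
}

# first index in idx (scanned forward) where deflection >= level
first_crossing <- function(defl, level) {
  hit <- which(defl >= level)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# interpolated crossing time (in samples, 1-based fractional) of `level`
# on the rising phase ending at i_peak
interp_crossing <- function(defl, level, i_peak) {
  i <- first_crossing(defl[seq_len(i_peak)], level)
  if (is.na(i)) return(NA_real_)
  if (i == 1 || defl[i] == defl[i - 1]) return(as.numeric(i))
  (i - 1) + (level - defl[i - 1]) / (defl[i] - defl[i - 1])
}

#' Onset extrapolation and synaptic latency
#'
#' Fits a least-squares line to the rising phase of the detected oEPSC
#' between its 20% and 80% amplitude crossings, extrapolates it to the
#' baseline, and defines the intersection as the oEPSC onset; the
#' latency is the onset minus the light-pulse onset. With fewer than 3
#' samples in the rise segment the first threshold-crossing time is
#' used instead and the result is flagged.
#'
#' @param avg `oepsc_average` or averaged [opto_sweep()].
#' @param pulse_onset Pulse onset, s.
#' @param m One-row tibble from [detect_and_measure()] with
#'   `detected = TRUE`.
#' @param cfg [detection_config()].
#' @return One-row tibble: `onset_time_s`, `latency_ms`, `flagged`.
#' @export
onset_and_latency <- function(avg, pulse_onset, m, cfg = detection_config()) {
  if (!isTRUE(m$detected)) {
    stop_arg("onset extrapolation requires a detected oEPSC")
  }
  smoothed <- if (inherits(avg, "oepsc_average")) avg$smoothed else smooth_trace(avg, cfg)
  fs <- attr(smoothed, "sampling_rate")
  t0 <- attr(smoothed, "t0")
  i_on <- time_to_index(smoothed, pulse_onset)
  i_peak <- time_to_index(smoothed, m$peak_time_s)
  defl <- m$baseline_mean - smoothed[i_on:i_peak] # positive inward deflection
  k <- length(defl)
  lo <- first_crossing(defl, cfg$rise_fit_bounds[1] * m$amplitude)
  hi <- first_crossing(defl, cfg$rise_fit_bounds[2] * m$amplitude)
  flagged <- FALSE
  if (is.na(lo) || is.na(hi) || hi - lo + 1 < 3) {
    # fallback: first crossing of the detection threshold
    thr <- first_crossing(defl, cfg$threshold_multiplier * m$baseline_sd)
    onset_idx <- if (is.na(thr)) 1L else thr
    onset_time <- pulse_onset + (onset_idx - 1L) / fs
    flagged <- TRUE
  } else {
    seg <- lo:hi
    tt <- (seg - 1) / fs
    fit <- stats::lm.fit(cbind(1, tt), defl[seg])
    b <- fit$coefficients
    if (!is.finite(b[2]) || b[2] <= 0) {
      onset_time <- pulse_onset + (lo - 1) / fs
      flagged <- TRUE
    } else {
      onset_time <- pulse_onset + (-b[1] / b[2])
    }
  }
  tibble::tibble(onset_time_s = onset_time,
                 latency_ms = (onset_time - pulse_onset) * 1000,
                 flagged = flagged)
}

#' Rise time and decay constant of a detected oEPSC
#'
#' The 20-80% rise time is measured between the linearly interpolated
#' amplitude crossings on the rising phase. The decay constant comes
#' from a least-squares single-exponential fit from the peak down to
#' `decay_fit_fraction` of the peak (log-linear initialisation refined
#' by nonlinear least squares); if the trace or window ends before the
#' decay reaches that fraction the available span is fitted and the
#' result is flagged.
#'
#' @inheritParams onset_and_latency
#' @param search_end End of this pulse's analysis window, s.
#' @return One-row tibble: `rise_time_ms`, `decay_tau_ms`,
#'   `decay_flagged`.
#' @export
rise_decay_kinetics <- function(avg, pulse_onset, m, cfg = detection_config(),
                                search_end = NULL) {
  if (!isTRUE(m$detected)) {
    stop_arg("kinetics require a detected oEPSC")
  }
  smoothed <- if (inherits(avg, "oepsc_average")) avg$smoothed else smooth_trace(avg, cfg)
  fs <- attr(smoothed, "sampling_rate")
  if (is.null(search_end)) search_end <- m$peak_time_s + cfg$search_window / 1000
  i_on <- time_to_index(smoothed, pulse_onset)
  i_peak <- time_to_index(smoothed, m$peak_time_s)
  i_end <- min(time_to_index(smoothed, search_end), length(smoothed))
  rise_defl <- m$baseline_mean - smoothed[i_on:i_peak]
  x20 <- interp_crossing(rise_defl, cfg$rise_fit_bounds[1] * m$amplitude,
                         length(rise_defl))
  x80 <- interp_crossing(rise_defl, cfg$rise_fit_bounds[2] * m$amplitude,
                         length(rise_defl))
  rise_ms <- if (is.na(x20) || is.na(x80)) NA_real_ else (x80 - x20) / fs * 1000

  decay <- m$baseline_mean - smoothed[i_peak:i_end] # positive, decaying
  cut <- which(decay <= cfg$decay_fit_fraction * m$amplitude)
  decay_flagged <- length(cut) == 0
  n_fit <- if (decay_flagged) length(decay) else cut[1]
  tau <- NA_real_
  if (n_fit >= 3) {
    tt <- (seq_len(n_fit) - 1) / fs * 1000 # ms
    yy <- decay[seq_len(n_fit)]
    pos <- yy > 0
    if (sum(pos) >= 3) {
      init <- stats::lm.fit(cbind(1, tt[pos]), log(yy[pos]))$coefficients
      tau0 <- -1 / init[2]
      if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(tt)) / 3
      fit <- tryCatch(
        suppressWarnings(
          stats::nls(yy ~ a * exp(-tt / tau_d),
                     start = list(a = max(yy), tau_d = tau0),
                     control = stats::nls.control(warnOnly = TRUE))
        ),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        tau <- coef(fit)[["tau_d"]]
      } else {
        tau <- tau0
        decay_flagged <- TRUE
      }
    }
  }
  tibble::tibble(rise_time_ms = rise_ms, decay_tau_ms = tau,
                 decay_flagged = decay_flagged)
}

#' Measure every pulse of an oEPSC train
#'
#' Full per-recording pipeline: average the repeated trains, take
#' baseline statistics immediately before each pulse, detect and
#' measure each pulse's oEPSC on the smoothed average, and derive onset
#' latency and kinetics for detected pulses. The paired-pulse ratio
#' (second/first amplitude) is attached whenever the first pulse is
#' detected.
#'
#' @param sweeps List of repeated-train sweeps (or a single sweep).
#' @param prot [light_stim_protocol()].
#' @param cfg [detection_config()].
#' @return Tibble with one row per pulse (`pulse`, `onset_s`,
#'   `detected`, `amplitude`, `latency_ms`, `rise_time_ms`,
#'   `decay_tau_ms`, baseline fields, flags) and the scalar `ppr` as a
#'   column (repeated; `NA` when undefined).
#' @export
measure_oepsc_train <- function(sweeps, prot, cfg = detection_config()) {
  if (inherits(sweeps, "opto_sweep")) sweeps <- list(sweeps)
  ave <- average_aligned(sweeps, prot, cfg)
  rows <- purrr::pmap(ave$windows, function(pulse, onset_s, search_end_s) {
    bl <- baseline_stats(ave$avg, onset_s, cfg)
    m <- detect_and_measure(ave, onset_s, cfg, search_end = search_end_s,
                            baseline = bl)
    if (m$detected) {
      ol <- onset_and_latency(ave, onset_s, m, cfg)
      kin <- rise_decay_kinetics(ave, onset_s, m, cfg, search_end = search_end_s)
    } else {
      ol <- tibble::tibble(onset_time_s = NA_real_, latency_ms = NA_real_,
                           flagged = FALSE)
      kin <- tibble::tibble(rise_time_ms = NA_real_, decay_tau_ms = NA_real_,
                            decay_flagged = FALSE)
    }
    dplyr::bind_cols(tibble::tibble(pulse = pulse, onset_s = onset_s), m[, -1],
                     ol, kin)
  })
  out <- dplyr::bind_rows(rows)
  ppr <- NA_real_
  if (nrow(out) >= 2 && isTRUE(out$detected[1]) && out$amplitude[1] > 0) {
    ppr <- out$amplitude[2] / out$amplitude[1]
  }
  out$ppr <- ppr
  out
}

#' Per-pulse amplitudes and paired-pulse ratio
#'
#' @inheritParams measure_oepsc_train
#' @return List with `per_pulse_amplitudes` (pA, one per pulse) and
#'   `ppr` (second/first; `NA` if the first pulse was not detected).
#' @export
train_amplitudes_and_ppr <- function(sweeps, prot, cfg = detection_config()) {
  meas <- measure_oepsc_train(sweeps, prot, cfg)
  if (!isTRUE(meas$detected[1])) {
    warn("first pulse not detected; paired-pulse ratio undefined")
  }
  list(per_pulse_amplitudes = meas$amplitude, ppr = meas$ppr[1])
}

#' Normalize amplitudes to a reference group
#'
#' Divides each value by the mean of the reference (e.g. oEPSC
#' amplitudes of pallidal neurons normalized to the mean of subthalamic
#' neurons from the same animal, or drug responses to control).
#'
#' @param values Numeric vector, pA.
#' @param reference Numeric reference vector or scalar; its mean must be
#'   strictly positive.
#' @return Dimensionless numeric vector.
#' @export
#' @examples
#' normalize_amplitude(60, 100) # 0.6
normalize_amplitude <- function(values, reference) {
  ref <- mean(reference)
  if (!is.finite(ref) || ref <= 0) {
    stop_arg("reference mean must be > 0")
  }
  values / ref
}

#' Run the oEPSC pipeline over a dataset
#'
#' Applies [measure_oepsc_train()] to every cell that has voltage-clamp
#' sweeps referencing a light-stimulation protocol.
#'
#' @param ds An [opto_dataset()].
#' @param cfg [detection_config()].
#' @return Tibble with one row per (cell, pulse), carrying the cell's
#'   `projection_class` and `cortical_source` beside every measurement
#'   field.
#' @export
detect_oepscs <- function(ds, cfg = detection_config()) {
  validate_dataset(ds)
  is_light <- vapply(ds$protocols, inherits, logical(1), "light_stim_protocol")
  light_ids <- names(ds$protocols)[is_light]
  sw <- dplyr::filter(ds$sweeps, .data$protocol_id %in% light_ids)
  if (nrow(sw) == 0) {
    return(tibble::tibble(cell_id = character(), pulse = integer(),
                          detected = logical(), amplitude = numeric()))
  }
  grouped <- dplyr::group_by(sw, .data$cell_id, .data$protocol_id)
  keys <- dplyr::group_keys(grouped)
  res <- purrr::map2(dplyr::group_split(grouped), seq_len(nrow(keys)), function(g, i) {
    meas <- measure_oepsc_train(g$sweep, ds$protocols[[keys$protocol_id[i]]], cfg)
    meas$cell_id <- keys$cell_id[i]
    meas
  })
  out <- dplyr::bind_rows(res)
  cell_cols <- intersect(c("cell_id", "projection_class", "cortical_source"),
                         names(ds$cells))
  dplyr::relocate(
    dplyr::left_join(out, ds$cells[, cell_cols], by = "cell_id"),
    dplyr::all_of(setdiff(cell_cols, "cell_id")), .after = "cell_id"
  )
}

#' Summarise oEPSC measurements per cell
#'
#' A cell counts as responsive (innervated) when its first-pulse oEPSC
#' is detected; the summary keeps the first-pulse amplitude, latency and
#' kinetics and the train's paired-pulse ratio.
#'
#' @param meas Per-pulse tibble from [detect_oepscs()].
#' @return One row per cell.
#' @export
summarise_oepsc_cells <- function(meas) {
  dplyr::summarise(
    dplyr::group_by(meas, dplyr::across(dplyr::any_of(
      c("cell_id", "projection_class", "cortical_source")))),
    responsive = .data$detected[.data$pulse == 1],
    amplitude = .data$amplitude[.data$pulse == 1],
    latency_ms = .data$latency_ms[.data$pulse == 1],
    rise_time_ms = .data$rise_time_ms[.data$pulse == 1],
    decay_tau_ms = .data$decay_tau_ms[.data$pulse == 1],
    ppr = .data$ppr[1],
    .groups = "drop"
  )
}
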