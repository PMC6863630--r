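#' @noRd
kernel_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# peak-normalized difference-of-exponentials kernel, t in ms (t >= 0)
epsc_kernel <- function(t, tau_rise, tau_decay) {
  tp <- kernel_peak_time(tau_rise, tau_decay)
  gmax <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  (exp(-t / tau_decay) - exp(-t / tau_rise)) / gmax
}

#' Simulate one voltage-clamp train of optically evoked EPSCs
#'
#' Produces a single sweep containing one photostimulation train:
#' Gaussian baseline noise plus, for every pulse `k`, an inward current
#' `-A_k * g(t - onset_k - latency_k)` where `g` is the peak-normalized
#' difference-of-exponentials kernel of [synapse_params()], `A_k` is the
#' configured amplitude times the pulse's plasticity factor (zero on
#' transmission failures), and the latency is jittered per pulse.
#'
#' @param sp [synapse_params()] ground truth.
#' @param prot [light_stim_protocol()] stimulus timing.
#' @param noise [noise_model()]; SD in pA.
#' @param seed Integer seed (`NULL` = use current RNG stream).
#' @param sampling_rate Hz.
#' @param baseline_pa Constant holding-current baseline, pA.
#' @return A voltage-clamp [opto_sweep()] with a `truth` attribute
#'   (per-pulse amplitudes and latencies actually realized).
#' @export
simulate_vc_train <- function(sp, prot = light_stim_protocol(),
                              noise = noise_model(2), seed = NULL,
                              sampling_rate = 20000, baseline_pa = 0) {
  stopifnot(inherits(sp, "synapse_params"), inherits(prot, "light_stim_protocol"))
  if (prot$n_pulses > 1 && (1000 / prot$train_freq) < sp$tau_rise) {
    warn("inter-pulse interval is shorter than tau_rise; kernels superpose heavily")
  }
  with_seed(seed, {
    fs <- sampling_rate
    n <- s_to_samples(prot$sweep_duration, fs)
    dt_ms <- 1000 / fs
    amps <- rep_len(sp$amplitude, prot$n_pulses)
    plast <- rep_len(sp$plasticity_factors %||% 1, prot$n_pulses)
    fails <- stats::rbinom(prot$n_pulses, 1L, sp$failure_prob) == 1L
    lat <- sp$latency_mean + sp$latency_jitter_sd * stats::rnorm(prot$n_pulses)
    lat <- pmax(lat, 0)
    a_true <- amps * plast * ifelse(fails, 0, 1)
    sig <- rep(baseline_pa, n)
    for (k in seq_len(prot$n_pulses)) {
      if (a_true[k] == 0) next
      i0 <- s_to_samples(prot$pulse_onsets[k] + lat[k] / 1000, fs) + 1L
      if (i0 > n) next
      t <- (seq.int(i0, n) - i0) * dt_ms
      sig[i0:n] <- sig[i0:n] - a_true[k] * epsc_kernel(t, sp$tau_rise, sp$tau_decay)
    }
    if (noise$gaussian_sd > 0) sig <- sig + stats::rnorm(n, 0, noise$gaussian_sd)
    if (noise$drift_slope != 0) {
      sig <- sig + noise$drift_slope * (seq_len(n) - 1) / fs
    }
    sw <- opto_sweep(sig, sampling_rate = fs, clamp_mode = "voltage_clamp",
                     holding = -60)
    attr(sw, "truth") <- list(amplitudes = a_true, latencies_ms = lat,
                              failures = fails)
    sw
  })
}

#' Simulate the repeated trains of one recording
#'
#' @inheritParams simulate_vc_train
#' @return List of `prot$n_trains` sweeps with independent noise,
#'   jitter and failures.
#' @export
simulate_vc_trains <- function(sp, prot = light_stim_protocol(),
                               noise = noise_model(2), seed = NULL,
                               sampling_rate = 20000, baseline_pa = 0) {
  lapply(seq_len(prot$n_trains), function(k) {
    simulate_vc_train(sp, prot, noise, seed = child_seed(seed, k),
                      sampling_rate = sampling_rate, baseline_pa = baseline_pa)
  })
}

# spike waveform written into the trace at a threshold crossing:
# symmetric triangle (FWHM = spike_width) followed by a short ramp to
# the reset potential. Values are mV relative to threshold.
build_spike_stamp <- function(mp, fs) {
  n_w <- max(2L, ms_to_samples(mp$spike_width, fs))
  n_r <- max(1L, ms_to_samples(0.3, fs))
  rise <- seq(0, mp$spike_height, length.out = n_w + 1)
  fall <- seq(mp$spike_height, 0, length.out = n_w + 1)[-1]
  ramp <- seq(0, mp$V_reset - mp$V_thr, length.out = n_r + 1)[-1]
  list(values = c(rise, fall, ramp), peak_offset = n_w)
}

# core integration wrapper around the compiled kernel
sim_lif <- function(mp, i_inj, noise = noise_model(0), seed = NULL,
                    sampling_rate = 20000, v0 = NULL) {
  fs <- sampling_rate
  dt_ms <- 1000 / fs
  if (dt_ms > mp$tau_m / 10) {
    warn("sampling interval exceeds tau_m/10; integration accuracy degrades")
  }
  n <- length(i_inj)
  stamp <- build_spike_stamp(mp, fs)
  rho <- mp$R_leak / 1000
  if (is.null(v0)) {
    v0 <- mp$E_rest + rho * (mp$pacemaker_current + i_inj[1])
    if (v0 >= mp$V_thr) v0 <- mp$V_reset
  }
  nz <- if (noise$gaussian_sd > 0) {
    with_seed(seed, stats::rnorm(n, 0, noise$gaussian_sd *
                                   sqrt(1 - exp(-2 * dt_ms / mp$tau_m))))
  } else {
    numeric(0)
  }
  res <- lif_integrate(i_inj, nz, dt_ms, mp$E_rest, mp$tau_m, rho,
                       mp$V_thr, mp$V_reset, mp$pacemaker_current,
                       mp$sag_k, if (mp$sag_mv > 0) mp$sag_tau_act else 0,
                       mp$fahp_amp, mp$fahp_tau, mp$sahp_amp, mp$sahp_tau,
                       mp$sahp_tau_rise,
                       stamp$values, stamp$peak_offset, v0)
  if (noise$drift_slope != 0) {
    res$v <- res$v + noise$drift_slope * (seq_len(n) - 1) / fs
  }
  res
}

#' Simulate current-clamp responses to square current steps
#'
#' Integrates the [membrane_params()] model by exponential-Euler at the
#' sampling interval. With sag and after-currents disabled and a
#' subthreshold step `I`, the steady-state deflection is `I * R_in` and
#' the onset relaxation has time constant `tau_m` (the scheme is exact
#' for the linear subthreshold core).
#'
#' @param mp [membrane_params()].
#' @param prot [current_step_protocol()].
#' @param noise [noise_model()]; SD in mV.
#' @param seed Integer seed.
#' @param sampling_rate Hz.
#' @param holding_pa Tonic holding current added throughout the sweep,
#'   pA. Passive properties of a pacemaking cell are conventionally
#'   measured under a hyperpolarizing bias that silences it; pass
#'   `-mp$pacemaker_current` to hold the model at its resting
#'   potential.
#' @return Tibble with one row per step: `step_pa`, the current-clamp
#'   `sweep` (list-column; each sweep carries a `step` attribute with
#'   onset/duration/amplitude), and ground-truth spike counts/times.
#' @export
simulate_cc_steps <- function(mp, prot = current_step_protocol(),
                              noise = noise_model(0.2), seed = NULL,
                              sampling_rate = 20000, holding_pa = 0) {
  stopifnot(inherits(mp, "membrane_params"),
            inherits(prot, "current_step_protocol"))
  fs <- sampling_rate
  n_pre <- s_to_samples(prot$pre_baseline, fs)
  n_step <- s_to_samples(prot$step_duration, fs)
  n_post <- s_to_samples(prot$post_baseline, fs)
  rows <- purrr::imap(prot$step_amplitudes, function(amp, k) {
    i_inj <- holding_pa + c(rep(0, n_pre), rep(amp, n_step), rep(0, n_post))
    res <- sim_lif(mp, i_inj, noise, seed = child_seed(seed, k),
                   sampling_rate = fs)
    sw <- opto_sweep(res$v, sampling_rate = fs, clamp_mode = "current_clamp",
                     holding = holding_pa)
    attr(sw, "step") <- list(onset = prot$pre_baseline,
                             duration = prot$step_duration,
                             amplitude = amp)
    in_step <- res$spike_onsets > n_pre & res$spike_onsets <= n_pre + n_step
    tibble::tibble(step_pa = amp, sweep = list(sw),
                   n_spikes_true = sum(in_step),
                   spike_peaks_true = list(res$spike_peaks / fs))
  })
  dplyr::bind_rows(rows)
}

#' Simulate spontaneous activity
#'
#' @param mp [membrane_params()].
#' @param duration Recording duration, s.
#' @param mode `"whole_cell"` or `"on_cell"` (sets the sweep's clamp
#'   mode; the underlying membrane model is the same).
#' @param noise [noise_model()].
#' @param seed Integer seed.
#' @param sampling_rate Hz.
#' @return An [opto_sweep()] with ground-truth spike peak times (s) in
#'   the `truth` attribute.
#' @export
simulate_spontaneous <- function(mp, duration = 120,
                                 mode = c("whole_cell", "on_cell"),
                                 noise = noise_model(0.2), seed = NULL,
                                 sampling_rate = 20000) {
  mode <- match.arg(mode)
  fs <- sampling_rate
  res <- sim_lif(mp, rep(0, s_to_samples(duration, fs)), noise, seed,
                 sampling_rate = fs)
  sw <- opto_sweep(res$v, sampling_rate = fs,
                   clamp_mode = if (mode == "on_cell") "on_cell" else "current_clamp")
  attr(sw, "truth") <- list(spike_peaks_s = res$spike_peaks / fs)
  sw
}

#' Analytic rheobase of the passive model
#'
#' For a brief pulse of duration `T` the passive membrane reaches
#' `I * R_in * (1 - exp(-T / tau_m))`, so the minimum spiking current is
#' `(V_thr - E_rest) / (R_in * (1 - exp(-T / tau_m)))` (in pA with R in
#' MOhm and voltages in mV). Optionally rounded up to a stimulus grid.
#'
#' @param mp [membrane_params()] (must have `V_thr > E_rest`).
#' @param pulse_ms Pulse duration, ms.
#' @param grid Optional ascending amplitude grid (pA); the smallest grid
#'   value at or above the analytic bound is returned.
#' @return Rheobase in pA (`NA` if the grid maximum is too small).
#' @export
rheobase_analytic <- function(mp, pulse_ms = 5, grid = NULL) {
  stopifnot(inherits(mp, "membrane_params"))
  if (mp$V_thr <= mp$E_rest) {
    stop_arg("V_thr must be above E_rest for a rheobase to exist")
  }
  i_min <- (mp$V_thr - mp$E_rest) * 1000 /
    (mp$R_in * (1 - exp(-pulse_ms / mp$tau_m)))
  if (is.null(grid)) return(i_min)
  hit <- grid[grid >= i_min - 1e-9]
  if (length(hit) == 0) NA_real_ else hit[1]
}

#' Simulate an ascending brief-pulse rheobase series
#'
#' Applies the protocol's amplitudes in ascending order and stops at the
#' first amplitude that evokes a spike.
#'
#' @param mp [membrane_params()]; `V_thr` must be above `E_rest`.
#' @param prot [brief_pulse_protocol()].
#' @param noise [noise_model()].
#' @param seed Integer seed.
#' @param sampling_rate Hz.
#' @return Tibble with `amplitude_pa`, `spiked`, and the sweeps actually
#'   simulated (list-column).
#' @export
simulate_brief_pulse_series <- function(mp, prot = brief_pulse_protocol(),
                                        noise = noise_model(0), seed = NULL,
                                        sampling_rate = 20000) {
  stopifnot(inherits(mp, "membrane_params"),
            inherits(prot, "brief_pulse_protocol"))
  if (mp$V_thr <= mp$E_rest) {
    stop_arg("invalid params: V_thr at or below E_rest")
  }
  fs <- sampling_rate
  n_pre <- s_to_samples(prot$pre_baseline, fs)
  n_pulse <- ms_to_samples(prot$pulse_duration, fs)
  n_post <- s_to_samples(prot$post_baseline, fs)
  rows <- list()
  for (k in seq_along(prot$amplitudes)) {
    amp <- prot$amplitudes[k]
    i_inj <- c(rep(0, n_pre), rep(amp, n_pulse), rep(0, n_post))
    res <- sim_lif(mp, i_inj, noise, seed = child_seed(seed, k),
                   sampling_rate = fs)
    sw <- opto_sweep(res$v, sampling_rate = fs, clamp_mode = "current_clamp")
    attr(sw, "step") <- list(onset = prot$pre_baseline,
                             duration = prot$pulse_duration / 1000,
                             amplitude = amp)
    spiked <- length(res$spike_peaks) > 0
    rows[[k]] <- tibble::tibble(amplitude_pa = amp, spiked = spiked,
                                sweep = list(sw))
    if (spiked) break
  }
  dplyr::bind_rows(rows)
}

#' Default cohort design emulating the circuit-mapping experiment
#'
#' One row per (cortical source, projection class) pair with the cohort
#' size, the Bernoulli innervation probability (defaults are the
#' reported responder fractions: M1->GP_CPu 28/35, M2->GP_CPu 23/27,
#' M1->GP_STN 17/51, M2->GP_STN 36/75), and the log-normal oEPSC
#' amplitude distribution of innervated cells. `GP_CPu` rows can be
#' given a two-component mixture (`mix_weight` > 0) to emulate the
#' apparently bimodal amplitude distribution of striatum-projecting
#' pallidal cells.
#'
#' @param n_cells Optional scalar overriding every cohort size.
#' @param bimodal_cpu If `TRUE`, give GP_CPu rows a 2-component
#'   log-normal mixture whose lower component matches GP_STN.
#' @param include_comparison_groups If `TRUE`, append MSN and STN rows
#'   (always innervated) for amplitude comparisons.
#' @return Tibble of cohort settings consumed by [simulate_cohort()].
#' @export
cohort_config <- function(n_cells = NULL, bimodal_cpu = FALSE,
                          include_comparison_groups = FALSE) {
  cfg <- tibble::tribble(
    ~cortical_source, ~projection_class, ~n_cells, ~innervation_prob,
    ~amp_meanlog, ~amp_sdlog, ~mix_weight, ~mix_meanlog, ~mix_sdlog,
    "M1", "GP_CPu", 35L, 28 / 35, log(90), 0.6, 0, NA_real_, NA_real_,
    "M2", "GP_CPu", 27L, 23 / 27, log(90), 0.6, 0, NA_real_, NA_real_,
    "M1", "GP_STN", 51L, 17 / 51, log(40), 0.6, 0, NA_real_, NA_real_,
    "M2", "GP_STN", 75L, 36 / 75, log(40), 0.6, 0, NA_real_, NA_real_
  )
  if (bimodal_cpu) {
    i <- cfg$projection_class == "GP_CPu"
    cfg$mix_weight[i] <- 0.5
    cfg$mix_meanlog[i] <- log(40)
    cfg$mix_sdlog[i] <- 0.6
    cfg$amp_meanlog[i] <- log(150)
  }
  if (include_comparison_groups) {
    cfg <- dplyr::bind_rows(cfg, tibble::tribble(
      ~cortical_source, ~projection_class, ~n_cells, ~innervation_prob,
      ~amp_meanlog, ~amp_sdlog, ~mix_weight, ~mix_meanlog, ~mix_sdlog,
      "M1", "MSN", 11L, 1, log(350), 0.5, 0, NA_real_, NA_real_,
      "M1", "STN", 18L, 1, log(70), 0.6, 0, NA_real_, NA_real_
    ))
  }
  if (!is.null(n_cells)) cfg$n_cells <- as.integer(n_cells)
  if (any(cfg$innervation_prob < 0 | cfg$innervation_prob > 1)) {
    stop_validation("innervation probabilities must lie in [0, 1]")
  }
  if (any(cfg$n_cells < 0)) stop_validation("n_cells must be >= 0")
  cfg
}

#' Simulate a cohort of recorded cells with known connectivity
#'
#' Every cell receives a Bernoulli innervation flag; innervated cells
#' draw a ground-truth amplitude from the configured (mixture of)
#' log-normal(s), and all cells get simulated voltage-clamp trains
#' (amplitude zero, i.e. noise only, for non-innervated cells) so that
#' the full detection pipeline can be run blind to the truth.
#'
#' @param cfg Cohort design tibble, see [cohort_config()].
#' @param protocol [light_stim_protocol()] used for every recording.
#' @param noise [noise_model()] in pA.
#' @param seed Integer seed; stored in the dataset metadata.
#' @param make_traces If `FALSE`, skip trace simulation and return only
#'   the cell table with ground truth (used for design-level checks).
#' @param synapse Base [synapse_params()] whose kinetics/latency are
#'   used for every cell (the amplitude is drawn per cell).
#' @param sampling_rate Hz.
#' @return An [opto_dataset()] whose cell table carries
#'   `innervated_true` and `amplitude_true`.
#' @export
simulate_cohort <- function(cfg = cohort_config(),
                            protocol = light_stim_protocol(),
                            noise = noise_model(2),
                            seed = NULL,
                            make_traces = TRUE,
                            synapse = synapse_params(),
                            sampling_rate = 20000) {
  with_seed(seed, {
    cells <- purrr::pmap(cfg, function(cortical_source, projection_class,
                                       n_cells, innervation_prob,
                                       amp_meanlog, amp_sdlog,
                                       mix_weight, mix_meanlog, mix_sdlog, ...) {
      if (n_cells == 0) return(NULL)
      innervated <- stats::rbinom(n_cells, 1L, innervation_prob) == 1L
      amp <- numeric(n_cells)
      n_in <- sum(innervated)
      if (n_in > 0) {
        draws <- stats::rlnorm(n_in, amp_meanlog, amp_sdlog)
        if (!is.na(mix_weight) && mix_weight > 0) {
          # mix_weight is the weight of the lower-amplitude component
          low <- stats::rbinom(n_in, 1L, mix_weight) == 1L
          draws[low] <- stats::rlnorm(sum(low), mix_meanlog, mix_sdlog)
        }
        amp[innervated] <- draws
      }
      tibble::tibble(
        cell_id = sprintf("%s_%s_%03d", cortical_source, projection_class,
                          seq_len(n_cells)),
        projection_class = projection_class,
        cortical_source = cortical_source,
        innervated_true = innervated,
        amplitude_true = amp
      )
    })
    cells <- dplyr::bind_rows(cells)
    sweeps <- tibble::tibble(cell_id = character(), sweep_id = character(),
                             protocol_id = character(), sweep = list())
    if (make_traces && nrow(cells) > 0) {
      sweep_rows <- purrr::map(seq_len(nrow(cells)), function(i) {
        sp <- synapse
        sp$amplitude <- cells$amplitude_true[i]
        sws <- simulate_vc_trains(sp, protocol, noise,
                                  seed = child_seed(seed, i * 131L),
                                  sampling_rate = sampling_rate)
        tibble::tibble(
          cell_id = cells$cell_id[i],
          sweep_id = sprintf("%s_train%02d", cells$cell_id[i],
                             seq_along(sws)),
          protocol_id = "light",
          sweep = sws
        )
      })
      sweeps <- dplyr::bind_rows(sweep_rows)
    }
    opto_dataset(
      cells = cells,
      sweeps = sweeps,
      protocols = list(light = protocol),
      metadata = list(seed = seed, generator = "simulate_cohort")
    )
  })
}

#' Spatial bouton-density field configuration
#'
#' Describes per-region mediolateral (M/L) density profiles of cortical
#' axon varicosities as Gaussian bumps: `density(ml) = peak *
#' exp(-(ml - peak_ml)^2 / (2 * ml_sd^2))` in boutons per
#' 100 x 100 um^2. Default magnitudes follow the reported maxima in GP,
#' striatum (CPu) and STN for M1 and M2 injections; per-animal
#' log-normal scaling emulates variable tracer-labeling efficacy.
#'
#' @param profiles Tibble with columns `cortical_source`, `region`,
#'   `peak_density`, `peak_ml`, `ml_sd`; `NULL` for the defaults.
#' @param n_animals Animals per cortical source.
#' @param ml_positions ROI centers along the M/L axis, mm from midline.
#' @param roi_width,roi_height ROI dimensions, um.
#' @param animal_effect_sdlog Log-normal SD of the per-animal labeling
#'   factor (0 disables it; the factor has mean 1).
#' @return A `bouton_field_config` object.
#' @export
bouton_field_config <- function(profiles = NULL,
                                n_animals = 4,
                                ml_positions = seq(2.4, 4.2, by = 0.3),
                                roi_width = 233, roi_height = 173,
                                animal_effect_sdlog = 0.35) {
  if (is.null(profiles)) {
    profiles <- tibble::tribble(
      ~cortical_source, ~region, ~peak_density, ~peak_ml, ~ml_sd,
      "M1", "GP",  224, 3.4, 0.6,
      "M1", "CPu", 1083, 3.4, 0.8,
      "M1", "STN", 468, 2.9, 0.4,
      "M2", "GP",  415, 3.0, 0.5,
      "M2", "CPu", 1387, 3.2, 0.8,
      "M2", "STN", 488, 2.7, 0.4
    )
  }
  if (any(profiles$peak_density < 0)) stop_validation("densities must be >= 0")
  stopifnot(roi_width > 0, roi_height > 0, n_animals >= 1)
  structure(
    list(profiles = tibble::as_tibble(profiles), n_animals = as.integer(n_animals),
         ml_positions = ml_positions, roi_width = roi_width,
         roi_height = roi_height, animal_effect_sdlog = animal_effect_sdlog),
    class = "bouton_field_config"
  )
}

#' Generate synthetic ROI bouton counts
#'
#' ROI counts are Poisson with mean `density(ml) * roi_area / 1e4`
#' (densities are per 100 x 100 um^2), after per-animal log-normal
#' scaling of the whole field.
#'
#' @param cfg [bouton_field_config()].
#' @param seed Integer seed.
#' @return Tibble of ROI counts with columns `animal_id`,
#'   `cortical_source`, `region`, `ml_position`, `count`, `roi_width`,
#'   `roi_height`; ground-truth expected densities in the
#'   `truth` attribute.
#' @export
generate_bouton_counts <- function(cfg = bouton_field_config(), seed = NULL) {
  stopifnot(inherits(cfg, "bouton_field_config"))
  with_seed(seed, {
    grid <- tidyr::crossing(
      animal = seq_len(cfg$n_animals),
      cfg$profiles,
      ml_position = cfg$ml_positions
    )
    sources <- unique(grid$cortical_source)
    factors <- tidyr::crossing(animal = seq_len(cfg$n_animals),
                               cortical_source = sources)
    s <- cfg$animal_effect_sdlog
    factors$animal_factor <- if (s > 0) {
      stats::rlnorm(nrow(factors), meanlog = -s^2 / 2, sdlog = s)
    } else {
      1
    }
    grid <- dplyr::left_join(grid, factors, by = c("animal", "cortical_source"))
    grid$density_true <- grid$peak_density * grid$animal_factor *
      exp(-(grid$ml_position - grid$peak_ml)^2 / (2 * grid$ml_sd^2))
    lambda <- grid$density_true * cfg$roi_width * cfg$roi_height / 1e4
    out <- tibble::tibble(
      animal_id = sprintf("%s_rat%d", grid$cortical_source, grid$animal),
      cortical_source = grid$cortical_source,
      region = grid$region,
      ml_position = grid$ml_position,
      count = stats::rpois(nrow(grid), lambda),
      roi_width = cfg$roi_width,
      roi_height = cfg$roi_height
    )
    attr(out, "truth") <- grid[, c("animal", "cortical_source", "region",
                                   "ml_position", "density_true")]
    out
  })
}
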