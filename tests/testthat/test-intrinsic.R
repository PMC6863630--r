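hyper_protocol <- current_step_protocol(
  step_amplitudes = c(seq(-100, -20, by = 20), -50, 100, 500)
)

test_that("input resistance is the slope of the steady-state V-I relation", {
  # perfectly ohmic synthetic cell
  mp <- membrane_params(R_in = 100, tau_m = 10, E_rest = -50, V_thr = 0,
                        V_reset = -60, fahp_amp = 0, sahp_amp = 0)
  st <- simulate_cc_steps(mp, current_step_protocol(
    step_amplitudes = seq(-100, -20, by = 20)), noise_model(0), seed = 1)
  r <- input_resistance(st)
  expect_lt(abs(r$r_in_mohm - 100) / 100, 0.01)
  expect_false(r$flagged)
  # all-zero responses: slope 0, flagged implausible
  flat <- st
  flat$sweep <- lapply(flat$sweep, function(s) {
    z <- opto_sweep(rep(-50, length(s)), clamp_mode = "current_clamp")
    attr(z, "step") <- attr(s, "step")
    z
  })
  rf <- input_resistance(flat)
  expect_equal(rf$r_in_mohm, 0, tolerance = 1e-8)
  expect_true(rf$flagged)
  # fewer than two amplitudes is an argument error
  expect_error(input_resistance(st[1, ]), class = "optopallidum_argument_error")
  # GP_STN preset with realistic noise recovers within 5% across seeds
  mp_gp <- membrane_preset("GP_STN")
  errs <- vapply(1:20, function(s) {
    st_s <- simulate_cc_steps(mp_gp, current_step_protocol(
      step_amplitudes = seq(-100, -20, by = 20)), noise_model(0.2), seed = s,
      holding_pa = -mp_gp$pacemaker_current)
    input_resistance(st_s)$r_in_mohm / 232.35 - 1
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.05)
})

test_that("membrane time constant is recovered from the -50 pA response", {
  for (tau_true in c(12.94, 21.92)) {
    mp <- membrane_params(R_in = 232.35, tau_m = tau_true, fahp_amp = 0,
                          sahp_amp = 0)
    st <- simulate_cc_steps(mp, current_step_protocol(step_amplitudes = -50),
                            noise_model(0), seed = 1)
    tau <- time_constant(st$sweep[[1]])
    expect_lt(abs(tau$tau_ms - tau_true) / tau_true, 0.02)
  }
  # flat response yields a flagged missing value
  z <- opto_sweep(rep(-50, 28000), clamp_mode = "current_clamp")
  attr(z, "step") <- list(onset = 0.2, duration = 1, amplitude = -50)
  expect_true(is.na(time_constant(z)$tau_ms))
})

test_that("sag amplitude matches a dense-simulation oracle", {
  # passive cell: no sag mechanism, measured sag ~ 0
  mp0 <- membrane_preset("GP_STN", passive = TRUE)
  st0 <- simulate_cc_steps(mp0, current_step_protocol(step_amplitudes = -100),
                           noise_model(0), seed = 1)
  expect_lt(sag_amplitude(st0$sweep[[1]])$sag_mv, 0.2)
  # sag-enabled cell: standard-rate estimate within 10% of the value
  # measured on a 5x-oversampled simulation of the same cell
  mp <- membrane_params(R_in = 232.35, sag_mv = 7, pacemaker_current = 0,
                        fahp_amp = 0, sahp_amp = 0)
  st20 <- simulate_cc_steps(mp, current_step_protocol(step_amplitudes = -100),
                            noise_model(0), seed = 1)
  est <- sag_amplitude(st20$sweep[[1]])$sag_mv
  st100 <- simulate_cc_steps(mp, current_step_protocol(step_amplitudes = -100),
                             noise_model(0), seed = 1, sampling_rate = 1e5)
  oracle <- sag_amplitude(st100$sweep[[1]])$sag_mv
  expect_gt(oracle, 1) # the mechanism does produce a sag
  expect_lt(abs(est - oracle) / oracle, 0.1)
  # depolarizing steps are rejected
  dep <- simulate_cc_steps(mp, current_step_protocol(step_amplitudes = 100),
                           noise_model(0), seed = 1)
  expect_error(sag_amplitude(dep$sweep[[1]]),
               class = "optopallidum_argument_error")
})

test_that("spike detection finds stamped spikes and nothing in noise", {
  tr <- make_spike_trace(c(0.5, 1.0, 1.5))
  sp <- detect_spikes(tr)
  expect_equal(nrow(sp), 3)
  expect_equal(sp$peak_time_s, c(0.5, 1.0, 1.5), tolerance = 1 / fs_default)
  # subthreshold trace: no spikes
  expect_equal(nrow(detect_spikes(make_spike_trace(numeric(0)))), 0)
  # sigma = 1 mV subthreshold noise: zero false spikes over repeated draws
  mp <- membrane_preset("GP_STN", passive = TRUE)
  fp <- vapply(1:100, function(s) {
    st <- simulate_cc_steps(mp, current_step_protocol(step_amplitudes = -20,
                                                      pre_baseline = 0.05,
                                                      step_duration = 0.2,
                                                      post_baseline = 0.05),
                            noise_model(1), seed = s)
    nrow(detect_spikes(st$sweep[[1]]))
  }, numeric(1))
  expect_equal(sum(fp), 0)
})

test_that("spike features recover the stamped waveform", {
  # Table-mean stamp: height and width recovered within 5%
  mp <- membrane_preset("GP_STN")
  sw <- simulate_spontaneous(mp, 5, noise = noise_model(0), seed = 1)
  spikes <- detect_spikes(sw)
  expect_gt(nrow(spikes), 3)
  f <- spike_features(sw, spikes[2, ], next_onset_idx = spikes$onset_idx[3])
  expect_lt(abs(f$height_mv - 74.06) / 74.06, 0.05)
  expect_lt(abs(f$width_ms - 0.95) / 0.95, 0.05)
  expect_lt(abs(f$v_thr - mp$V_thr), 1)
  # AHP troughs fall below threshold with ordered delays
  expect_gt(f$fahp_amp_mv, 0)
  expect_gte(f$sahp_delay_ms, f$fahp_delay_ms)
  # symmetric triangular spike: width equals half the base duration
  tr <- make_spike_trace(1, width_ms = 2) # base = 2 * 2 ms
  sp <- detect_spikes(tr)
  f2 <- spike_features(tr, sp[1, ])
  expect_equal(f2$width_ms, 2, tolerance = 0.03)
  # no post-spike minimum below threshold: AHP fields missing, flagged
  n <- 2000
  v <- rep(-60, n)
  v[1000:1010] <- seq(-40, 30, length.out = 11)
  v[1011:1020] <- seq(30, -39, length.out = 10)
  v[1021:n] <- -39 # stays at threshold level, never dips below
  sw3 <- opto_sweep(v, clamp_mode = "current_clamp")
  sp3 <- detect_spikes(sw3)
  f3 <- spike_features(sw3, sp3[1, ])
  expect_true(is.na(f3$fahp_amp_mv) && is.na(f3$sahp_amp_mv))
  expect_true(f3$ahp_flagged)
})

test_that("f-I metrics count spikes per 1 s step with the stated tie-break", {
  fake_step <- function(n_spikes, amp) {
    times <- if (n_spikes > 0) 0.2 + seq_len(n_spikes) / (n_spikes + 1) else numeric(0)
    sw <- make_spike_trace(times, duration = 1.4)
    attr(sw, "step") <- list(onset = 0.2, duration = 1, amplitude = amp)
    sw
  }
  steps <- tibble::tibble(
    step_pa = c(100, 200, 500, 600),
    sweep = list(fake_step(48, 100), fake_step(60, 200), fake_step(75, 500),
                 fake_step(75, 600))
  )
  fi <- f_i_metrics(steps)
  expect_equal(fi$f_100_hz, 48)
  expect_equal(fi$f_500_hz, 75)
  expect_equal(fi$f_max_hz, 75)
  expect_equal(fi$i_at_fmax_pa, 500) # tie at 500/600 pA: smaller current wins
  # frequencies on 1 s steps are integers by construction
  expect_true(all(c(fi$f_100_hz, fi$f_500_hz, fi$f_max_hz) %% 1 == 0))
})

test_that("rheobase scan returns the first spiking amplitude or a missing value", {
  mp <- membrane_preset("GP_STN", passive = TRUE)
  ser <- simulate_brief_pulse_series(mp)
  expect_equal(rheobase(ser)$rheobase_pa, 125)
  # grid maximum too small: no rheobase found
  ser_small <- simulate_brief_pulse_series(
    mp, brief_pulse_protocol(amplitudes = c(5, 10, 20)))
  rb <- rheobase(ser_small)
  expect_true(is.na(rb$rheobase_pa))
  expect_false(rb$found)
  # threshold exactly reachable at one grid point returns that point
  g1 <- rheobase_analytic(mp, 5)
  expect_equal(rheobase_analytic(mp, 5, grid = c(g1, 500)), g1)
})

test_that("spontaneous rate is count over duration with a length gate", {
  tr <- make_spike_trace(seq(0.5, 119.5, by = 1), duration = 120)
  r <- spontaneous_rate(tr, "on_cell")
  expect_equal(r$rate_hz, 1)
  expect_false(r$flagged)
  expect_equal(spontaneous_rate(make_spike_trace(numeric(0)), "whole_cell")$rate_hz, 0)
  expect_true(spontaneous_rate(make_spike_trace(0.5, duration = 2), "on_cell")$flagged)
  # simulated pacemaker: extracted rate equals the generator's spike count
  mp <- membrane_preset("GP_STN")
  sw <- simulate_spontaneous(mp, 30, mode = "on_cell", noise = noise_model(0),
                             seed = 3)
  truth_rate <- length(attr(sw, "truth")$spike_peaks_s) / 30
  expect_lt(abs(spontaneous_rate(sw, "on_cell")$rate_hz - truth_rate) /
              truth_rate, 0.05)
})

test_that("putative cholinergic flag applies the stated rule strictly", {
  feats <- tibble::tibble(
    rate_oncell_hz = c(0.5, 20, 3, 2.9),
    spike_width_ms = c(2.5, 2.5, 2.5, 1.0)
  )
  out <- flag_putative_cholinergic(feats)
  expect_identical(out$putative_cholinergic, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("full preset round trip recovers the configured phenotype", {
  for (ty in c("GP_STN", "GP_CPu")) {
    mp <- membrane_preset(ty)
    st <- simulate_cc_steps(mp, hyper_protocol, noise_model(0), seed = 1,
                            holding_pa = -mp$pacemaker_current)
    sw <- simulate_spontaneous(mp, 20, noise = noise_model(0), seed = 2)
    f <- intrinsic_features(st, spont_wholecell = sw)
    expect_lt(abs(f$r_in_mohm / mp$R_in - 1), 0.05)
    expect_lt(abs(f$tau_ms / mp$tau_m - 1), 0.05)
    expect_lt(abs(f$spike_height_mv / mp$spike_height - 1), 0.05)
    expect_lt(abs(f$spike_width_ms / mp$spike_width - 1), 0.05)
    truth_rate <- length(attr(sw, "truth")$spike_peaks_s) / 20
    expect_lt(abs(f$rate_wholecell_hz / truth_rate - 1), 0.05)
  }
})
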