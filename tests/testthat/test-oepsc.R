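test_that("boxcar smoothing is a trailing 4-point average that conserves mass", {
  fs <- 20000
  x <- rep(0, 100)
  x[50] <- 1
  sm <- smooth_trace(x, detection_config(), sampling_rate = fs)
  expect_equal(sm[50:53], rep(0.25, 4))
  expect_true(all(sm[-(50:53)] == 0))
  expect_equal(sum(sm), sum(x)) # interior-supported: mass conserved
  # constants are unchanged
  expect_equal(smooth_trace(rep(-20, 50), sampling_rate = fs), rep(-20, 50))
  # window longer than trace errors
  expect_error(smooth_trace(1:3, sampling_rate = fs),
               class = "optopallidum_argument_error")
})

test_that("aligned averaging reduces noise as 1/sqrt(N)", {
  prot <- short_light_protocol(n_pulses = 1, n_trains = 1)
  sp <- synapse_params(amplitude = 0)
  # identical sweeps average to themselves
  sw <- simulate_vc_train(synapse_params(amplitude = 30, latency_jitter_sd = 0),
                          prot, noise_model(0), seed = 1)
  ave <- average_aligned(list(sw, sw, sw), prot)
  expect_equal(as.numeric(ave$avg), as.numeric(sw))
  # symmetric noise cancels exactly
  eps <- rnorm(length(sw))
  up <- opto_sweep(as.numeric(sw) + eps, clamp_mode = "voltage_clamp")
  dn <- opto_sweep(as.numeric(sw) - eps, clamp_mode = "voltage_clamp")
  expect_equal(as.numeric(average_aligned(list(up, dn), prot)$avg),
               as.numeric(sw))
  # CLT: residual SD of a 100-sweep average of sigma = 2 noise
  sws <- simulate_vc_trains(sp, light_stim_protocol(n_pulses = 1, n_trains = 100,
                                                    first_onset = 0.05, tail = 0.05),
                            noise_model(2), seed = 4)
  resid <- as.numeric(average_aligned(sws, prot)$avg)
  expect_lt(abs(sd(resid) - 2 / sqrt(100)) / (2 / sqrt(100)), 0.2)
  # mismatched sweeps are a validation error
  short <- opto_sweep(as.numeric(sw)[1:100], clamp_mode = "voltage_clamp")
  expect_error(average_aligned(list(sw, short), prot),
               class = "optopallidum_validation_error")
})

test_that("baseline statistics recover the pre-pulse mean and SD", {
  flat <- make_vc_sweep(numeric(0), baseline = -20)
  bs <- baseline_stats(flat, 0.1)
  expect_equal(bs$baseline_mean, -20)
  expect_equal(bs$baseline_sd, 0)
  expect_equal(bs$n_samples, 1000)
  # sample SD concentrates around the true sigma = 2
  noisy <- make_vc_sweep(numeric(0), noise_sd = 2, seed = 8)
  bs2 <- baseline_stats(noisy, 0.1)
  se_sd <- 2 / sqrt(2 * (bs2$n_samples - 1))
  expect_lt(abs(bs2$baseline_sd - 2), 3 * se_sd)
  # an onset with no pre-samples is an error
  expect_error(baseline_stats(flat, 0), class = "optopallidum_argument_error")
  # short but usable baselines shrink with a warning
  expect_warning(baseline_stats(flat, 0.02), "shortened")
})

test_that("detection separates real oEPSCs from noise and is scale-equivariant", {
  prot <- short_light_protocol(n_pulses = 1, n_trains = 10)
  sp <- synapse_params(amplitude = 50)
  sws <- simulate_vc_trains(sp, prot, noise_model(2), seed = 2)
  m <- measure_oepsc_train(sws, prot)
  expect_true(m$detected[1])
  expect_lt(abs(m$amplitude[1] - 50) / 50, 0.05)
  # amplitude-zero synapse: not detected
  sws0 <- simulate_vc_trains(synapse_params(amplitude = 0), prot,
                             noise_model(2), seed = 2)
  m0 <- measure_oepsc_train(sws0, prot)
  expect_false(m0$detected[1])
  # zero signal, zero noise: detected FALSE with amplitude 0
  mz <- detect_and_measure(make_vc_sweep(numeric(0)), 0.1)
  expect_false(mz$detected)
  expect_equal(mz$amplitude, 0)
  # scale equivariance: rescaling the traces leaves the flag unchanged
  for (c_scale in c(0.1, 17)) {
    scaled <- lapply(sws, function(s) {
      opto_sweep(as.numeric(s) * c_scale, clamp_mode = "voltage_clamp")
    })
    ms <- measure_oepsc_train(scaled, prot)
    expect_true(ms$detected[1])
    expect_equal(ms$amplitude[1], m$amplitude[1] * c_scale, tolerance = 1e-10)
    scaled0 <- lapply(sws0, function(s) {
      opto_sweep(as.numeric(s) * c_scale, clamp_mode = "voltage_clamp")
    })
    expect_false(measure_oepsc_train(scaled0, prot)$detected[1])
  }
})

test_that("false-positive rate on pure noise matches the Gaussian-extremum null", {
  # package pipeline on noise-only recordings
  prot <- short_light_protocol(n_pulses = 1, n_trains = 2)
  n_rep <- 150
  fp_pkg <- vapply(seq_len(n_rep), function(s) {
    sws <- simulate_vc_trains(synapse_params(amplitude = 0), prot,
                              noise_model(2), seed = s)
    measure_oepsc_train(sws, prot)$detected[1]
  }, logical(1))
  # independent Monte-Carlo oracle of the same null: extremum of the
  # 4-point-smoothed averaged Gaussian noise vs 3 x raw-baseline SD
  set.seed(4242)
  cfg <- detection_config()
  n_base <- 1000
  n_win <- 1800
  fp_null <- vapply(seq_len(n_rep), function(s) {
    avg <- colMeans(matrix(rnorm(2 * (n_base + n_win), 0, 2), nrow = 2))
    thr <- 3 * sd(avg[seq_len(n_base)])
    sm <- as.numeric(stats::filter(avg, rep(0.25, 4), sides = 1))
    peak <- min(sm[(n_base + 4):(n_base + n_win)], na.rm = TRUE) -
      mean(avg[seq_len(n_base)])
    -peak > thr
  }, logical(1))
  # the two rates agree within 3 binomial SEs of their pooled estimate
  p_pool <- (sum(fp_pkg) + sum(fp_null) + 1) / (2 * n_rep + 2)
  se <- sqrt(2 * p_pool * (1 - p_pool) / n_rep)
  expect_lt(abs(mean(fp_pkg) - mean(fp_null)), 3 * se + 1e-12)
  expect_lt(mean(fp_pkg), 0.05)
})

test_that("onset extrapolation recovers ramp onsets and configured latencies", {
  fs <- 20000
  # noiseless linear ramp: the fitted line extrapolates to its own start
  ramp <- c(seq(0, -50, length.out = 101)[-1], rep(-50, 200))
  sw <- make_vc_sweep(ramp, t_on = 0.1)
  m <- detect_and_measure(sw, 0.1)
  ol <- onset_and_latency(sw, 0.1, m)
  expect_lt(abs(ol$onset_time_s - 0.1), 1 / fs + 1e-12)
  expect_false(ol$flagged)
  # synthetic kernel with configured 3.0 ms latency, no jitter/noise
  sp <- synapse_params(amplitude = 50, latency_mean = 3, latency_jitter_sd = 0)
  prot <- short_light_protocol(n_pulses = 1, n_trains = 1)
  mm <- measure_oepsc_train(simulate_vc_train(sp, prot, noise_model(0), seed = 1),
                            prot)
  expect_lt(abs(mm$latency_ms[1] - 3), 0.15)
  # latency is non-negative when the search starts at the pulse onset
  expect_gte(mm$latency_ms[1], 0)
  # undetected oEPSC is a precondition error
  mz <- detect_and_measure(make_vc_sweep(numeric(0)), 0.1)
  expect_error(onset_and_latency(make_vc_sweep(numeric(0)), 0.1, mz),
               class = "optopallidum_argument_error")
})

test_that("rise and decay kinetics match their analytic values", {
  fs <- 20000
  tau_r <- 2 # ms
  t_ms <- (0:4000) / fs * 1000
  # single-exponential rise: 20-80% rise time = tau * ln 4
  rise <- -40 * (1 - exp(-t_ms / tau_r))
  sw <- make_vc_sweep(rise, t_on = 0.1, duration = 0.5)
  m <- detect_and_measure(sw, 0.1)
  kin <- rise_decay_kinetics(sw, 0.1, m)
  expect_lt(abs(kin$rise_time_ms - tau_r * log(4)) / (tau_r * log(4)), 0.01)
  # pure exponential decay self-fits to its own constant
  decay <- c(seq(0, -40, length.out = 11)[-1], -40 * exp(-t_ms / 10))
  sw2 <- make_vc_sweep(decay, t_on = 0.1, duration = 0.5)
  m2 <- detect_and_measure(sw2, 0.1)
  kin2 <- rise_decay_kinetics(sw2, 0.1, m2)
  expect_lt(abs(kin2$decay_tau_ms - 10) / 10, 0.01)
  # double-exponential kernel: decay constant agrees with the value
  # obtained by the same fit definition on the densely sampled kernel
  sp <- synapse_params(amplitude = 50, latency_jitter_sd = 0)
  prot <- short_light_protocol(n_pulses = 1, n_trains = 1)
  mm <- measure_oepsc_train(simulate_vc_train(sp, prot, noise_model(0), seed = 1),
                            prot)
  td <- seq(0, 60, by = 1e-3) # dense kernel, 1 us steps
  g <- exp(-td / sp$tau_decay) - exp(-td / sp$tau_rise)
  g <- g / max(g)
  i_pk <- which.max(g)
  i_10 <- i_pk + which(g[-seq_len(i_pk)] <= 0.1)[1] - 1
  seg_t <- td[i_pk:i_10] - td[i_pk]
  seg_y <- g[i_pk:i_10]
  fit <- stats::optim(c(1, 8), function(p) {
    sum((seg_y - p[1] * exp(-seg_t / p[2]))^2)
  })
  expect_lt(abs(mm$decay_tau_ms[1] - fit$par[2]) / fit$par[2], 0.05)
})

test_that("per-pulse amplitudes and paired-pulse ratio use local baselines", {
  prot <- light_stim_protocol(n_pulses = 2, n_trains = 1, first_onset = 0.1)
  sp <- synapse_params(amplitude = 10, latency_jitter_sd = 0,
                       plasticity_factors = c(1, 1.45))
  res <- train_amplitudes_and_ppr(simulate_vc_train(sp, prot, noise_model(0),
                                                    seed = 1), prot)
  expect_length(res$per_pulse_amplitudes, 2)
  expect_lt(abs(res$ppr - 1.45) / 1.45, 0.05)
  # direct arithmetic: amplitudes (10, 12.5) give ppr 1.25
  sp2 <- synapse_params(amplitude = 10, latency_jitter_sd = 0,
                        plasticity_factors = c(1, 1.25))
  res2 <- train_amplitudes_and_ppr(simulate_vc_train(sp2, prot, noise_model(0),
                                                     seed = 1), prot)
  expect_equal(res2$ppr, 1.25, tolerance = 0.01)
  # complete failure on pulse 2: ppr ~ 0 and pulse 2 not detected
  sp3 <- synapse_params(amplitude = 10, latency_jitter_sd = 0,
                        plasticity_factors = c(1, 0))
  m3 <- measure_oepsc_train(simulate_vc_train(sp3, prot, noise_model(0),
                                              seed = 1), prot)
  expect_false(m3$detected[2])
  expect_equal(m3$ppr[1], 0)
  # undetected first pulse leaves the ratio undefined, with a warning
  sw0 <- simulate_vc_train(synapse_params(amplitude = 0), prot,
                           noise_model(2), seed = 1)
  expect_warning(res0 <- train_amplitudes_and_ppr(sw0, prot), "paired-pulse")
  expect_true(is.na(res0$ppr))
})

test_that("amplitude normalization divides by the reference mean", {
  expect_equal(normalize_amplitude(60, 100), 0.6)
  expect_equal(normalize_amplitude(c(50, 100), c(90, 110)), c(0.5, 1))
  expect_equal(normalize_amplitude(rep(77, 3), 77), rep(1, 3))
  expect_error(normalize_amplitude(1, 0), class = "optopallidum_argument_error")
  expect_error(normalize_amplitude(1, c(-2, 2)),
               class = "optopallidum_argument_error")
})

test_that("amplitude recovery holds across an SNR grid (median error < 5%)", {
  prot <- light_stim_protocol(n_pulses = 1, n_trains = 10, first_onset = 0.1,
                              tail = 0.12)
  grid <- expand.grid(A = c(20, 50, 100), sigma = c(1, 2))
  grid <- grid[grid$A / grid$sigma >= 10, ]
  errs <- unlist(lapply(seq_len(nrow(grid)), function(i) {
    vapply(1:10, function(s) {
      sp <- synapse_params(amplitude = grid$A[i])
      sws <- simulate_vc_trains(sp, prot, noise_model(grid$sigma[i]),
                                seed = 1000 * i + s)
      m <- measure_oepsc_train(sws, prot)
      abs(m$amplitude[1] / grid$A[i] - 1)
    }, numeric(1))
  }))
  expect_lt(median(errs), 0.05)
})
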