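test_that("spike detector finds template spikes and nothing on flat traces", {
  fs <- 10000
  expect_length(detect_spikes(rep(-70, fs), fs), 0)
  # three template spikes planted by the generator at known ground truth
  tr <- noiseless_truth(rheobase_pa = 100, gain_hz_na = 3)
  sw <- simulate_neuron_sweeps(tr, fast_protocol(max_pa = 1100), seed = 1)
  k <- which(sw$amplitude_pa == 1100)  # f = 3 Hz -> 3 spikes
  truth_times <- attr(sw, "spike_times")[[k]]
  det <- detect_spikes(sw$voltage[[k]], fs)
  expect_length(det, length(truth_times))
  expect_lt(max(abs(det - truth_times)), 1e-3)
})

test_that("detector is invariant to moderate additive noise on template trains", {
  tr <- noiseless_truth(rheobase_pa = 200, gain_hz_na = 100)
  sw0 <- simulate_neuron_sweeps(tr, fast_protocol(max_pa = 600), seed = 1)
  k <- which(sw0$amplitude_pa == 600)
  n0 <- length(detect_spikes(sw0$voltage[[k]], 10000))
  for (s in 1:3) {
    noisy <- sw0$voltage[[k]] +
      withr::with_seed(s, rnorm(length(sw0$voltage[[k]]), sd = 1))
    expect_equal(length(detect_spikes(noisy, 10000)), n0)
  }
})

test_that("firing frequencies follow their definitions", {
  # 1/(t2 - t1)
  ff <- firing_frequencies(c(0.10, 0.20), 1)
  expect_equal(ff$instantaneous_hz, 10)
  expect_equal(ff$mean_hz, 10)
  # regular 50 Hz train: all three equal 50
  st <- seq(0.01, 0.99, by = 0.02)
  ff <- firing_frequencies(st, 1)
  expect_equal(ff$instantaneous_hz, 50)
  expect_equal(ff$steady_state_hz, 50)
  expect_equal(ff$mean_hz, 50)
  # < 2 spikes: instantaneous undefined, mean 0 by convention
  ff1 <- firing_frequencies(0.5, 1)
  expect_true(is.na(ff1$instantaneous_hz))
  expect_equal(ff1$mean_hz, 0)
  # decelerating train: instantaneous >= mean
  dec <- cumsum(c(0.05, 0.02 * 1.25^(0:14)))
  ffd <- firing_frequencies(dec[dec < 1], 1)
  expect_gte(ffd$instantaneous_hz, ffd$mean_hz)
  expect_error(firing_frequencies(c(0.2, 1.5), 1), "within")
})

test_that("rheobase is the first spiking grid point, flagged when unreached", {
  tr <- noiseless_truth(rheobase_pa = 230)
  sw <- simulate_neuron_sweeps(tr, fast_protocol(max_pa = 400), seed = 1)
  rb <- rheobase(sw)
  expect_true(rb$reached)
  expect_equal(rb$rheobase_pa, 240)
  # ceiling case: no spikes up to the protocol maximum
  tr_hi <- noiseless_truth(rheobase_pa = 1200)
  sw_hi <- simulate_neuron_sweeps(tr_hi, fast_protocol(max_pa = 1000), seed = 1)
  rb_hi <- rheobase(sw_hi)
  expect_false(rb_hi$reached)
  expect_true(is.na(rb_hi$rheobase_pa))
})

test_that("F-I gain is the OLS slope and is exact on an exact line", {
  amps <- seq(240, 1000, by = 20)
  freq <- tibble::tibble(
    amplitude_pa = amps,
    mean_hz = 161.01 * (amps / 1000 - 0.22187),
    instantaneous_hz = 161.01 * (amps / 1000 - 0.22187),
    n_spikes = 10
  )
  g <- fi_gain(freq)
  expect_equal(g$gain_hz_na, 161.01, tolerance = 1e-10)
  expect_equal(g$instantaneous_gain_hz_na, 161.01, tolerance = 1e-10)
  # identical frequencies across currents -> zero gain
  flat <- dplyr::mutate(freq, mean_hz = 30, instantaneous_hz = 30)
  expect_equal(fi_gain(flat)$gain_hz_na, 0, tolerance = 1e-12)
  # fewer than 2 defined points -> flagged undefined
  few <- freq[1, ]
  expect_false(fi_gain(few)$defined)
})

test_that("passive properties recover Rin, tau and Cm from noiseless sweeps", {
  tr <- noiseless_truth(rheobase_pa = 500, rin_mohm = 100, cm_pf = 100)
  sw <- simulate_neuron_sweeps(tr, fast_protocol(max_pa = 400), seed = 1)
  pp <- passive_properties(sw)
  expect_true(pp$defined)
  expect_equal(pp$input_resistance_mohm, 100, tolerance = 1e-3)
  expect_equal(pp$tau_ms, 10, tolerance = 0.02)
  expect_equal(pp$capacitance_pf, 100, tolerance = 0.02)
})

test_that("AHP metrics match the closed form for an exponential AHP", {
  fs <- 20000
  baseline <- -70
  v <- rep(baseline, 3 * fs / 10)
  t_spk <- 0.1
  i_spk <- round(t_spk * fs) + 1
  # minimal spike stub then a 5 mV AHP with tau = 30 ms
  v[i_spk:(i_spk + 19)] <- 30
  idx <- (i_spk + 20):length(v)
  v[idx] <- baseline - 5 * exp(-((idx - i_spk - 20) / fs) / 0.030)
  m <- ahp_metrics(v, fs, t_spk, search_ms = 250)
  expect_true(m$defined)
  expect_equal(m$ahp_amplitude_mv, 5, tolerance = 1e-3)
  expect_equal(m$ahp_half_decay_ms, 30 * log(2), tolerance = 0.02)
  # no hyperpolarization -> amplitude 0, times undefined
  flat <- rep(baseline, fs)
  flat[i_spk:(i_spk + 19)] <- 30
  m0 <- ahp_metrics(flat, fs, t_spk)
  expect_equal(m0$ahp_amplitude_mv, 0)
  expect_false(m0$defined)
})

test_that("extract_properties recovers all noiseless ground truths", {
  tr <- noiseless_truth(rheobase_pa = 230, gain_hz_na = 100,
                        rin_mohm = 100, cm_pf = 100,
                        ahp_amp_mv = 4, ahp_tau_ms = 20)
  sw <- simulate_neuron_sweeps(tr, fast_protocol(max_pa = 600), seed = 1)
  pr <- extract_properties(sw)
  expect_equal(pr$rheobase_pa, 240)
  expect_equal(pr$gain_hz_na, 100, tolerance = 1e-2)
  expect_equal(pr$input_resistance_mohm, 100, tolerance = 1e-2)
  expect_equal(pr$capacitance_pf, 100, tolerance = 1e-2)
  expect_equal(pr$ahp_amplitude_mv, 4, tolerance = 0.05)
  expect_equal(pr$ahp_half_decay_ms, 20 * log(2), tolerance = 0.1)
  expect_true(pr$ahp_defined)
  expect_error(extract_properties(tibble::tibble()), "non-empty")
})

test_that("gain and rheobase recovery hold across randomized noiseless presets", {
  withr::with_seed(42, {
    for (i in 1:4) {
      rheo <- runif(1, 150, 450)
      gain <- runif(1, 40, 200)
      tr <- noiseless_truth(rheobase_pa = rheo, gain_hz_na = gain,
                            rin_mohm = runif(1, 40, 150),
                            cm_pf = runif(1, 60, 240))
      sw <- simulate_neuron_sweeps(tr, fast_protocol(max_pa = 800), seed = i)
      pr <- extract_properties(sw)
      expect_lte(pr$rheobase_pa - rheo, 20 + 1e-9)
      expect_gt(pr$rheobase_pa, rheo)
      expect_equal(pr$gain_hz_na, gain, tolerance = 2e-2)
    }
  })
})
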