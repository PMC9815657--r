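test_that("the length command matches the ramp-and-hold protocol", {
  cfg <- spindle_sim_config()
  for (amp in cfg$amplitudes) {
    tr <- simulate_stretch_trial(cfg, amplitude = amp)
    ramp_dur <- tr$events[["ramp_end"]] - tr$events[["ramp_start"]]
    # 2.5 / 5 / 7.5% Lo at 40% Lo/s -> 62.5 / 125 / 187.5 ms ramps
    expect_equal(ramp_dur, amp / 0.40, tolerance = 1e-9)
    expect_equal(max(tr$channels$length), amp, tolerance = 1e-6)
  }
  expect_error(spindle_sim_config(amplitudes = 0.5), "0.2")
  expect_error(spindle_sim_config(ramp_speed = 0), "ramp_speed")
})

test_that("a rate-free configuration gives a homogeneous train", {
  tr <- simulate_stretch_trial(
    spindle_sim_config(rd_hz = 5, k_dyn = 0, k_static = 0), amplitude = 0.05
  )
  isi <- diff(tr$spike_times_s)
  expect_equal(unique(round(1 / isi, 6)), 5)
  m <- ramp_hold_metrics(tr)
  expect_equal(m$rd_hz, 5, tolerance = 0.11)
  expect_equal(m$dp_hz, 5, tolerance = 1e-6)
  expect_equal(m$sr_hz, 5, tolerance = 1e-6)
  expect_equal(m$di_hz, 0, tolerance = 1e-6)
  expect_equal(m$resting_class, "above")
})

test_that("deterministic spikes integrate the underlying rate", {
  cfg <- spindle_sim_config(rd_hz = 10, k_dyn = 100, k_static = 600)
  tr <- simulate_stretch_trial(cfg, amplitude = 0.05)
  # spike count over any window = integral of r(t) +/- 1
  rate <- tr$rate_true
  for (win in list(c(0, 2), c(2, 2.2), c(2.5, 4), c(0, max(rate$time_s)))) {
    integral <- sum(rate$rate_hz[rate$time_s >= win[1] &
                                   rate$time_s < win[2]]) /
      cfg$sampling_rate_hz
    count <- sum(tr$spike_times_s >= win[1] & tr$spike_times_s < win[2])
    expect_lte(abs(count - integral), 1)
  }
})

test_that("ramp-and-hold metrics recover the generator ground truth", {
  # rd 10; plateau = 10 + 600 * 0.05 = 40; ramp peak = 40 + 100 * 0.4 = 80
  tr <- simulate_stretch_trial(
    spindle_sim_config(rd_hz = 10, k_dyn = 100, k_static = 600),
    amplitude = 0.05
  )
  truth_dp <- max(tr$rate_true$rate_hz)
  expect_equal(truth_dp, 80, tolerance = 1e-2)  # channel-sampling resolution
  m <- ramp_hold_metrics(tr)
  # DP/DI quantization: the reciprocal-ISI estimate of a linearly rising rate
  # lags by one to two ISIs, i.e. up to ~2 * (dr/dt) / DP in rate units
  quant <- 2 * (600 * 0.40) / 80
  expect_lt(abs(m$rd_hz - 10), 0.5)
  expect_lt(abs(m$dp_hz - 80), quant)
  expect_lt(abs(m$sr_hz - 40), 1)
  expect_lt(abs(m$di_hz - 40), quant)
  # resting classification threshold at 2 Hz
  low <- simulate_stretch_trial(
    spindle_sim_config(rd_hz = 1.5, k_dyn = 100, k_static = 600),
    amplitude = 0.05
  )
  expect_equal(ramp_hold_metrics(low)$resting_class, "below")
})

test_that("DP grows with k_dyn and SR with k_static", {
  base <- function(k_dyn = 100, k_static = 600) {
    ramp_hold_metrics(simulate_stretch_trial(
      spindle_sim_config(rd_hz = 10, k_dyn = k_dyn, k_static = k_static),
      amplitude = 0.05
    ))
  }
  dps <- purrr::map_dbl(c(50, 100, 200), ~base(k_dyn = .x)$dp_hz)
  expect_true(all(diff(dps) > 0))
  srs <- purrr::map_dbl(c(300, 600, 900), ~base(k_static = .x)$sr_hz)
  expect_true(all(diff(srs) > 0))
})

test_that("negative underlying rates are clipped with a warning", {
  expect_warning(
    simulate_stretch_trial(
      spindle_sim_config(rd_hz = 0, k_dyn = -500, k_static = -500),
      amplitude = 0.05
    ),
    "clipped"
  )
})

test_that("instantaneous rate is the reciprocal-ISI series", {
  ir <- instantaneous_rate(c(0, 0.1, 0.15))
  expect_equal(ir$rate_hz, c(10, 20))
  expect_equal(nrow(instantaneous_rate(0.5)), 0)
  # count conservation: n spikes -> n - 1 rates
  st <- cumsum(runif(20, 0.01, 0.2))
  expect_equal(nrow(instantaneous_rate(st)), length(st) - 1)
})

test_that("poisson spike model approximates the same rate profile", {
  cfg <- spindle_sim_config(rd_hz = 20, k_dyn = 0, k_static = 0,
                            spike_model = "poisson")
  tr <- simulate_stretch_trial(cfg, amplitude = 0.05, seed = 12)
  dur <- max(tr$channels$time_s)
  expect_equal(length(tr$spike_times_s) / dur, 20, tolerance = 0.25)
  # deterministic given seed
  tr2 <- simulate_stretch_trial(cfg, amplitude = 0.05, seed = 12)
  expect_identical(tr$spike_times_s, tr2$spike_times_s)
})

test_that("k-means detection separates spikes from artifacts and noise", {
  st <- seq(0.5, 9.5, by = 0.45)
  art <- seq(0.7, 9.3, by = 0.5)
  sig <- simulate_afferent_signal(st, 10, snr = 8, artifact_times = art,
                                  artifact_snr = 2.5, seed = 4)
  det <- detect_afferent_spikes_kmeans(sig, 10000)
  expect_equal(length(det), length(st))
  expect_lt(max(purrr::map_dbl(st, ~min(abs(det - .x)))), 1e-3)
  # flat signal: empty train
  expect_length(detect_afferent_spikes_kmeans(rep(0, 1000), 10000), 0)
  # pure noise: at most 1 false event per 10 s (Monte-Carlo, fixed seeds)
  fp <- purrr::map_int(1:5, function(s) {
    suppressWarnings(length(detect_afferent_spikes_kmeans(
      simulate_afferent_signal(numeric(0), 10, seed = s), 10000
    )))
  })
  expect_true(all(fp <= 1))
})

test_that("detector + metrics recover the resting discharge within 0.5 Hz", {
  cfg <- spindle_sim_config(rd_hz = 8, k_dyn = 50, k_static = 300,
                            baseline_s = 10)
  tr <- simulate_stretch_trial(cfg, amplitude = 0.05)
  sig <- simulate_afferent_signal(tr$spike_times_s,
                                  max(tr$channels$time_s), snr = 8, seed = 2)
  det <- detect_afferent_spikes_kmeans(sig, 10000)
  tr_det <- tr
  tr_det$spike_times_s <- det
  m <- ramp_hold_metrics(tr_det)
  expect_lt(abs(m$rd_hz - 8), 0.5)
})

test_that("afferent summaries report counts and proportions per group", {
  withr::with_seed(1, {
    rd <- c(runif(80, 3, 20), runif(20, 0, 1.8))[sample(100)]
    metrics <- tibble::tibble(
      group = "control",
      rd_hz = rd,
      dp_hz = rd + 30, di_hz = 10, sr_hz = rd + 15,
      resting_class = ifelse(rd > 2, "above", "below")
    )
    s <- summarize_afferents(metrics)
    expect_equal(s$proportions$n, 100)
    expect_equal(s$proportions$prop_above, 0.8)
    expect_equal(s$proportions$n_above +
                   s$proportions$n_below, s$proportions$n)
  })
})
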