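# Intrinsic-property extraction from current-clamp sweep sets: spike
# detection, rheobase, firing frequencies, F-I gain, passive properties and
# AHP metrics, composed by extract_properties().

#' Spike detection configuration
#'
#' Spikes are upward crossings of a voltage threshold with a minimum rising
#' slope at the crossing and a refractory lockout. All three are exposed
#' because the underlying acquisition protocols do not fix them.
#'
#' @param threshold_mv Voltage threshold (mV). Default 0 mV.
#' @param slope_mv_ms Minimum dV/dt at the crossing (mV/ms). Default 10.
#' @param lockout_ms Refractory lockout (ms). Default 2.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(threshold_mv = 0, slope_mv_ms = 10,
                             lockout_ms = 2) {
  structure(list(threshold_mv = threshold_mv, slope_mv_ms = slope_mv_ms,
                 lockout_ms = lockout_ms),
            class = "detection_config")
}

#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of `threshold_mv` whose instantaneous dV/dt
#' exceeds `slope_mv_ms`, subject to a refractory lockout. The spike time is
#' the threshold-crossing sample. An empty train is a valid result.
#'
#' @param voltage Numeric voltage series (mV).
#' @param sampling_rate Sampling rate (Hz).
#' @param detection A [detection_config()].
#' @return Numeric vector of spike times (s, relative to the start of the
#'   series), with the detection configuration attached as attribute
#'   `detection`.
#' @examples
#' detect_spikes(rep(-70, 1000), 10000)
#' @export
detect_spikes <- function(voltage, sampling_rate,
                          detection = detection_config()) {
  if (!all(is.finite(voltage))) abort("`voltage` must be finite.")
  n <- length(voltage)
  thr <- detection$threshold_mv
  if (n < 2) return(structure(numeric(0), detection = detection))
  cross <- which(voltage[-n] < thr & voltage[-1] >= thr)
  if (length(cross) > 0) {
    slope <- (voltage[cross + 1] - voltage[cross]) * sampling_rate / 1000
    cross <- cross[slope >= detection$slope_mv_ms]
  }
  if (length(cross) > 1) {
    lock <- detection$lockout_ms / 1000 * sampling_rate
    # sequential lockout: a rejected event does not reset the lockout
    acc <- cross[1]
    kept <- acc
    for (i in cross[-1]) {
      if (i - acc > lock) {
        kept <- c(kept, i)
        acc <- i
      }
    }
    cross <- kept
  }
  structure((cross - 1) / sampling_rate, detection = detection)
}

#' Firing frequencies of a spike train over a current pulse
#'
#' Computes the three standard discharge measures over a square pulse:
#' *instantaneous* firing frequency, the inverse of the interval between the
#' first two spikes; *steady-state* frequency, the mean of reciprocal
#' inter-spike intervals whose midpoints fall in a mid-pulse window (default
#' 0.25-0.75 s); and *mean* frequency, `(count - 1) / (t_last - t_first)` over
#' the full pulse. All are equal for a regular train.
#'
#' @param spike_times Spike times (s) relative to pulse onset.
#' @param step_duration_s Pulse duration (s).
#' @param ss_window Steady-state window (s), default `c(0.25, 0.75)`.
#' @return A one-row tibble: `n_spikes`, `instantaneous_hz` (NA when fewer
#'   than 2 spikes), `steady_state_hz` (NA when no interval midpoint falls in
#'   the window), `mean_hz` (0 when fewer than 2 spikes, by convention).
#' @examples
#' firing_frequencies(c(0.10, 0.20), 1)
#' @export
firing_frequencies <- function(spike_times, step_duration_s = 1,
                               ss_window = c(0.25, 0.75)) {
  st <- sort(spike_times)
  if (any(st < -1e-9) || any(st > step_duration_s + 1e-9)) {
    abort("`spike_times` must lie within [0, step_duration_s].")
  }
  n <- length(st)
  if (n < 2) {
    return(tibble(n_spikes = n, instantaneous_hz = NA_real_,
                  steady_state_hz = NA_real_, mean_hz = 0))
  }
  isi <- diff(st)
  mids <- st[-n] + isi / 2
  in_win <- mids >= ss_window[1] & mids <= ss_window[2]
  tibble(
    n_spikes = n,
    instantaneous_hz = 1 / isi[1],
    steady_state_hz = if (any(in_win)) mean(1 / isi[in_win]) else NA_real_,
    mean_hz = (n - 1) / (st[n] - st[1])
  )
}

# per-sweep detected spike trains (relative to step onset, within the pulse)
sweep_spike_trains <- function(sweeps, detection = detection_config()) {
  purrr::pmap(
    list(sweeps$voltage, sweeps$sampling_rate_hz, sweeps$onset_s,
         sweeps$offset_s),
    function(v, fs, onset, offset) {
      st <- detect_spikes(v, fs, detection)
      st <- st[st >= onset & st < offset] - onset
      st
    }
  )
}

#' Rheobase of a sweep set
#'
#' The smallest step amplitude whose sweep contains at least one detected
#' spike; quantized to the protocol grid by construction. When no sweep spikes
#' up to the protocol ceiling the rheobase is flagged as not reached rather
#' than reported as a number.
#'
#' @param sweeps A `sweep_set`.
#' @param detection A [detection_config()].
#' @return A one-row tibble: `rheobase_pa` (NA when not reached), `reached`.
#' @export
rheobase <- function(sweeps, detection = detection_config()) {
  stopifnot(is.data.frame(sweeps))
  if (is.unsorted(sweeps$amplitude_pa, strictly = TRUE)) {
    abort("sweep amplitudes must be strictly increasing.")
  }
  trains <- sweep_spike_trains(sweeps, detection)
  idx <- which(purrr::map_int(trains, length) > 0)
  if (length(idx) == 0) {
    tibble(rheobase_pa = NA_real_, reached = FALSE)
  } else {
    tibble(rheobase_pa = sweeps$amplitude_pa[min(idx)], reached = TRUE)
  }
}

#' F-I gain from per-sweep firing frequencies
#'
#' Ordinary least-squares slope of firing frequency (Hz) on injected current
#' (nA) over suprathreshold sweeps with a defined frequency; `gain_hz_na` uses
#' the mean frequency, `instantaneous_gain_hz_na` the instantaneous frequency.
#'
#' @param freq_tbl A tibble with columns `amplitude_pa`, `mean_hz`,
#'   `instantaneous_hz`, `n_spikes` (as produced inside
#'   [extract_properties()]). Sweeps with fewer than 2 spikes are excluded:
#'   their frequency is undefined rather than 0.
#' @return A one-row tibble: `gain_hz_na`, `instantaneous_gain_hz_na`,
#'   `n_points`, `defined`.
#' @export
fi_gain <- function(freq_tbl) {
  use <- freq_tbl[freq_tbl$n_spikes >= 2, , drop = FALSE]
  slope <- function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 2) return(NA_real_)
    unname(coef(lm(y[ok] ~ I(use$amplitude_pa[ok] / 1000)))[2])
  }
  tibble(
    gain_hz_na = slope(use$mean_hz),
    instantaneous_gain_hz_na = slope(use$instantaneous_hz),
    n_points = nrow(use),
    defined = nrow(use) >= 2
  )
}

#' Passive membrane properties from subthreshold sweeps
#'
#' Input resistance is the OLS slope of steady-state voltage deflection on
#' injected current over the subthreshold (spike-free) sweeps; the membrane
#' time constant is estimated from the onset relaxation of the largest
#' subthreshold deflection by the area method
#' (`tau = integral of (dV_ss - dV(t)) dt / dV_ss`, exact for a
#' single-exponential charge curve and robust to additive noise); capacitance
#' is `tau / Rin`.
#'
#' @param sweeps A `sweep_set`.
#' @param detection A [detection_config()] used to identify spike-free sweeps.
#' @param ss_fraction Final fraction of the pulse averaged for the
#'   steady-state deflection (default last 20%).
#' @param min_deflection_mv Deflections smaller than this are considered below
#'   the noise floor and flagged undefined.
#' @return A one-row tibble: `input_resistance_mohm`, `tau_ms`,
#'   `capacitance_pf`, `n_subthreshold`, `defined`.
#' @export
passive_properties <- function(sweeps, detection = detection_config(),
                               ss_fraction = 0.2, min_deflection_mv = 1) {
  trains <- sweep_spike_trains(sweeps, detection)
  sub <- which(purrr::map_int(trains, length) == 0)
  undefined <- tibble(input_resistance_mohm = NA_real_, tau_ms = NA_real_,
                      capacitance_pf = NA_real_, n_subthreshold = length(sub),
                      defined = FALSE)
  if (length(sub) < 1) return(undefined)
  meas <- purrr::map_dfr(sub, function(k) {
    v <- sweeps$voltage[[k]]
    fs <- sweeps$sampling_rate_hz[k]
    onset <- sweeps$onset_s[k]
    offset <- sweeps$offset_s[k]
    i_base <- which((seq_along(v) - 1) / fs < onset)
    i_step <- which((seq_along(v) - 1) / fs >= onset &
                      (seq_along(v) - 1) / fs < offset)
    i_ss <- tail(i_step, max(1, round(length(i_step) * ss_fraction)))
    tibble(amplitude_pa = sweeps$amplitude_pa[k],
           v0 = mean(v[i_base]), dv = mean(v[i_ss]) - mean(v[i_base]),
           k = k)
  })
  if (max(abs(meas$dv)) < min_deflection_mv) return(undefined)
  rin <- if (nrow(meas) >= 2) {
    unname(coef(lm(dv ~ amplitude_pa, data = meas))[2]) * 1000
  } else {
    meas$dv / meas$amplitude_pa * 1000
  }
  # area method on the largest-deflection subthreshold sweep
  kk <- meas$k[which.max(abs(meas$dv))]
  row <- meas[which.max(abs(meas$dv)), ]
  v <- sweeps$voltage[[kk]]
  fs <- sweeps$sampling_rate_hz[kk]
  tt <- (seq_along(v) - 1) / fs
  i_step <- which(tt >= sweeps$onset_s[kk] & tt < sweeps$offset_s[kk])
  tau_s <- sum(row$dv - (v[i_step] - row$v0)) / fs / row$dv
  tibble(input_resistance_mohm = rin, tau_ms = tau_s * 1000,
         capacitance_pf = 1000 * tau_s * 1000 / rin,
         n_subthreshold = nrow(meas),
         defined = is.finite(rin) && rin > 0 && tau_s > 0)
}

#' Afterhyperpolarization metrics around one spike
#'
#' Measures the AHP following an isolated spike: `amplitude` is baseline minus
#' the post-spike trough (baseline taken just before the spike);
#' `half_width` the duration spent below baseline minus half the amplitude;
#' `half_decay` the time from the trough back to half recovery. Metrics are
#' flagged undefined when a following spike intrudes before half recovery or
#' when no hyperpolarization below baseline is seen.
#'
#' @param voltage Voltage series (mV).
#' @param sampling_rate Sampling rate (Hz).
#' @param spike_time Spike time (s, relative to series start).
#' @param next_spike_time Optional time of the following spike; the search is
#'   truncated there.
#' @param search_ms Post-spike search window for the trough (ms).
#' @param baseline_ms Window `[spike - baseline_ms[1], spike - baseline_ms[2]]`
#'   averaged for the baseline (ms before the spike).
#' @return One-row tibble: `ahp_amplitude_mv`, `ahp_half_width_ms`,
#'   `ahp_half_decay_ms`, `defined`.
#' @export
ahp_metrics <- function(voltage, sampling_rate, spike_time,
                        next_spike_time = NULL, search_ms = 100,
                        baseline_ms = c(6, 1)) {
  n <- length(voltage)
  i_spk <- round(spike_time * sampling_rate) + 1
  i0 <- max(1, i_spk - round(baseline_ms[1] / 1000 * sampling_rate))
  i1 <- max(1, i_spk - round(baseline_ms[2] / 1000 * sampling_rate))
  baseline <- mean(voltage[i0:i1])
  i_end <- min(n, i_spk + round(search_ms / 1000 * sampling_rate))
  if (!is.null(next_spike_time)) {
    i_end <- min(i_end, round(next_spike_time * sampling_rate))
  }
  # skip the spike waveform itself: start after the peak
  seg <- (i_spk + 1):i_end
  i_peak <- seg[which.max(voltage[seg])]
  seg <- seg[seg > i_peak]
  if (length(seg) < 2) {
    return(tibble(ahp_amplitude_mv = NA_real_, ahp_half_width_ms = NA_real_,
                  ahp_half_decay_ms = NA_real_, defined = FALSE))
  }
  i_tr <- seg[which.min(voltage[seg])]
  amp <- baseline - voltage[i_tr]
  if (!is.finite(amp) || amp <= 0) {
    return(tibble(ahp_amplitude_mv = 0, ahp_half_width_ms = NA_real_,
                  ahp_half_decay_ms = NA_real_, defined = FALSE))
  }
  half <- baseline - amp / 2
  below <- which(voltage[seg] < half)
  first_below <- seg[min(below)]
  after_tr <- seg[seg >= i_tr]
  rec <- after_tr[voltage[after_tr] >= half]
  if (length(rec) == 0) {
    # trough found but recovery truncated (next spike or window end)
    return(tibble(ahp_amplitude_mv = amp, ahp_half_width_ms = NA_real_,
                  ahp_half_decay_ms = NA_real_, defined = FALSE))
  }
  i_rec <- min(rec)
  tibble(
    ahp_amplitude_mv = amp,
    ahp_half_width_ms = (i_rec - first_below) / sampling_rate * 1000,
    ahp_half_decay_ms = (i_rec - i_tr) / sampling_rate * 1000,
    defined = TRUE
  )
}

#' Extract the full intrinsic-property signature of one neuron
#'
#' Composes spike detection, rheobase, firing frequencies, F-I gains, passive
#' properties and AHP metrics into the per-neuron biophysical signature.
#' Firing frequencies are reported at `ff_current_pa` (by default the
#' neuron's calibration reference current if recorded with the sweep set,
#' otherwise the largest-amplitude sweep). AHP metrics are measured on the
#' first spike of the lowest suprathreshold sweep, where spikes are well
#' isolated. Undefined quantities are NA with their `*_defined` flags.
#'
#' @param sweeps A `sweep_set`.
#' @param detection A [detection_config()]; recorded in the result for
#'   provenance.
#' @param ff_current_pa Current step (pA) at which the reported firing
#'   frequencies are measured.
#' @return A one-row tibble with the intrinsic-property signature.
#' @examples
#' sw <- simulate_neuron_sweeps(
#'   neuron_truth(230, 100, 100, 100, noise_sd_mv = 0),
#'   step_protocol(max_pa = 400, sampling_rate_hz = 10000), seed = 1
#' )
#' extract_properties(sw)
#' @export
extract_properties <- function(sweeps, detection = detection_config(),
                               ff_current_pa = NULL) {
  if (!is.data.frame(sweeps) || nrow(sweeps) == 0) {
    abort("`sweeps` must be a non-empty sweep_set.")
  }
  trains <- sweep_spike_trains(sweeps, detection)
  counts <- purrr::map_int(trains, length)
  dur <- sweeps$offset_s - sweeps$onset_s
  freq_tbl <- purrr::map_dfr(seq_len(nrow(sweeps)), function(k) {
    firing_frequencies(trains[[k]], dur[k])
  })
  freq_tbl$amplitude_pa <- sweeps$amplitude_pa
  rheo <- rheobase(sweeps, detection)
  if (is.null(ff_current_pa)) {
    truth <- attr(sweeps, "truth")
    ff_current_pa <- if (!is.null(truth) && is.finite(truth$ref_current_pa)) {
      truth$ref_current_pa
    } else {
      max(sweeps$amplitude_pa)
    }
  }
  k_ff <- which.min(abs(sweeps$amplitude_pa - ff_current_pa))
  gain <- fi_gain(freq_tbl)
  passive <- passive_properties(sweeps, detection)
  ahp <- tibble(ahp_amplitude_mv = NA_real_, ahp_half_width_ms = NA_real_,
                ahp_half_decay_ms = NA_real_, defined = FALSE)
  if (rheo$reached) {
    k_low <- min(which(counts > 0))
    st <- trains[[k_low]] + sweeps$onset_s[k_low]
    ahp <- ahp_metrics(sweeps$voltage[[k_low]], sweeps$sampling_rate_hz[k_low],
                       st[1], next_spike_time = if (length(st) > 1) st[2])
  }
  tibble(
    neuron_id = sweeps$neuron_id[1],
    group = sweeps$group[1],
    rheobase_pa = rheo$rheobase_pa,
    rheobase_reached = rheo$reached,
    ff_current_pa = sweeps$amplitude_pa[k_ff],
    instantaneous_ff_hz = freq_tbl$instantaneous_hz[k_ff],
    steady_state_ff_hz = freq_tbl$steady_state_hz[k_ff],
    mean_ff_hz = freq_tbl$mean_hz[k_ff],
    gain_hz_na = gain$gain_hz_na,
    instantaneous_gain_hz_na = gain$instantaneous_gain_hz_na,
    gain_defined = gain$defined,
    input_resistance_mohm = passive$input_resistance_mohm,
    capacitance_pf = passive$capacitance_pf,
    membrane_tau_ms = passive$tau_ms,
    passive_defined = passive$defined,
    ahp_amplitude_mv = ahp$ahp_amplitude_mv,
    ahp_half_width_ms = ahp$ahp_half_width_ms,
    ahp_half_decay_ms = ahp$ahp_half_decay_ms,
    ahp_defined = ahp$defined,
    detection_threshold_mv = detection$threshold_mv,
    detection_slope_mv_ms = detection$slope_mv_ms,
    detection_lockout_ms = detection$lockout_ms
  )
}

#' Simulate and extract a calibrated cohort
#'
#' Draws `n` jittered ground truths around a preset ([cohort_truth()]),
#' simulates each neuron's sweep set under the preset's step protocol, and
#' extracts its intrinsic-property signature. Traces are generated and
#' discarded one neuron at a time.
#'
#' @inheritParams cohort_truth
#' @param protocol Optional [step_protocol()]; defaults to 20 pA steps up to
#'   the preset's current ceiling.
#' @param detection A [detection_config()].
#' @return A tibble with one signature row per neuron ([extract_properties()])
#'   joined with the ground-truth columns (prefixed `true_`).
#' @examples
#' \donttest{
#' extract_cohort("gamma_control", n = 3, seed = 1)
#' }
#' @export
extract_cohort <- function(preset, n, seed = 1, jitter_cv = NULL,
                           protocol = NULL, detection = detection_config()) {
  truths <- cohort_truth(preset, n, seed = seed, jitter_cv = jitter_cv)
  preset_truth <- attr(truths, "preset_truth")
  if (is.null(protocol)) {
    protocol <- step_protocol(max_pa = preset_truth$protocol_max_pa)
  }
  res <- purrr::map_dfr(seq_len(n), function(i) {
    row <- truths[i, ]
    sw <- simulate_neuron_sweeps(row_to_truth(row), protocol,
                                 seed = seed * 10000 + i,
                                 neuron_id = row$neuron_id,
                                 group = row$preset)
    extract_properties(sw, detection,
                       ff_current_pa = preset_truth$ref_current_pa)
  })
  truth_cols <- truths |>
    dplyr::select("neuron_id", true_rheobase_pa = "rheobase_pa",
                  true_gain_hz_na = "gain_hz_na", true_rin_mohm = "rin_mohm",
                  true_cm_pf = "cm_pf", true_ahp_amp_mv = "ahp_amp_mv",
                  true_ahp_tau_ms = "ahp_tau_ms")
  dplyr::left_join(res, truth_cols, by = "neuron_id")
}
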