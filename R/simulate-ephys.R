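# Phenomenological current-clamp generator: first-order RC subthreshold
# dynamics plus template spikes at the rate given by a piecewise-linear F-I
# law, so every extracted feature has an analytically known ground truth.

#' Square current-step stimulation protocol
#'
#' Describes a ladder of square current pulses as used for F-I curve
#' characterization: 20 pA increments, 1000 ms pulses, with a stated current
#' ceiling (1 nA for gamma-range, 3 nA for alpha-range recordings).
#'
#' @param max_pa Largest step amplitude (pA).
#' @param by_pa Step increment (pA); the amplitude ladder is
#'   `seq(by_pa, max_pa, by = by_pa)`.
#' @param amplitudes_pa Optional explicit strictly increasing amplitude ladder
#'   (pA), overriding `max_pa`/`by_pa`.
#' @param step_duration_s Pulse duration (s).
#' @param pre_s,post_s Baseline durations before and after the pulse (s).
#' @param sampling_rate_hz Sampling rate (Hz); must be at least 10 kHz so that
#'   2 ms spike waveforms are resolved.
#' @return A list of class `step_protocol`.
#' @examples
#' step_protocol(max_pa = 1000)
#' @export
step_protocol <- function(max_pa = 1000, by_pa = 20, amplitudes_pa = NULL,
                          step_duration_s = 1, pre_s = 0.25, post_s = 0.25,
                          sampling_rate_hz = 20000) {
  if (is.null(amplitudes_pa)) {
    amplitudes_pa <- seq(by_pa, max_pa, by = by_pa)
  }
  if (length(amplitudes_pa) < 1 || any(diff(amplitudes_pa) <= 0)) {
    abort("`amplitudes_pa` must be strictly increasing.")
  }
  assert_scalar_number(step_duration_s, "step_duration_s", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(pre_s, "pre_s", lower = 0)
  assert_scalar_number(post_s, "post_s", lower = 0)
  if (sampling_rate_hz < 10000) {
    abort("`sampling_rate_hz` must be >= 10 kHz to resolve 1-2 ms spikes.")
  }
  structure(
    list(amplitudes_pa = amplitudes_pa, step_duration_s = step_duration_s,
         pre_s = pre_s, post_s = post_s, sampling_rate_hz = sampling_rate_hz,
         by_pa = if (length(amplitudes_pa) > 1) min(diff(amplitudes_pa)) else amplitudes_pa),
    class = "step_protocol"
  )
}

# ground-truth spike times for one step, relative to sweep start.
# First-spike latency min(0.5/f, 0.1 s) after onset, then regular 1/f spacing;
# the regular spacing makes instantaneous, steady-state and mean firing
# frequency all equal f exactly.
truth_spike_times <- function(f, onset, duration) {
  if (f <= 0) return(numeric(0))
  t1 <- onset + min(0.5 / f, 0.1)
  if (t1 >= onset + duration) return(numeric(0))
  seq(t1, onset + duration - 1e-9, by = 1 / f)
}

#' Simulate a current-clamp sweep set for one neuron
#'
#' Generates one voltage trace per protocol step. Subthreshold segments follow
#' first-order RC relaxation with resistance `rin_mohm` and time constant
#' `tau_ms = rin_mohm * cm_pf / 1000`; the depolarization is capped at the
#' rheobase level for suprathreshold steps (the membrane spikes instead of
#' depolarizing further). For `I > rheobase`, stereotyped 2 ms biphasic spike
#' waveforms (peak +40 mV) are inserted at regular intervals of
#' `1/f(I)` with `f(I) = gain * (I - rheobase)` (currents in nA), each followed
#' by a single-exponential afterhyperpolarization of amplitude `ahp_amp_mv`
#' and decay constant `ahp_tau_ms`. Additive Gaussian noise of SD
#' `noise_sd_mv` completes the trace. Identical `(truth, protocol, seed)`
#' yield bit-identical sweep sets.
#'
#' @param truth A one-row `neuron_truth` tibble ([calibrate_preset()],
#'   [neuron_truth()]).
#' @param protocol A [step_protocol()].
#' @param seed Integer seed.
#' @param neuron_id,group Identifiers stored with the sweep set.
#' @return A tibble of class `sweep_set`: one row per sweep with columns
#'   `neuron_id`, `group`, `amplitude_pa`, `onset_s`, `offset_s`,
#'   `sampling_rate_hz`, and `voltage` (list-column of mV series). The ground
#'   truth and protocol are attached as attributes `truth` and `protocol`;
#'   ground-truth spike times per sweep as attribute `spike_times`.
#' @examples
#' sw <- simulate_neuron_sweeps(
#'   calibrate_preset("gamma_control"),
#'   step_protocol(max_pa = 400, sampling_rate_hz = 10000), seed = 1
#' )
#' sw
#' @export
simulate_neuron_sweeps <- function(truth, protocol = step_protocol(),
                                   seed = 1, neuron_id = "n1",
                                   group = truth$preset) {
  stopifnot(inherits(truth, "neuron_truth"), inherits(protocol, "step_protocol"))
  fs <- protocol$sampling_rate_hz
  dt <- 1 / fs
  onset <- protocol$pre_s
  dur <- protocol$step_duration_s
  offset <- onset + dur
  n_total <- round((protocol$pre_s + dur + protocol$post_s) * fs)
  tt <- (seq_len(n_total) - 1) * dt
  v_rest <- -70
  tau_s <- truth$tau_ms / 1000
  rheo <- truth$rheobase_pa
  spike_ms <- 2
  n_spike <- round(spike_ms / 1000 * fs)
  if (n_spike < 4) {
    abort("Sampling too coarse to place 2 ms spike waveforms.")
  }
  # biphasic template shape on [0, 1]: rise to peak in the first 30%, fall to
  # the AHP trough over the remainder (expressed as interpolation weights)
  frac <- seq_len(n_spike) / n_spike
  up <- pmin(frac / 0.3, 1)
  down <- pmax((frac - 0.3) / 0.7, 0)
  spikes_list <- vector("list", length(protocol$amplitudes_pa))
  withr::with_seed(seed, {
    sweeps <- purrr::map(seq_along(protocol$amplitudes_pa), function(k) {
      amp <- protocol$amplitudes_pa[k]
      dv <- min(amp, rheo) * truth$rin_mohm / 1000  # mV, capped at rheobase
      v <- rep(v_rest, n_total)
      step_idx <- tt >= onset & tt < offset
      v[step_idx] <- v_rest + dv * (1 - exp(-(tt[step_idx] - onset) / tau_s))
      v_end <- v_rest + dv * (1 - exp(-dur / tau_s))
      post_idx <- tt >= offset
      v[post_idx] <- v_rest + (v_end - v_rest) * exp(-(tt[post_idx] - offset) / tau_s)
      f <- truth$gain_hz_na * (amp - rheo) / 1000
      st <- truth_spike_times(f, onset, dur)
      spikes_list[[k]] <<- st
      if (length(st) > 0) {
        idx0 <- pmin(round(st * fs) + 1L, n_total - n_spike)
        bounds <- c(idx0, n_total + 1L)
        for (j in seq_along(idx0)) {
          i0 <- idx0[j]
          seg <- i0:(i0 + n_spike - 1L)
          base_seg <- v[seg]
          peak <- 40
          wave <- base_seg + (peak - base_seg) * up
          trough <- base_seg - truth$ahp_amp_mv
          wave <- wave * (1 - down) + trough * down
          v[seg] <- wave
          # AHP tail: exponential recovery until the next spike (or trace end)
          a0 <- i0 + n_spike
          a1 <- bounds[j + 1L] - 1L
          if (a0 <= a1) {
            ta <- (seq(a0, a1) - a0 + 1) * dt
            v[a0:a1] <- v[a0:a1] - truth$ahp_amp_mv * exp(-ta / (truth$ahp_tau_ms / 1000))
          }
        }
      }
      if (truth$noise_sd_mv > 0) {
        v <- v + stats::rnorm(n_total, sd = truth$noise_sd_mv)
      }
      v
    })
  })
  out <- tibble(
    neuron_id = neuron_id,
    group = group,
    amplitude_pa = protocol$amplitudes_pa,
    onset_s = onset,
    offset_s = offset,
    sampling_rate_hz = fs,
    voltage = sweeps
  )
  attr(out, "truth") <- truth
  attr(out, "protocol") <- protocol
  attr(out, "spike_times") <- spikes_list
  class(out) <- c("sweep_set", class(out))
  out
}

#' Draw a jittered cohort of ground truths around a preset
#'
#' Each neuron's rheobase, gain, input resistance, capacitance and AHP
#' parameters are drawn log-normally around the preset mean with coefficient
#' of variation `jitter_cv` (mean-preserving), so simulated cohorts have
#' nontrivial population SEMs while individual ground truths stay exact.
#'
#' @param preset Preset name (see [calibrate_preset()]) or a `neuron_truth`.
#' @param n Number of neurons.
#' @param seed Integer seed.
#' @param jitter_cv Coefficient of variation; defaults to the preset's value.
#' @return A tibble with one `neuron_truth`-compatible row per neuron plus a
#'   `neuron_id` column; attribute `preset_truth` carries the preset means.
#' @export
cohort_truth <- function(preset, n, seed = 1, jitter_cv = NULL) {
  truth <- if (inherits(preset, "neuron_truth")) preset else calibrate_preset(preset)
  cv <- jitter_cv %||% truth$jitter_cv
  jittered <- withr::with_seed(seed, {
    purrr::map(c("rheobase_pa", "gain_hz_na", "rin_mohm", "cm_pf",
                 "ahp_amp_mv", "ahp_tau_ms"),
               function(f) rlnorm_cv(n, truth[[f]], cv))
  })
  names(jittered) <- c("rheobase_pa", "gain_hz_na", "rin_mohm", "cm_pf",
                       "ahp_amp_mv", "ahp_tau_ms")
  out <- tibble(
    neuron_id = sprintf("%s_%02d", truth$preset, seq_len(n)),
    preset = truth$preset,
    !!!jittered,
    tau_ms = jittered$rin_mohm * jittered$cm_pf / 1000,
    noise_sd_mv = truth$noise_sd_mv,
    ref_current_pa = truth$ref_current_pa,
    protocol_max_pa = truth$protocol_max_pa
  )
  attr(out, "preset_truth") <- truth
  out
}

# one-row cohort tibble -> neuron_truth object
row_to_truth <- function(row) {
  neuron_truth(
    rheobase_pa = row$rheobase_pa, gain_hz_na = row$gain_hz_na,
    rin_mohm = row$rin_mohm, cm_pf = row$cm_pf,
    ahp_amp_mv = row$ahp_amp_mv, ahp_tau_ms = row$ahp_tau_ms,
    noise_sd_mv = row$noise_sd_mv, jitter_cv = 0,
    ref_current_pa = row$ref_current_pa
  )
}
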