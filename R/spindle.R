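# Muscle-spindle afferent analysis: ramp-and-hold stretch simulation with a
# known underlying rate, k-means spike detection from raw extracellular
# signal, instantaneous-rate estimation, and the classical ramp-and-hold
# metrics RD / DP / DI / SR.

#' Spindle stretch simulation configuration
#'
#' Parameters of the rate model
#' `r(t) = rd + k_dyn * max(dL/dt, 0) + k_static * dL(t)` driven by a
#' ramp-and-hold length command: baseline at resting length Lo, linear ramp
#' at `ramp_speed` (fraction of Lo per second) to `amplitude` (fraction of
#' Lo), hold, and return.
#'
#' @param rd_hz Resting discharge rate (Hz), >= 0.
#' @param k_dyn Rate gain per unit lengthening velocity (Hz per Lo/s).
#' @param k_static Rate gain per unit length change (Hz per Lo).
#' @param amplitudes Stretch amplitudes as fractions of Lo; the protocol
#'   default is 2.5%, 5% and 7.5% Lo.
#' @param ramp_speed Ramp speed (fraction of Lo per second), default 0.40.
#' @param baseline_s Pre-ramp baseline duration (s), default 2.
#' @param hold_s Hold duration (s), default 3 (long enough for the default
#'   static-response window).
#' @param post_s Post-return duration (s).
#' @param sampling_rate_hz Channel sampling rate (Hz).
#' @param spike_model `"deterministic"` (integrate-to-threshold of `r(t)`,
#'   default) or `"poisson"` (inhomogeneous Poisson).
#' @return A list of class `spindle_sim_config`.
#' @export
spindle_sim_config <- function(rd_hz = 10, k_dyn = 100, k_static = 600,
                               amplitudes = c(0.025, 0.05, 0.075),
                               ramp_speed = 0.40, baseline_s = 2,
                               hold_s = 3, post_s = 1,
                               sampling_rate_hz = 2000,
                               spike_model = c("deterministic", "poisson")) {
  spike_model <- match.arg(spike_model)
  assert_scalar_number(rd_hz, "rd_hz", lower = 0)
  assert_scalar_number(ramp_speed, "ramp_speed", lower = 0,
                       strict_lower = TRUE)
  if (any(amplitudes <= 0 | amplitudes > 0.2)) {
    abort("`amplitudes` must lie in (0, 0.2] (fractions of Lo).")
  }
  structure(list(rd_hz = rd_hz, k_dyn = k_dyn, k_static = k_static,
                 amplitudes = amplitudes, ramp_speed = ramp_speed,
                 baseline_s = baseline_s, hold_s = hold_s, post_s = post_s,
                 sampling_rate_hz = sampling_rate_hz,
                 spike_model = spike_model),
            class = "spindle_sim_config")
}

#' Simulate one ramp-and-hold stretch trial
#'
#' Builds the length command (baseline, linear ramp at `ramp_speed` to
#' `amplitude`, hold, linear return), evaluates the underlying afferent rate
#' `r(t) = rd + k_dyn * max(dL/dt, 0) + k_static * dL(t)` (negative values
#' clipped to 0 with a warning), and draws spikes either by deterministic
#' integrate-to-threshold of `r(t)` (a spike at each half-integer crossing of
#' the integrated rate, so a constant rate `r` yields exactly `r` spikes per
#' second) or as an inhomogeneous Poisson process. The tension
#' channel is an affine function of length (displayed, not analyzed).
#'
#' @param config A [spindle_sim_config()].
#' @param amplitude Stretch amplitude for this trial (fraction of Lo);
#'   defaults to the first configured amplitude.
#' @param seed Integer seed (used by the Poisson model; the deterministic
#'   model is seed-independent).
#' @return An object of class `stretch_trial`: list with `channels` (tibble
#'   `time_s`, `length`, `tension`), `spike_times_s`, `rate_true` (tibble
#'   `time_s`, `rate_hz`), `events` (named vector `ramp_start`, `ramp_end`,
#'   `hold_end`), `amplitude`, `ramp_speed`, `config`.
#' @examples
#' trial <- simulate_stretch_trial(spindle_sim_config(), amplitude = 0.05)
#' ramp_hold_metrics(trial)
#' @export
simulate_stretch_trial <- function(config = spindle_sim_config(),
                                   amplitude = config$amplitudes[1],
                                   seed = 1) {
  stopifnot(inherits(config, "spindle_sim_config"))
  assert_scalar_number(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  fs <- config$sampling_rate_hz
  ramp_dur <- amplitude / config$ramp_speed
  t_ramp <- config$baseline_s
  t_hold <- t_ramp + ramp_dur
  t_rel <- t_hold + config$hold_s
  t_end <- t_rel + ramp_dur + config$post_s
  tt <- seq(0, t_end, by = 1 / fs)
  dl <- numeric(length(tt))
  ramp_idx <- tt >= t_ramp & tt < t_hold
  dl[ramp_idx] <- (tt[ramp_idx] - t_ramp) * config$ramp_speed
  dl[tt >= t_hold & tt < t_rel] <- amplitude
  rel_idx <- tt >= t_rel & tt < t_rel + ramp_dur
  dl[rel_idx] <- amplitude - (tt[rel_idx] - t_rel) * config$ramp_speed
  vel <- numeric(length(tt))
  vel[ramp_idx] <- config$ramp_speed
  rate <- config$rd_hz + config$k_dyn * pmax(vel, 0) + config$k_static * dl
  if (any(rate < 0)) {
    warn(sprintf("Underlying rate negative on %.1f%% of samples; clipped to 0.",
                 100 * mean(rate < 0)))
    rate <- pmax(rate, 0)
  }
  cum <- cumsum(rate) / fs  # integrated rate
  spikes <- if (config$spike_model == "deterministic") {
    integer_crossings(tt, cum)
  } else {
    withr::with_seed(seed, {
      # time-rescaling: unit-rate exponential waiting times on the
      # integrated-rate axis, mapped back through the inverse of cum
      targets <- cumsum(stats::rexp(ceiling(max(cum)) + 10))
      targets <- targets[targets < max(cum)]
      stats::approx(cum, tt, xout = targets, ties = "ordered")$y
    })
  }
  channels <- tibble(time_s = tt, length = dl,
                     tension = 2 + 50 * dl)  # affine placeholder channel
  structure(
    list(channels = channels, spike_times_s = spikes,
         rate_true = tibble(time_s = tt, rate_hz = rate),
         events = c(ramp_start = t_ramp, ramp_end = t_hold, hold_end = t_rel),
         amplitude = amplitude, ramp_speed = config$ramp_speed,
         config = config),
    class = "stretch_trial"
  )
}

# spike times where the integrated rate crosses successive thresholds
# (midpoint convention: 0.5, 1.5, ... so a constant rate r yields exactly
# r spikes per unit time with the first spike at 1/(2r))
integer_crossings <- function(tt, cum) {
  targets <- seq_len(floor(max(cum) + 0.5)) - 0.5
  if (length(targets) == 0) return(numeric(0))
  stats::approx(cum, tt, xout = targets, ties = "ordered")$y
}

#' Simulate a series of ramp-and-hold trials
#'
#' Applies the configured protocol (each amplitude repeated `n_reps` times,
#' 3 x 3 by default, giving the standard series of 9 stretches).
#'
#' @param config A [spindle_sim_config()].
#' @param n_reps Repetitions per amplitude.
#' @param seed Integer seed.
#' @return A list of `stretch_trial` objects.
#' @export
simulate_stretch_series <- function(config = spindle_sim_config(),
                                    n_reps = 3, seed = 1) {
  grid <- expand.grid(rep = seq_len(n_reps), amplitude = config$amplitudes)
  purrr::map(seq_len(nrow(grid)), function(i) {
    simulate_stretch_trial(config, amplitude = grid$amplitude[i],
                           seed = seed * 100 + i)
  })
}

#' Instantaneous firing rate from spike times
#'
#' Reciprocal inter-spike-interval series, each rate assigned to the interval's
#' end spike.
#'
#' @param spike_times Spike times (s), strictly increasing.
#' @return A tibble `time_s` (end spike of each interval), `rate_hz`. Empty
#'   when fewer than 2 spikes.
#' @examples
#' instantaneous_rate(c(0, 0.1, 0.15))
#' @export
instantaneous_rate <- function(spike_times) {
  st <- sort(spike_times)
  if (length(st) < 2) return(tibble(time_s = numeric(0), rate_hz = numeric(0)))
  tibble(time_s = st[-1], rate_hz = 1 / diff(st))
}

# instantaneous rate at one time point: reciprocal of the ISI containing it
rate_at <- function(spike_times, t) {
  st <- sort(spike_times)
  if (length(st) < 2) return(NA_real_)
  i <- findInterval(t, st)
  if (i < 1 || i >= length(st)) return(NA_real_)
  1 / (st[i + 1] - st[i])
}

#' Ramp-and-hold afferent metrics
#'
#' The four classical measures of a spindle afferent's ramp-and-hold
#' response: resting discharge `RD` (spike count over the pre-ramp baseline
#' divided by its duration), dynamic peak `DP` (maximum instantaneous rate
#' during the ramp), dynamic index `DI` (DP minus the instantaneous rate
#' `di_delay` = 0.5 s after ramp end), and static response `SR` (mean of
#' reciprocal inter-spike intervals whose midpoints fall in a plateau window,
#' by default 1.0-2.0 s after ramp end). Afferents are classed by whether the
#' resting discharge exceeds 2 Hz.
#'
#' @param trial A `stretch_trial` (or any list with `spike_times_s` and
#'   `events`).
#' @param sr_window Static-response window relative to ramp end (s).
#' @param di_delay Reference delay after ramp end for the dynamic index (s).
#' @param threshold_hz Resting-discharge classification threshold (Hz).
#' @return One-row tibble: `rd_hz`, `dp_hz`, `di_hz`, `sr_hz`,
#'   `resting_class` (`"above"`/`"below"` threshold), `n_spikes`, plus
#'   `*_defined` flags for windows with too few spikes (`rd_hz = 0` is valid
#'   and classes as below threshold).
#' @export
ramp_hold_metrics <- function(trial, sr_window = c(1, 2), di_delay = 0.5,
                              threshold_hz = 2) {
  st <- sort(trial$spike_times_s)
  ev <- trial$events
  baseline_dur <- ev[["ramp_start"]]
  rd <- sum(st < ev[["ramp_start"]]) / baseline_dur
  ir <- instantaneous_rate(st)
  # intervals overlapping the ramp: for sparse trains the rate prevailing
  # during the ramp may come from an interval straddling its bounds
  if (nrow(ir) > 0) {
    isi_start <- st[-length(st)]
    in_ramp <- isi_start <= ev[["ramp_end"]] & ir$time_s >= ev[["ramp_start"]]
  } else {
    in_ramp <- logical(0)
  }
  dp <- if (any(in_ramp)) max(ir$rate_hz[in_ramp]) else NA_real_
  r_ref <- rate_at(st, ev[["ramp_end"]] + di_delay)
  di <- dp - r_ref
  # plateau rate: reciprocal ISIs whose midpoints fall inside the window
  if (length(st) >= 2) {
    mids <- st[-length(st)] + diff(st) / 2
    w0 <- ev[["ramp_end"]] + sr_window[1]
    w1 <- ev[["ramp_end"]] + sr_window[2]
    in_w <- mids >= w0 & mids <= w1
    sr <- if (any(in_w)) mean(1 / diff(st)[in_w]) else NA_real_
  } else {
    sr <- NA_real_
  }
  tibble(
    rd_hz = rd,
    dp_hz = dp,
    di_hz = di,
    sr_hz = sr,
    resting_class = ifelse(rd > threshold_hz, "above", "below"),
    n_spikes = length(st),
    dp_defined = is.finite(dp),
    di_defined = is.finite(di),
    sr_defined = is.finite(sr)
  )
}

#' Summarize afferent metrics by group
#'
#' Per-group counts and proportions of afferents firing above/below the
#' resting-discharge threshold, plus group mean and SEM of each metric.
#'
#' @param metrics A tibble of [ramp_hold_metrics()] rows with a `group`
#'   column.
#' @param group_col Name of the group column.
#' @return A list of class `afferent_summary` with `proportions` (tibble:
#'   `group`, `n`, `n_above`, `n_below`, `prop_above`) and `metrics` (tibble
#'   of per-group mean and SEM of RD/DP/DI/SR).
#' @export
summarize_afferents <- function(metrics, group_col = "group") {
  stopifnot(group_col %in% names(metrics))
  props <- metrics |>
    group_by(group = .data[[group_col]]) |>
    summarise(n = dplyr::n(),
              n_above = sum(.data$resting_class == "above"),
              n_below = sum(.data$resting_class == "below"),
              prop_above = .data$n_above / dplyr::n(),
              .groups = "drop")
  mets <- metrics |>
    group_by(group = .data[[group_col]]) |>
    summarise(across(c("rd_hz", "dp_hz", "di_hz", "sr_hz"),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sem = ~sem(.x[is.finite(.x)]))),
              .groups = "drop")
  structure(list(proportions = props, metrics = mets),
            class = "afferent_summary")
}

# --- raw-signal spike detection ---------------------------------------------

#' Simulate an extracellular afferent signal
#'
#' Renders a spike train as a raw extracellular trace: a stereotyped biphasic
#' waveform per spike scaled to `snr` times the noise SD, optional smaller
#' artifact events, and white Gaussian noise. Used to exercise the raw-signal
#' spike detector against a known ground truth.
#'
#' @param spike_times Spike times (s).
#' @param duration_s Total duration (s).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param snr Spike peak amplitude in noise-SD units.
#' @param artifact_times Optional artifact event times (s).
#' @param artifact_snr Artifact peak amplitude in noise-SD units.
#' @param noise_sd Noise SD (a.u.).
#' @param seed Integer seed.
#' @return Numeric signal vector of length `duration_s * sampling_rate_hz`.
#' @export
simulate_afferent_signal <- function(spike_times, duration_s,
                                     sampling_rate_hz = 10000, snr = 8,
                                     artifact_times = NULL,
                                     artifact_snr = 2.5, noise_sd = 1,
                                     seed = 1) {
  n <- round(duration_s * sampling_rate_hz)
  wave_ms <- 1.2
  nw <- max(6, round(wave_ms / 1000 * sampling_rate_hz))
  ph <- seq(0, 2 * pi, length.out = nw)
  wave <- sin(ph) * exp(-3 * (seq_len(nw) - 1) / nw)  # biphasic, decaying
  wave <- wave / max(wave)
  add_events <- function(sig, times, amp) {
    for (s in times) {
      i0 <- round(s * sampling_rate_hz) + 1
      if (i0 + nw - 1 <= n && i0 >= 1) {
        sig[i0:(i0 + nw - 1)] <- sig[i0:(i0 + nw - 1)] + amp * wave
      }
    }
    sig
  }
  withr::with_seed(seed, {
    sig <- stats::rnorm(n, sd = noise_sd)
    sig <- add_events(sig, spike_times, snr * noise_sd)
    if (!is.null(artifact_times)) {
      sig <- add_events(sig, artifact_times, artifact_snr * noise_sd)
    }
    sig
  })
}

#' K-means spike detection from a raw extracellular signal
#'
#' Candidate events are upward crossings of an amplitude threshold (a
#' multiple of the robust noise SD, estimated by the median absolute
#' deviation). Each candidate is described by three waveform features (peak
#' amplitude, trough amplitude, width at half peak) and the candidates are
#' partitioned by 2-means clustering; the cluster with the larger mean peak
#' amplitude is labelled "spike". When the two cluster centers are separated
#' by less than `min_separation` noise SDs the candidates form a single
#' homogeneous event type, which is accepted as a unit only if its mean peak
#' clearly exceeds the candidate threshold (threshold-crossing noise peaks
#' concentrate just above it); otherwise an empty train is returned (no unit
#' present). With a single candidate the threshold alone decides, with a
#' warning.
#'
#' @param signal Raw extracellular series (a.u.).
#' @param sampling_rate Sampling rate (Hz).
#' @param threshold_mult Candidate threshold as a multiple of the MAD-based
#'   noise SD (default 4).
#' @param min_separation Minimal separation of cluster mean peak amplitudes,
#'   in noise SDs, for the spike cluster to be accepted (default 2).
#' @param window_ms Feature window around each candidate peak (ms).
#' @return Numeric vector of spike times (s, at the event peak), with the
#'   candidate feature table attached as attribute `features`.
#' @export
detect_afferent_spikes_kmeans <- function(signal, sampling_rate,
                                          threshold_mult = 4,
                                          min_separation = 2,
                                          window_ms = 1.5) {
  if (!all(is.finite(signal))) abort("`signal` must be finite.")
  sigma <- stats::mad(signal)
  if (sigma == 0) return(structure(numeric(0), features = NULL))
  thr <- threshold_mult * sigma
  n <- length(signal)
  up <- which(signal[-n] < thr & signal[-1] >= thr)
  if (length(up) == 0) return(structure(numeric(0), features = NULL))
  half_w <- round(window_ms / 1000 * sampling_rate / 2)
  feats <- purrr::map_dfr(up, function(i) {
    i0 <- max(1, i - half_w); i1 <- min(n, i + 2 * half_w)
    seg <- signal[i0:i1]
    i_peak <- i0 + which.max(seg) - 1
    after <- signal[i_peak:min(n, i_peak + 2 * half_w)]
    width <- sum(seg >= max(seg) / 2) / sampling_rate * 1000
    tibble(i_peak = i_peak, peak = max(seg), trough = min(after),
           width_ms = width)
  })
  feats <- dplyr::distinct(feats, .data$i_peak, .keep_all = TRUE)
  if (nrow(feats) == 1) {
    warn("Single candidate event: threshold-only decision.")
    return(structure((feats$i_peak - 1) / sampling_rate, features = feats))
  }
  fm <- scale(as.matrix(feats[, c("peak", "trough", "width_ms")]))
  fm[, apply(fm, 2, function(x) any(!is.finite(x)))] <- 0
  clusters <- if (nrow(fm) == 2) {
    c(1L, 2L)  # two candidates partition trivially
  } else {
    stats::kmeans(fm, centers = 2, nstart = 5)$cluster
  }
  mean_peaks <- tapply(feats$peak, clusters, mean)
  spike_cluster <- as.integer(names(which.max(mean_peaks)))
  if (diff(range(mean_peaks)) < min_separation * sigma) {
    # homogeneous candidate population: one event type only. Decide by
    # amplitude whether it is a unit or threshold-crossing noise (noise
    # peaks concentrate just above the threshold).
    if (mean(feats$peak) >= (threshold_mult + 1.5) * sigma) {
      return(structure(sort((feats$i_peak - 1) / sampling_rate),
                       features = feats))
    }
    return(structure(numeric(0), features = feats))
  }
  keep <- feats[clusters == spike_cluster, ]
  structure(sort((keep$i_peak - 1) / sampling_rate), features = feats)
}
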