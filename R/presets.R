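# Calibrated presets: published cohort summaries packaged as generator ground
# truth for the synthetic neuron and behavior generators.

parse_kv_fixture <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  block <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      block <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[block]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(block)) abort(sprintf("entry before first block in %s", path))
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      num <- suppressWarnings(as.numeric(val))
      out[[block]][[key]] <- if (is.na(num)) val else num
    }
  }
  out
}

ephys_presets <- function() {
  parse_kv_fixture(system.file("extdata", "ephys_presets.txt",
                               package = "gammasig", mustWork = TRUE))
}

#' Calibrated neuron ground-truth presets
#'
#' Returns the ground-truth parameter set of one of the packaged motor neuron
#' presets, calibrated against published whole-cell patch-clamp cohort
#' summaries for Fluoro-Gold-high (putative gamma) and Fluoro-Gold-low
#' (putative alpha) motor neurons in control and ERR2/3 conditional-knockout
#' mice.
#'
#' The generator's frequency-current (F-I) law is piecewise linear:
#' `f(I) = gain * (I - rheobase)` for `I > rheobase` (currents in nA) and 0
#' otherwise, so the F-I gain and rheobase of a simulated neuron are known
#' exactly. Because a linear law cannot also reproduce the published mean
#' firing frequency at an arbitrary current, each preset carries a *reference
#' current* `ref_current_pa = rheobase + ff_ref/gain` (quantized to the 20 pA
#' protocol grid) at which the law yields the published firing-frequency mean
#' `ff_ref_hz`.
#'
#' @param preset One of `"gamma_control"`, `"alpha_control"`,
#'   `"gamma_err23cko"`, `"alpha_err23cko"`.
#' @param step_by_pa Step-amplitude grid (pA) used to quantize the reference
#'   current. Default 20 pA, matching the step protocol.
#'
#' @return A one-row tibble of class `neuron_truth` with columns
#'   `preset`, `rheobase_pa`, `gain_hz_na`, `ff_ref_hz`, `ref_current_pa`,
#'   `rin_mohm`, `cm_pf`, `tau_ms` (membrane time constant `rin * cm`),
#'   `ahp_amp_mv`, `ahp_tau_ms`, `noise_sd_mv`, `jitter_cv`,
#'   `protocol_max_pa`, `n_neurons`, and the published SEM columns (`*_sem`).
#'
#' @examples
#' calibrate_preset("gamma_control")
#' @export
calibrate_preset <- function(preset, step_by_pa = 20) {
  presets <- ephys_presets()
  if (!is.character(preset) || length(preset) != 1 ||
      !preset %in% names(presets)) {
    abort(sprintf(
      "Unknown preset %s. Available presets: %s.",
      if (is.character(preset)) paste0('"', preset, '"') else "<non-string>",
      paste0('"', names(presets), '"', collapse = ", ")
    ))
  }
  p <- presets[[preset]]
  ref_exact <- p$rheobase_pa + 1000 * p$ff_ref_hz / p$gain_hz_na
  truth <- tibble(
    preset = preset,
    rheobase_pa = p$rheobase_pa,
    rheobase_sem = p$rheobase_sem,
    gain_hz_na = p$gain_hz_na,
    gain_sem = p$gain_sem,
    ff_ref_hz = p$ff_ref_hz,
    ff_ref_sem = p$ff_ref_sem,
    ref_current_pa = step_by_pa * round(ref_exact / step_by_pa),
    rin_mohm = p$rin_mohm,
    rin_sem = p$rin_sem,
    cm_pf = p$cm_pf,
    cm_sem = p$cm_sem,
    tau_ms = p$rin_mohm * p$cm_pf / 1000,
    ahp_amp_mv = p$ahp_amp_mv,
    ahp_tau_ms = p$ahp_tau_ms,
    noise_sd_mv = 0.5,
    jitter_cv = 0.15,
    protocol_max_pa = p$protocol_max_pa,
    n_neurons = p$n_neurons
  )
  validate_neuron_truth(truth)
  class(truth) <- c("neuron_truth", class(truth))
  truth
}

#' Construct a neuron ground truth by hand
#'
#' Builds the same ground-truth record as [calibrate_preset()] from explicit
#' values, for simulations that are not tied to a published cohort.
#'
#' @param rheobase_pa Threshold current (pA), > 0.
#' @param gain_hz_na F-I slope (Hz/nA), >= 0.
#' @param rin_mohm Input resistance (MOhm), > 0.
#' @param cm_pf Membrane capacitance (pF), > 0.
#' @param ahp_amp_mv Afterhyperpolarization amplitude (mV), >= 0.
#' @param ahp_tau_ms AHP exponential decay constant (ms), > 0.
#' @param noise_sd_mv Additive Gaussian voltage noise SD (mV), >= 0.
#' @param jitter_cv Coefficient of variation of log-normal population jitter.
#' @param ff_ref_hz,ref_current_pa Optional reference firing frequency and the
#'   current at which it is attained; derived from the F-I law when omitted.
#' @return A one-row `neuron_truth` tibble.
#' @export
neuron_truth <- function(rheobase_pa, gain_hz_na, rin_mohm, cm_pf,
                         ahp_amp_mv = 4, ahp_tau_ms = 20,
                         noise_sd_mv = 0.5, jitter_cv = 0.15,
                         ff_ref_hz = NULL, ref_current_pa = NULL) {
  if (is.null(ref_current_pa)) {
    ref_current_pa <- if (is.null(ff_ref_hz) || gain_hz_na == 0) {
      NA_real_
    } else {
      rheobase_pa + 1000 * ff_ref_hz / gain_hz_na
    }
  }
  if (is.null(ff_ref_hz)) ff_ref_hz <- NA_real_
  truth <- tibble(
    preset = "custom",
    rheobase_pa = rheobase_pa, rheobase_sem = NA_real_,
    gain_hz_na = gain_hz_na, gain_sem = NA_real_,
    ff_ref_hz = ff_ref_hz, ff_ref_sem = NA_real_,
    ref_current_pa = ref_current_pa,
    rin_mohm = rin_mohm, rin_sem = NA_real_,
    cm_pf = cm_pf, cm_sem = NA_real_,
    tau_ms = rin_mohm * cm_pf / 1000,
    ahp_amp_mv = ahp_amp_mv, ahp_tau_ms = ahp_tau_ms,
    noise_sd_mv = noise_sd_mv, jitter_cv = jitter_cv,
    protocol_max_pa = NA_real_, n_neurons = NA_real_
  )
  validate_neuron_truth(truth)
  class(truth) <- c("neuron_truth", class(truth))
  truth
}

validate_neuron_truth <- function(truth) {
  assert_scalar_number(truth$rheobase_pa, "rheobase_pa", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(truth$gain_hz_na, "gain_hz_na", lower = 0)
  assert_scalar_number(truth$rin_mohm, "rin_mohm", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(truth$cm_pf, "cm_pf", lower = 0, strict_lower = TRUE)
  assert_scalar_number(truth$tau_ms, "tau_ms", lower = 0, strict_lower = TRUE)
  assert_scalar_number(truth$ahp_amp_mv, "ahp_amp_mv", lower = 0)
  assert_scalar_number(truth$ahp_tau_ms, "ahp_tau_ms", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(truth$noise_sd_mv, "noise_sd_mv", lower = 0)
  invisible(truth)
}

#' Published precision-movement miss-count means
#'
#' The packaged fixture of published per-condition group means (and SEMs) of
#' per-animal mean misses per trial on horizontal beams (30, 25, 20 mm width)
#' and a horizontal ladder, for control versus ERR2/3 conditional-knockout
#' mice. Used to calibrate [simulate_behavior_counts()] and as the reference
#' for [fold_change()].
#'
#' @return A tibble with columns `condition`, `group`, `mean`, `sem`,
#'   `n_animals`.
#' @examples
#' behavior_means()
#' @export
behavior_means <- function() {
  path <- system.file("extdata", "behavior_means.txt",
                      package = "gammasig", mustWork = TRUE)
  tbl <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("condition", "group", "mean",
                                         "sem", "n_animals"),
                           stringsAsFactors = FALSE)
  as_tibble(tbl)
}
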