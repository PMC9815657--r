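# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_polygon
#'   geom_col geom_histogram geom_vline facet_wrap labs theme_minimal
#'   scale_color_manual coord_flip
#' @export
ggplot2::autoplot

#' Plot a sweep set
#'
#' Voltage traces of selected sweeps, faceted by injected current.
#'
#' @param object A `sweep_set`.
#' @param amplitudes_pa Amplitudes to show (default: up to 4, spread over the
#'   ladder).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_set <- function(object, amplitudes_pa = NULL, ...) {
  if (is.null(amplitudes_pa)) {
    k <- unique(round(seq(1, nrow(object), length.out = min(4, nrow(object)))))
    amplitudes_pa <- object$amplitude_pa[k]
  }
  sub <- object[object$amplitude_pa %in% amplitudes_pa, ]
  df <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    v <- sub$voltage[[i]]
    tibble(amplitude_pa = sub$amplitude_pa[i],
           time_s = (seq_along(v) - 1) / sub$sampling_rate_hz[i],
           voltage_mv = v)
  })
  ggplot(df, aes(x = .data$time_s, y = .data$voltage_mv)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~amplitude_pa, labeller = ggplot2::label_both) +
    labs(x = "time (s)", y = "membrane potential (mV)",
         title = object$neuron_id[1]) +
    theme_minimal()
}

#' Plot an F-I curve
#'
#' Mean firing frequency against injected current for one extracted neuron or
#' a frequency table.
#'
#' @param freq_tbl A tibble with `amplitude_pa` and `mean_hz` columns.
#' @return A ggplot.
#' @export
plot_fi_curve <- function(freq_tbl) {
  ggplot(freq_tbl, aes(x = .data$amplitude_pa / 1000, y = .data$mean_hz)) +
    geom_point() +
    geom_line(alpha = 0.5) +
    labs(x = "injected current (nA)", y = "mean firing frequency (Hz)") +
    theme_minimal()
}

#' Plot the signature scatter
#'
#' Rheobase against F-I gain per neuron, point size by mean firing frequency,
#' colored by group: the standard display of the gamma-versus-alpha
#' electrophysiological signature.
#'
#' @param object A `signature_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signature_summary <- function(object, ...) {
  df <- object$scatter
  ggplot(df, aes(x = .data[[object$vars[1]]], y = .data[[object$vars[3]]],
                 size = .data[[object$vars[2]]], color = .data$group)) +
    geom_point(alpha = 0.7) +
    labs(x = "rheobase (pA)", y = "gain (Hz/nA)",
         size = "mean firing\nfrequency (Hz)",
         subtitle = sprintf("separation index %.2f", object$separation_index)) +
    theme_minimal()
}

#' Plot OSC-PLS scores
#'
#' Component-1 versus component-2 scores with one convex polygon per group:
#' group separation along the first (predictive) axis indicates a gait
#' difference.
#'
#' @param object An `oscpls` model.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oscpls <- function(object, ...) {
  sc <- object$core$pls$scores
  df <- tibble(
    comp1 = sc[, 1],
    comp2 = if (ncol(sc) >= 2) sc[, 2] else 0,
    group = ifelse(object$y_raw > 0, object$levels[2], object$levels[1])
  )
  hulls <- df |>
    group_by(.data$group) |>
    dplyr::slice(grDevices::chull(.data$comp1, .data$comp2)) |>
    ungroup()
  ggplot(df, aes(x = .data$comp1, y = .data$comp2, color = .data$group)) +
    geom_polygon(data = hulls, aes(fill = .data$group), alpha = 0.2,
                 linewidth = 0.2) +
    geom_point() +
    labs(x = "component 1 (predictive)", y = "component 2") +
    theme_minimal()
}

#' Plot ranked loadings
#'
#' Signed loadings of the predictive component, ranked by magnitude, colored
#' by direction of change in the mutant group.
#'
#' @param loadings A [rank_loadings()] table (or an `oscpls` model).
#' @param top Number of variables shown.
#' @return A ggplot.
#' @export
plot_loadings <- function(loadings, top = 20) {
  if (inherits(loadings, "oscpls")) loadings <- rank_loadings(loadings)
  df <- head(loadings, top)
  df$variable <- factor(df$variable, levels = rev(df$variable))
  ggplot(df, aes(x = .data$variable, y = .data$loading,
                 fill = .data$direction)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "signed loading (component 1)") +
    theme_minimal()
}

#' Plot a permutation-validation report
#'
#' Histograms of the permuted and non-permuted Q2 distributions with the
#' full-data model's Q2 marked.
#'
#' @param object An `oscpls_validation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oscpls_validation <- function(object, ...) {
  df <- tidyr::pivot_longer(object$repeats, c("q2", "q2_perm"),
                            names_to = "which", values_to = "value")
  df$which <- ifelse(df$which == "q2", "resampled", "permuted")
  ggplot(df, aes(x = .data$value, fill = .data$which)) +
    geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    geom_vline(xintercept = object$q2, linetype = 2) +
    labs(x = "Q2", y = "repeats", fill = NULL,
         subtitle = sprintf("model Q2 = %.2f; permuted mean = %.2f (p = %.2g)",
                            object$q2, object$q2_perm_mean, object$t_q2$p)) +
    theme_minimal()
}

#' Plot a stretch trial
#'
#' Length channel, underlying rate (when available) and instantaneous firing
#' rate of a ramp-and-hold trial.
#'
#' @param object A `stretch_trial`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stretch_trial <- function(object, ...) {
  ir <- instantaneous_rate(object$spike_times_s)
  len <- tibble(time_s = object$channels$time_s,
                value = object$channels$length * 100,
                panel = "length (% Lo)")
  est <- tibble(time_s = ir$time_s, value = ir$rate_hz, panel = "rate (Hz)")
  truth <- if (!is.null(object$rate_true)) {
    tibble(time_s = object$rate_true$time_s,
           value = object$rate_true$rate_hz, panel = "rate (Hz)")
  }
  ggplot(bind_rows(len, est, truth),
         aes(x = .data$time_s, y = .data$value)) +
    geom_line(data = len, linewidth = 0.4) +
    {if (!is.null(truth)) geom_line(data = truth, alpha = 0.5,
                                    color = "grey50")} +
    geom_point(data = est, size = 0.6) +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}
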