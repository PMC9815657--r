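# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an OSC-PLS model
#'
#' One row per gait variable: the signed loading on the predictive component,
#' its magnitude and rank ([rank_loadings()]).
#'
#' @param x An `oscpls` model.
#' @param ... Unused.
#' @return A tibble: `variable`, `loading`, `abs_loading`, `direction`,
#'   `rank`.
#' @export
tidy.oscpls <- function(x, ...) {
  rank_loadings(x)
}

#' Glance at an OSC-PLS model
#'
#' @param x An `oscpls` model.
#' @param ... Unused.
#' @return A one-row tibble: `n_obs`, `n_vars`, `n_components`, `n_osc`,
#'   `var_captured_cum` (cumulative predictor variance captured by the PLS
#'   components).
#' @export
glance.oscpls <- function(x, ...) {
  vc <- variance_captured(x)
  tibble(
    n_obs = x$n_obs, n_vars = length(x$variables),
    n_components = x$n_components, n_osc = x$n_osc,
    var_captured_cum = vc$cumulative[nrow(vc)]
  )
}

#' Tidy a permutation-validation report
#'
#' One row per resampling repeat with the permuted and non-permuted Q2 and
#' RMSEP values.
#'
#' @param x An `oscpls_validation` object.
#' @param ... Unused.
#' @return A tibble with columns `repeat_i`, `q2`, `rmsep`, `q2_perm`,
#'   `rmsep_perm`.
#' @export
tidy.oscpls_validation <- function(x, ...) {
  x$repeats
}

#' Glance at a permutation-validation report
#'
#' @param x An `oscpls_validation` object.
#' @param ... Unused.
#' @return A one-row tibble: the full-model leave-one-out `q2`, the averaged
#'   non-permuted and permuted Q2/RMSEP, the two-sample t statistics and p
#'   values of the permuted-vs-non-permuted comparisons, the z-score of the
#'   full model in the permuted Q2 distribution, and the settings.
#' @export
glance.oscpls_validation <- function(x, ...) {
  tibble(
    q2 = x$q2, q2_mean = x$q2_mean, q2_perm_mean = x$q2_perm_mean,
    rmsep_mean = x$rmsep_mean, rmsep_perm_mean = x$rmsep_perm_mean,
    t_q2 = x$t_q2$t, p_q2 = x$t_q2$p,
    t_rmsep = x$t_rmsep$t, p_rmsep = x$t_rmsep$p,
    z_q2 = x$z_q2,
    n_repeats = x$n_repeats, train_fraction = x$train_fraction,
    seed = x$seed
  )
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` ([group_compare()]).
#' @param ... Unused.
#' @return A two-row tibble (`group`, `mean`, `sem`, `n`) plus the shared
#'   test columns `t`, `df`, `p`, `stars`.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(
    group = c("a", "b"),
    mean = c(x$mean_a, x$mean_b),
    sem = c(x$sem_a, x$sem_b),
    n = c(x$n_a, x$n_b),
    t = x$t, df = x$df, p = x$p, stars = x$stars
  )
}

#' Glance at a signature summary
#'
#' @param x A `signature_summary` ([signature_summary()]).
#' @param ... Unused.
#' @return A one-row tibble: `separation_index`, `perm_p`, `n_perm`,
#'   `degenerate`.
#' @export
glance.signature_summary <- function(x, ...) {
  tibble(separation_index = x$separation_index, perm_p = x$perm_p,
         n_perm = x$n_perm, degenerate = x$degenerate)
}
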