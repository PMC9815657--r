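# Precision-movement scoring: overdispersed per-trial miss counts, animal ->
# group aggregation, fold changes and group comparisons.

#' Behavior simulation configuration
#'
#' Per-trial miss counts are drawn from a negative-binomial distribution with
#' the configured per-group, per-condition means and a common dispersion
#' parameter (`size` of [stats::rnbinom()]; variance `mu + mu^2/size`, so the
#' Poisson limit is `dispersion -> Inf`). The published summaries give only
#' means and SEMs, so the inter-trial dispersion is a free parameter.
#'
#' @param group_means A tibble with columns `condition`, `group`, `mean` (and
#'   optionally `n_animals`); defaults to the packaged published means
#'   ([behavior_means()]).
#' @param dispersion Negative-binomial size parameter, > 0 (default 10).
#' @param trials_per_animal Trials per animal (default 4, within the
#'   published 4-5 range).
#' @param n_animals Animals per group; defaults to the fixture's `n_animals`
#'   when present, else 4.
#' @return A list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(group_means = behavior_means(),
                                dispersion = 10, trials_per_animal = 4,
                                n_animals = NULL) {
  stopifnot(all(c("condition", "group", "mean") %in% names(group_means)))
  if (any(group_means$mean < 0)) abort("Means must be >= 0.")
  assert_scalar_number(dispersion, "dispersion", lower = 0,
                       strict_lower = TRUE)
  stopifnot(trials_per_animal >= 1)
  structure(list(group_means = group_means, dispersion = dispersion,
                 trials_per_animal = trials_per_animal,
                 n_animals = n_animals),
            class = "behavior_sim_config")
}

#' Simulate precision-task trial scores
#'
#' Draws per-animal, per-trial miss counts from the configured
#' negative-binomial model for every group x condition cell. A nominal count
#' of miss opportunities per trial (`steps`: paw placements, roughly 4 per
#' stride over the ~40 strides analyzed per trial) is attached so miss rates
#' per opportunity can be formed.
#'
#' @param config A [behavior_sim_config()].
#' @param seed Integer seed.
#' @return A tibble of trial scores: `animal_id`, `group`, `condition`,
#'   `trial`, `misses`, `steps`.
#' @examples
#' head(simulate_behavior_counts(seed = 1))
#' @export
simulate_behavior_counts <- function(config = behavior_sim_config(),
                                     seed = 1) {
  stopifnot(inherits(config, "behavior_sim_config"))
  gm <- config$group_means
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(gm)), function(i) {
      n_an <- config$n_animals %||%
        (if ("n_animals" %in% names(gm)) gm$n_animals[i] else 4)
      purrr::map_dfr(seq_len(n_an), function(a) {
        # miss opportunities: paw placements (~4 per stride, ~40 strides
        # analyzed per trial), so counts well above the stride count are
        # possible while misses <= steps still holds
        steps <- pmax(100, stats::rnbinom(config$trials_per_animal,
                                          mu = 160, size = 50))
        misses <- stats::rnbinom(config$trials_per_animal,
                                 mu = gm$mean[i], size = config$dispersion)
        tibble(
          animal_id = sprintf("%s_%s_%02d", gm$group[i], gm$condition[i], a),
          group = gm$group[i], condition = gm$condition[i],
          trial = seq_len(config$trials_per_animal),
          misses = pmin(misses, steps), steps = steps
        )
      })
    })
  })
}

# animal-level means for one condition
animal_means <- function(scores, condition) {
  stopifnot(all(c("animal_id", "group", "condition", "misses") %in%
                  names(scores)))
  sub <- scores[scores$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(sprintf("Condition \"%s\" not present in the scores.", condition))
  }
  sub |>
    group_by(.data$group, .data$animal_id) |>
    summarise(mean_misses = mean(.data$misses), .groups = "drop")
}

#' Summarize a precision-task condition
#'
#' Trials are first averaged within animal, then the group mean and SEM are
#' taken across animals (the published N refers to animals, so the SEM is an
#' across-animal SEM).
#'
#' @param scores A trial-score table (`animal_id`, `group`, `condition`,
#'   `trial`, `misses`, optionally `steps`).
#' @param condition Condition to summarize (e.g. `"beam_30mm"`).
#' @return A tibble: `group`, `condition`, `n_animals`, `mean`, `sem`.
#' @examples
#' scores <- simulate_behavior_counts(seed = 1)
#' summarize_condition(scores, "beam_30mm")
#' @export
summarize_condition <- function(scores, condition) {
  animal_means(scores, condition) |>
    group_by(.data$group) |>
    summarise(condition = condition, n_animals = dplyr::n(),
              mean = mean(.data$mean_misses),
              sem = if (dplyr::n() > 1) sem(.data$mean_misses) else 0,
              .groups = "drop")
}

#' Fold change of misses, mutant over control
#'
#' Ratio of the mutant group mean to the control group mean for one
#' condition, on a condition summary ([summarize_condition()]) or directly on
#' a fixture-style means table.
#'
#' @param summary A tibble with `group`, `condition`, `mean` columns.
#' @param condition Condition of interest.
#' @param control,mutant Group labels.
#' @return The fold-change scalar (NA with a warning when the control mean
#'   is 0).
#' @examples
#' fold_change(behavior_means(), "beam_30mm", mutant = "err23cko")
#' @export
fold_change <- function(summary, condition, control = "control",
                        mutant = NULL) {
  sub <- summary[summary$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(sprintf("Condition \"%s\" not present.", condition))
  }
  if (is.null(mutant)) {
    mutant <- setdiff(unique(sub$group), control)
    if (length(mutant) != 1) abort("Cannot identify a single mutant group.")
  }
  m_ctrl <- sub$mean[sub$group == control]
  m_mut <- sub$mean[sub$group == mutant]
  if (length(m_ctrl) != 1 || length(m_mut) != 1) {
    abort("Need exactly one control and one mutant row for the condition.")
  }
  if (m_ctrl == 0) {
    warn("Control mean is 0: fold change undefined.")
    return(NA_real_)
  }
  m_mut / m_ctrl
}

#' Compare groups on a precision-task condition
#'
#' Two-sample Student t test ([group_compare()]) on the animal-level mean
#' misses of the two groups.
#'
#' @inheritParams summarize_condition
#' @param control Label of the group used as `values_a`.
#' @return A `group_comparison` tibble.
#' @export
compare_conditions <- function(scores, condition, control = "control") {
  am <- animal_means(scores, condition)
  groups <- unique(am$group)
  if (length(groups) != 2) abort("Need exactly 2 groups.")
  other <- setdiff(groups, control)
  group_compare(am$mean_misses[am$group == control],
                am$mean_misses[am$group == other])
}
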