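# Synthetic gait tables with planted group effects and low-rank inter-variable
# correlation, emulating the structure of automated treadmill gait analysis
# (many partially redundant variables, few animals, few trials).

#' Gait simulation configuration
#'
#' @param n_per_group Animals per group, length 2 (control, mutant). Default
#'   `c(9, 8)`, the cohort sizes of the emulated experiment.
#' @param trials_per_animal Trials per animal (default 3).
#' @param n_vars Number of gait variables (default 58).
#' @param n_informative Number of variables carrying a group shift.
#' @param effect_sizes Standardized mean shifts added to the informative
#'   variables in the mutant group; recycled to `n_informative`.
#' @param latent_rank Rank of the animal-level latent factor structure that
#'   induces inter-variable correlation (must be < `n_vars`).
#' @param noise_sd Trial-level noise SD (the latent structure has unit scale).
#' @return A list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_per_group = c(9, 8), trials_per_animal = 3,
                            n_vars = 58, n_informative = 10,
                            effect_sizes = 1.5, latent_rank = 5,
                            noise_sd = 0.5) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1),
            trials_per_animal >= 1, n_vars >= 1)
  if (n_informative > n_vars) {
    abort("`n_informative` must be <= `n_vars`.")
  }
  if (latent_rank >= n_vars) abort("`latent_rank` must be < `n_vars`.")
  if (!all(is.finite(effect_sizes))) abort("`effect_sizes` must be finite.")
  effect_sizes <- rep_len(effect_sizes, max(1, n_informative))
  structure(list(n_per_group = n_per_group,
                 trials_per_animal = trials_per_animal, n_vars = n_vars,
                 n_informative = n_informative, effect_sizes = effect_sizes,
                 latent_rank = latent_rank, noise_sd = noise_sd),
            class = "gait_sim_config")
}

#' Simulate a multivariate gait table
#'
#' Draws animal-level latent factors of rank `latent_rank`, maps them to
#' `n_vars` correlated gait variables through a fixed random loading matrix,
#' adds the configured standardized mean shifts to the informative variables
#' for the mutant group, and adds independent trial-level noise. The
#' ground-truth informative variable set is attached as attribute
#' `informative`.
#'
#' @param config A [gait_sim_config()].
#' @param seed Integer seed; identical config and seed give an identical
#'   table.
#' @param groups Group labels, length 2 (control first).
#' @return A tibble with columns `animal_id`, `group`, `trial`, and the gait
#'   variables `gv_01` ... (one row per animal x trial).
#' @examples
#' simulate_gait_table(gait_sim_config(n_per_group = c(3, 3), n_vars = 6,
#'                                     n_informative = 2), seed = 1)
#' @export
simulate_gait_table <- function(config = gait_sim_config(), seed = 1,
                                groups = c("control", "mutant")) {
  stopifnot(inherits(config, "gait_sim_config"), length(groups) == 2)
  n_animals <- sum(config$n_per_group)
  vars <- sprintf("gv_%02d", seq_len(config$n_vars))
  informative <- if (config$n_informative > 0) {
    vars[seq_len(config$n_informative)]
  } else {
    character(0)
  }
  withr::with_seed(seed, {
    loadings <- matrix(stats::rnorm(config$latent_rank * config$n_vars),
                       config$latent_rank, config$n_vars) /
      sqrt(config$latent_rank)
    animals <- tibble(
      animal_id = sprintf("a%02d", seq_len(n_animals)),
      group = rep(groups, config$n_per_group)
    )
    latent <- matrix(stats::rnorm(n_animals * config$latent_rank),
                     n_animals, config$latent_rank)
    base <- latent %*% loadings  # animal-level correlated structure
    shift <- numeric(config$n_vars)
    if (config$n_informative > 0) {
      shift[seq_len(config$n_informative)] <- config$effect_sizes
    }
    rows <- purrr::map_dfr(seq_len(n_animals), function(a) {
      mu <- base[a, ] + if (animals$group[a] == groups[2]) shift else 0
      trial_mat <- matrix(stats::rnorm(config$trials_per_animal *
                                         config$n_vars,
                                       sd = config$noise_sd),
                          config$trials_per_animal, config$n_vars)
      trial_mat <- sweep(trial_mat, 2, mu, "+")
      colnames(trial_mat) <- vars
      dplyr::bind_cols(
        tibble(animal_id = animals$animal_id[a], group = animals$group[a],
               trial = seq_len(config$trials_per_animal)),
        as_tibble(trial_mat)
      )
    })
    attr(rows, "informative") <- informative
    rows
  })
}
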