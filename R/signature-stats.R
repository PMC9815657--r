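# Group statistics and marker-quantification analyses: intensity
# normalization, Fluoro-Gold gating, correlations, two-sample comparisons and
# the electrophysiological signature scatter summary.

#' Normalize fluorescence intensities to a reference maximum
#'
#' `(raw - background) / (reference_max - background)`, clipped to `[0, 1]`:
#' the convention of normalizing nuclear marker intensities against the
#' background level and the brightest neuron of the section.
#'
#' @param raw Raw intensities (arbitrary units); vectorized.
#' @param background Background level (scalar or vector).
#' @param reference_max Intensity of the brightest neuron; must exceed the
#'   background.
#' @return Normalized intensities in `[0, 1]`.
#' @examples
#' normalize_intensity(c(10, 55, 100), background = 10, reference_max = 100)
#' @export
normalize_intensity <- function(raw, background, reference_max) {
  if (any(reference_max <= background)) {
    abort("`reference_max` must exceed `background`.")
  }
  pmin(1, pmax(0, (raw - background) / (reference_max - background)))
}

#' Fluoro-Gold gate configuration
#'
#' Rectangular 2-D gates on Fluoro-Gold (FG) level and soma size: FG-high
#' (putative gamma) cells have `fg >= fg_hi` and `soma <= soma_small`; FG-low
#' (putative alpha) cells have `fg` in `[fg_lo_min, fg_hi)` and
#' `soma >= soma_large`. There are no published numeric cutoffs; the defaults
#' were chosen on synthetic bimodal populations (see the methods vignette)
#' and should be adapted to each normalization.
#'
#' @param fg_hi FG threshold above which a cell can be FG-high.
#' @param fg_lo_min Minimal FG level for the FG-low gate (excludes unlabeled
#'   cells).
#' @param soma_small Largest soma size admitted to the FG-high gate.
#' @param soma_large Smallest soma size admitted to the FG-low gate.
#' @return A list of class `fg_gate_config`.
#' @export
fg_gate_config <- function(fg_hi = 0.5, fg_lo_min = 0.02,
                           soma_small = 450, soma_large = 450) {
  if (fg_lo_min >= fg_hi) {
    abort("Overlapping gates: `fg_lo_min` must be < `fg_hi`.")
  }
  if (soma_small > soma_large) {
    abort("Overlapping gates: `soma_small` must be <= `soma_large`.")
  }
  structure(list(fg_hi = fg_hi, fg_lo_min = fg_lo_min,
                 soma_small = soma_small, soma_large = soma_large),
            class = "fg_gate_config")
}

#' Gate motor neurons into FG-high / FG-low populations
#'
#' Applies the 2-D rectangular gate of [fg_gate_config()] to a per-neuron
#' table, labelling each record `"FG-high"`, `"FG-low"` or `"ungated"`.
#'
#' @param data A data frame with the FG level and soma size columns.
#' @param fg,soma Tidy-selected columns holding the FG level and soma size.
#' @param gate A [fg_gate_config()].
#' @return `data` with an added `fg_gate` column.
#' @export
gate_fg <- function(data, fg = "fg", soma = "soma",
                    gate = fg_gate_config()) {
  fg_v <- data[[fg]]
  soma_v <- data[[soma]]
  if (is.null(fg_v) || is.null(soma_v)) {
    abort("`data` must contain the FG and soma columns.")
  }
  data$fg_gate <- dplyr::case_when(
    fg_v >= gate$fg_hi & soma_v <= gate$soma_small ~ "FG-high",
    fg_v >= gate$fg_lo_min & fg_v < gate$fg_hi &
      soma_v >= gate$soma_large ~ "FG-low",
    TRUE ~ "ungated"
  )
  data
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with explicit degenerate-input handling: at
#' least three paired values and nonzero variance in both arguments are
#' required; a zero-variance argument yields NA with a warning rather than an
#' error.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The correlation coefficient `r` (NA when undefined).
#' @examples
#' pearson_corr(1:10, (1:10) * 2 + 1)
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal lengths.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("Zero variance: correlation undefined.")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Two-sample group comparison (Student t test)
#'
#' Pooled-variance two-sample two-sided t test, the convention used for all
#' published group comparisons here, with group means and SEMs and the usual
#' significance stars. Welch's unequal-variance test is available behind
#' `var_equal = FALSE`.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (Student, default) or not (Welch).
#' @return A one-row tibble of class `group_comparison`: `mean_a`, `sem_a`,
#'   `n_a`, `mean_b`, `sem_b`, `n_b`, `t`, `df`, `p`, `stars`.
#' @examples
#' group_compare(c(1, 2, 3), c(4, 5, 6))
#' @export
group_compare <- function(values_a, values_b, var_equal = TRUE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("Each group needs at least 2 values.")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    # identical degenerate groups: no evidence of difference
    ht <- list(statistic = c(t = 0),
               parameter = c(df = length(values_a) + length(values_b) - 2),
               p.value = 1)
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  }
  out <- tibble(
    mean_a = mean(values_a), sem_a = sem(values_a), n_a = length(values_a),
    mean_b = mean(values_b), sem_b = sem(values_b), n_b = length(values_b),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, stars = p_stars(ht$p.value)
  )
  class(out) <- c("group_comparison", class(out))
  out
}

# centroid separation in z-scored feature space: Euclidean distance between
# the two group centroids divided by the mean within-group spread (mean
# distance of members to their own centroid)
separation_index_matrix <- function(X, groups) {
  z <- scale(X)
  z[, attr(z, "scaled:scale") == 0] <- 0
  gs <- unique(groups)
  if (length(gs) != 2) abort("Separation index is defined for 2 groups.")
  c1 <- colMeans(z[groups == gs[1], , drop = FALSE])
  c2 <- colMeans(z[groups == gs[2], , drop = FALSE])
  spread <- mean(c(
    sqrt(rowSums((z[groups == gs[1], , drop = FALSE] -
                    matrix(c1, sum(groups == gs[1]), ncol(z), byrow = TRUE))^2)),
    sqrt(rowSums((z[groups == gs[2], , drop = FALSE] -
                    matrix(c2, sum(groups == gs[2]), ncol(z), byrow = TRUE))^2))
  ))
  if (spread == 0) return(Inf)
  sqrt(sum((c1 - c2)^2)) / spread
}

#' Electrophysiological signature summary and separation index
#'
#' Emits the (rheobase, mean firing frequency, gain) signature tuple per
#' neuron and a scalar *separation index*: the Euclidean distance between the
#' two group centroids in z-scored signature space divided by the mean
#' within-group spread. A label-permutation test quantifies whether the
#' groups segregate more than chance.
#'
#' @param properties A tibble of per-neuron properties (as from
#'   [extract_properties()] / [extract_cohort()]) with a `group` column and
#'   the signature columns.
#' @param vars Signature columns (default rheobase, mean firing frequency,
#'   gain).
#' @param n_perm Number of label permutations for the null (0 to skip).
#' @param seed Seed for the permutation draw.
#' @return A list of class `signature_summary`: `scatter` (tibble of tuples),
#'   `separation_index`, `perm_p` (permutation p value, NA if `n_perm = 0`),
#'   `n_perm`, `degenerate` flag (a group with fewer than 2 complete
#'   signatures).
#' @export
signature_summary <- function(properties,
                              vars = c("rheobase_pa", "mean_ff_hz",
                                       "gain_hz_na"),
                              n_perm = 999, seed = 1) {
  stopifnot(all(c("group", vars) %in% names(properties)))
  scatter <- properties |>
    dplyr::select(dplyr::any_of(c("neuron_id", "group")), all_of(vars)) |>
    dplyr::filter(dplyr::if_all(all_of(vars), is.finite))
  groups <- unique(scatter$group)
  if (length(groups) != 2) abort("`properties` must contain exactly 2 groups.")
  degenerate <- any(table(scatter$group) < 2)
  if (degenerate) {
    warn("A group has fewer than 2 complete signatures; index flagged.")
  }
  X <- as.matrix(scatter[, vars])
  idx <- separation_index_matrix(X, scatter$group)
  perm_p <- NA_real_
  if (n_perm > 0 && !degenerate) {
    obs <- idx
    perm <- withr::with_seed(seed, {
      purrr::map_dbl(seq_len(n_perm), function(i) {
        separation_index_matrix(X, sample(scatter$group))
      })
    })
    perm_p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  structure(
    list(scatter = scatter, separation_index = idx, perm_p = perm_p,
         n_perm = n_perm, degenerate = degenerate, vars = vars),
    class = "signature_summary"
  )
}

#' Simulate a bimodal marker population
#'
#' Generates per-neuron marker records emulating the joint structure of
#' Fluoro-Gold level, soma size and two correlated nuclear marker intensities
#' in a mixed gamma/alpha motor neuron population: small somas with high FG
#' and high correlated marker levels versus large somas with low FG and low
#' marker levels.
#'
#' @param n_gamma,n_alpha Neurons per population.
#' @param marker_corr Within-population correlation of the two marker
#'   intensities.
#' @param seed Integer seed.
#' @return A tibble with columns `neuron_id`, `population` (ground truth),
#'   `soma`, `fg`, `marker1`, `marker2` (normalized intensities in `[0, 1]`).
#' @export
simulate_marker_population <- function(n_gamma = 50, n_alpha = 50,
                                       marker_corr = 0.6, seed = 1) {
  stopifnot(abs(marker_corr) <= 1)
  withr::with_seed(seed, {
    draw <- function(n, soma_m, soma_sd, fg_m, fg_sd, mk_m, mk_sd) {
      z1 <- stats::rnorm(n)
      z2 <- marker_corr * z1 + sqrt(1 - marker_corr^2) * stats::rnorm(n)
      tibble(
        soma = stats::rnorm(n, soma_m, soma_sd),
        fg = pmin(1, pmax(0, stats::rnorm(n, fg_m, fg_sd))),
        marker1 = pmin(1, pmax(0, mk_m + mk_sd * z1)),
        marker2 = pmin(1, pmax(0, mk_m + mk_sd * z2))
      )
    }
    g <- draw(n_gamma, 300, 50, 0.75, 0.10, 0.7, 0.12)
    a <- draw(n_alpha, 600, 60, 0.25, 0.08, 0.2, 0.08)
    out <- bind_rows(
      mutate(g, population = "gamma"),
      mutate(a, population = "alpha")
    )
    out$neuron_id <- sprintf("mn_%03d", seq_len(nrow(out)))
    dplyr::relocate(out, "neuron_id", "population")
  })
}
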