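#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows across all_of n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd var coef lm t.test cor kmeans rnorm rlnorm rnbinom
#'   runif mad quantile setNames
#' @importFrom utils head tail
NULL

# significance stars at the conventional 0.05 / 0.01 / 0.001 cutpoints
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}

# standard error of the mean
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g.", name, lower))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%g, %g].", name, lower, upper))
  }
  invisible(x)
}

# log-normal draws with a given mean and coefficient of variation,
# mean-preserving (E[X] = mean exactly)
rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}
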