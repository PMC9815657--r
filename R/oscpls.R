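# Orthogonal signal correction + NIPALS PLS1 discriminant modelling of gait
# tables, with leave-one-out Q2, RMSEP on held-out rows, and permutation
# validation. The OSC filter and PLS core are implemented from first
# principles; they are the method under study, not a wrapped dependency.

#' Center and scale a predictor matrix
#'
#' Columns are centered to mean 0 and scaled to standard deviation 1 (sample
#' SD, n-1 convention, recorded in the scaling state). Zero-variance columns
#' cannot be scaled and are dropped with a warning.
#'
#' @param X Numeric matrix (observations x variables).
#' @return A list of class `cs_scaling`: `X` (scaled matrix), `center`,
#'   `scale`, `dropped` (names of dropped columns), `sd_convention`.
#' @export
center_scale <- function(X) {
  X <- as.matrix(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- rep("", ncol(X))
  colnames(X) <- ifelse(nzchar(nm), nm, paste0("V", seq_len(ncol(X))))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[scl == 0 | !is.finite(scl)]
  if (length(dropped) > 0) {
    warn(sprintf("Dropping %d zero-variance column(s): %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  keep <- setdiff(colnames(X), dropped)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  structure(list(X = Xs, center = ctr[keep], scale = scl[keep],
                 dropped = dropped, sd_convention = "sample (n-1)"),
            class = "cs_scaling")
}

# apply a stored scaling state to new data (matching columns by name)
apply_scaling <- function(scaling, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  missing <- setdiff(names(scaling$center), colnames(X))
  if (length(missing) > 0) {
    abort(sprintf("New data lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  X <- X[, names(scaling$center), drop = FALSE]
  sweep(sweep(X, 2, scaling$center), 2, scaling$scale, "/")
}

#' Orthogonal signal correction filter
#'
#' Iteratively finds the direction of maximal predictor variance whose score
#' vector is orthogonalized against the response, and removes its rank-one
#' contribution from `X`, `n_osc` times. Each removed score vector `t`
#' satisfies `|t'y| <= 1e-8` by construction. With `n_osc = 0` the matrix is
#' returned unchanged.
#'
#' @param X Centered-scaled predictor matrix.
#' @param y Centered class response vector.
#' @param n_osc Number of orthogonal components to remove (>= 0).
#' @param max_iter,tol Convergence control of the inner iteration.
#' @return A list of class `osc_filter`: `X` (deflated), `weights` (p x k),
#'   `scores` (n x k), `loadings` (p x k), `n_osc`.
#' @export
osc_filter <- function(X, y, n_osc = 1, max_iter = 100, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), n_osc >= 0)
  r <- qr(X)$rank
  if (n_osc >= r) {
    abort(sprintf("`n_osc` (%d) must be smaller than rank(X) (%d).", n_osc, r))
  }
  p <- ncol(X)
  W <- matrix(0, p, n_osc); Tm <- matrix(0, nrow(X), n_osc)
  P <- matrix(0, p, n_osc)
  yy <- sum(y^2)
  orth_y <- function(t) t - y * sum(t * y) / yy
  if (n_osc > 0) {
    for (k in seq_len(n_osc)) {
      sv <- svd(X)
      keep_sv <- sv$d > sv$d[1] * 1e-10
      # minimum-norm pseudo-inverse: the weight vector must generalize to
      # unseen rows, so the smoothest w reproducing the score is used
      pinv <- sv$v[, keep_sv, drop = FALSE] %*%
        (t(sv$u[, keep_sv, drop = FALSE]) / sv$d[keep_sv])
      t_vec <- sv$u[, 1] * sv$d[1]
      for (it in seq_len(max_iter)) {
        t_old <- t_vec
        t_vec <- orth_y(t_vec)
        w <- pinv %*% t_vec
        w <- w / sqrt(sum(w^2))
        t_vec <- X %*% w
        if (sqrt(sum((t_vec - t_old)^2)) < tol * sqrt(sum(t_old^2))) break
      }
      t_vec <- orth_y(as.numeric(t_vec))  # exact orthogonality before removal
      p_vec <- crossprod(X, t_vec) / sum(t_vec^2)
      X <- X - tcrossprod(t_vec, p_vec)
      W[, k] <- w; Tm[, k] <- t_vec; P[, k] <- p_vec
    }
  }
  structure(list(X = X, weights = W, scores = Tm, loadings = P,
                 n_osc = n_osc),
            class = "osc_filter")
}

# apply a fitted OSC filter to new (already scaled) data
apply_osc <- function(osc, X) {
  X <- as.matrix(X)
  if (osc$n_osc == 0) return(X)
  for (k in seq_len(osc$n_osc)) {
    t_new <- as.numeric(X %*% osc$weights[, k])
    X <- X - tcrossprod(t_new, as.numeric(osc$loadings[, k]))
  }
  X
}

#' NIPALS PLS1 regression
#'
#' Partial least squares with a single response, fitted by the NIPALS
#' algorithm with deflation of `X` and `y`. Score vectors of successive
#' components are mutually orthogonal. The regression vector
#' `B = W (P'W)^-1 q` rebuilds predictions on the scaled predictor space.
#'
#' @param X Centered-scaled predictor matrix.
#' @param y Centered response.
#' @param n_components Number of latent components (<= rank of `X`).
#' @return A list of class `pls_fit`: `weights` (W), `scores` (T),
#'   `x_loadings` (P), `y_loadings` (q), `coefficients` (B), `fitted`,
#'   `n_components`.
#' @export
pls_fit <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  r <- qr(X)$rank
  if (n_components > r) {
    abort(sprintf("`n_components` (%d) exceeds rank(X) (%d).",
                  n_components, r))
  }
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  Xd <- X; yd <- y
  for (k in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {
      abort("PLS inner iteration degenerate: X'y vanished before reaching the requested number of components.")
    }
    w <- w / nw
    t_vec <- Xd %*% w
    tt <- sum(t_vec^2)
    p_vec <- crossprod(Xd, t_vec) / tt
    q_k <- sum(yd * t_vec) / tt
    Xd <- Xd - tcrossprod(t_vec, p_vec)
    yd <- yd - as.numeric(t_vec) * q_k
    W[, k] <- w; P[, k] <- p_vec; Tm[, k] <- t_vec; q[k] <- q_k
  }
  B <- W %*% solve(crossprod(P, W), q)
  rownames(B) <- colnames(X)
  fitted <- as.numeric(X %*% B)
  structure(list(weights = W, scores = Tm, x_loadings = P, y_loadings = q,
                 coefficients = B, fitted = fitted,
                 n_components = n_components),
            class = "pls_fit")
}

# --- gait-table plumbing -----------------------------------------------------

# split a gait table into X (numeric matrix), y (-1/+1 centered), ids
gait_xy <- function(data, group_col = "group",
                    id_cols = c("animal_id", "trial")) {
  stopifnot(group_col %in% names(data))
  groups <- data[[group_col]]
  levels <- sort(unique(as.character(groups)))
  if (length(levels) != 2) abort("The table must contain exactly 2 groups.")
  y_raw <- ifelse(as.character(groups) == levels[2], 1, -1)
  var_cols <- setdiff(names(data), c(group_col, id_cols))
  X <- as.matrix(data[, var_cols, drop = FALSE])
  if (!is.numeric(X)) abort("Gait variables must all be numeric.")
  if (anyNA(X)) abort("The table must have no missing cells.")
  list(X = X, y = y_raw - mean(y_raw), y_raw = y_raw, levels = levels,
       animal = if ("animal_id" %in% names(data)) data[["animal_id"]] else
         seq_len(nrow(data)))
}

# core fit on a matrix + response: scaling -> OSC -> PLS
oscpls_core <- function(X, y, n_components, n_osc) {
  scaling <- center_scale(X)
  osc <- osc_filter(scaling$X, y, n_osc = n_osc)
  pls <- pls_fit(osc$X, y, n_components = n_components)
  list(scaling = scaling, osc = osc, pls = pls)
}

predict_core <- function(core, X_new) {
  Xs <- apply_scaling(core$scaling, X_new)
  Xo <- apply_osc(core$osc, Xs)
  as.numeric(Xo %*% core$pls$coefficients)
}

#' Fit an OSC-PLS discriminant model to a gait table
#'
#' Centers and scales the gait variables, removes `n_osc` response-orthogonal
#' components ([osc_filter()]), and fits a NIPALS PLS1 model ([pls_fit()]) to
#' the centered -1/+1 group response. Two latent components are the default
#' model size.
#'
#' @param data A gait table: one row per observation (animal x trial) with a
#'   group column and numeric gait variables. Columns named in `id_cols` are
#'   carried as identifiers, not predictors.
#' @param n_components Number of PLS components (default 2).
#' @param n_osc Number of OSC components removed first (default 1).
#' @param group_col Name of the group column.
#' @param id_cols Identifier columns excluded from the predictors.
#' @return An object of class `oscpls`; see [tidy.oscpls()],
#'   [glance.oscpls()], [rank_loadings()], [variance_captured()],
#'   [autoplot.oscpls()].
#' @examples
#' tbl <- simulate_gait_table(gait_sim_config(n_per_group = c(5, 5),
#'                                            n_vars = 10), seed = 1)
#' fit <- oscpls_fit(tbl)
#' glance(fit)
#' @export
oscpls_fit <- function(data, n_components = 2, n_osc = 1,
                       group_col = "group",
                       id_cols = c("animal_id", "trial")) {
  xy <- gait_xy(data, group_col, id_cols)
  core <- oscpls_core(xy$X, xy$y, n_components, n_osc)
  structure(
    list(core = core, levels = xy$levels, y = xy$y, y_raw = xy$y_raw,
         animal = xy$animal, variables = colnames(core$osc$X),
         n_components = n_components, n_osc = n_osc,
         group_col = group_col, id_cols = id_cols,
         n_obs = nrow(xy$X)),
    class = "oscpls"
  )
}

#' Predict group membership from an OSC-PLS model
#'
#' Applies the training scaling and OSC filter to new rows and evaluates the
#' PLS regression vector. The continuous score is thresholded at the centered
#' response midpoint to yield a class label.
#'
#' @param object An `oscpls` model.
#' @param newdata A data frame with the training gait-variable columns.
#' @param ... Unused.
#' @return A tibble with `score` (continuous prediction on the centered -1/+1
#'   scale) and `class` (predicted group label).
#' @export
predict.oscpls <- function(object, newdata, ...) {
  score <- predict_core(object$core, newdata[, names(object$core$scaling$center),
                                             drop = FALSE])
  cut <- mean(range(c(-1, 1) - mean(object$y_raw)))
  tibble(score = score,
         class = ifelse(score > cut, object$levels[2], object$levels[1]))
}

#' Leave-one-out Q2 of an OSC-PLS model
#'
#' `Q2 = 1 - PRESS / TSS`, where PRESS accumulates squared leave-one-out
#' prediction errors (the scaling, OSC filter and PLS fit are re-estimated
#' inside every fold) and TSS is the total sum of squares of the centered
#' response. `Q2 <= 0` means the model predicts no better than the mean.
#'
#' @param data A gait table (see [oscpls_fit()]).
#' @inheritParams oscpls_fit
#' @return The Q2 scalar.
#' @export
q2_loo <- function(data, n_components = 2, n_osc = 1, group_col = "group",
                   id_cols = c("animal_id", "trial")) {
  xy <- gait_xy(data, group_col, id_cols)
  q2_loo_matrix(xy$X, xy$y, n_components, n_osc)
}

q2_loo_matrix <- function(X, y, n_components, n_osc) {
  n <- nrow(X)
  if (n < 3) abort("Leave-one-out Q2 needs at least 3 observations.")
  press <- 0
  for (i in seq_len(n)) {
    if (stats::sd(y[-i]) == 0) {
      # fold with a constant training response: the mean is the only model
      press <- press + (y[i] - mean(y[-i]))^2
      next
    }
    core <- withCallingHandlers(
      oscpls_core(X[-i, , drop = FALSE], y[-i] - mean(y[-i]),
                  n_components, n_osc),
      warning = function(w) invokeRestart("muffleWarning")
    )
    pred <- predict_core(core, X[i, , drop = FALSE]) + mean(y[-i])
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Root mean square error of prediction on held-out rows
#'
#' Applies a fitted model to test rows using the training scaling and returns
#' the RMSE between predicted scores and the test response on the centered
#' -1/+1 coding of the training fit.
#'
#' @param model An `oscpls` model.
#' @param newdata Held-out gait-table rows with the training columns.
#' @param group_col Group column of `newdata`.
#' @return The RMSEP scalar.
#' @export
rmsep <- function(model, newdata, group_col = model$group_col) {
  stopifnot(inherits(model, "oscpls"))
  y_test <- ifelse(as.character(newdata[[group_col]]) == model$levels[2],
                   1, -1) - mean(model$y_raw)
  pred <- predict_core(model$core,
                       newdata[, names(model$core$scaling$center),
                               drop = FALSE])
  sqrt(mean((y_test - pred)^2))
}

#' Ranked signed loadings of the predictive component
#'
#' Variables sorted by the magnitude of their loading on the first
#' (predictive) PLS component. The sign carries the direction of change in
#' the second-level ("mutant") group: positive means the variable is
#' increased where the response is coded +1.
#'
#' @param model An `oscpls` model.
#' @return A tibble: `variable`, `loading` (signed), `abs_loading`,
#'   `direction` (`"increased"`/`"decreased"` in the second group), `rank`.
#' @export
rank_loadings <- function(model) {
  stopifnot(inherits(model, "oscpls"))
  p1 <- model$core$pls$x_loadings[, 1]
  signed <- p1 * sign(model$core$pls$y_loadings[1])
  tibble(
    variable = model$variables,
    loading = signed,
    abs_loading = abs(signed),
    direction = ifelse(signed >= 0, "increased", "decreased")
  ) |>
    arrange(dplyr::desc(.data$abs_loading)) |>
    mutate(rank = dplyr::row_number())
}

#' Predictor variance captured per PLS component
#'
#' Fraction of the total sum of squares of the scaled (post-OSC) predictor
#' matrix explained by each component's rank-one reconstruction `t p'`, and
#' the cumulative fraction.
#'
#' @param model An `oscpls` model.
#' @return A tibble: `component`, `fraction`, `cumulative`.
#' @export
variance_captured <- function(model) {
  stopifnot(inherits(model, "oscpls"))
  ss_total <- sum(model$core$osc$X^2)
  ss_comp <- purrr::map_dbl(seq_len(model$n_components), function(k) {
    sum(model$core$pls$scores[, k]^2) *
      sum(model$core$pls$x_loadings[, k]^2)
  })
  tibble(component = seq_along(ss_comp), fraction = ss_comp / ss_total,
         cumulative = cumsum(ss_comp / ss_total))
}

# stratified animal-level train/test split: a fraction of animals per group
# goes to training; all trials of an animal stay together
split_animals <- function(animal, group, train_fraction) {
  info <- dplyr::distinct(tibble(animal = animal, group = group))
  train_animals <- info |>
    group_by(.data$group) |>
    dplyr::group_map(function(d, key) {
      n_train <- round(nrow(d) * train_fraction)
      if (n_train < 1 || n_train >= nrow(d)) {
        abort("A group is too small to stratify the train/test split.")
      }
      sample(d$animal, n_train)
    }) |>
    unlist()
  animal %in% train_animals
}

#' Permutation validation of an OSC-PLS gait model
#'
#' Internal cross-validation against a permutation null: in each repeat the
#' group labels are permuted (at animal level), a stratified 2/3-1/3
#' animal-level split is drawn, a full OSC-PLS model is fitted on the
#' training rows, and the training leave-one-out Q2 plus the test-set RMSEP
#' are recorded. A matched resampling *without* permutation runs in parallel,
#' and two-sample t tests compare the permuted and non-permuted Q2 and RMSEP
#' distributions. The full-data model's Q2/RMSEP are additionally located in
#' the permuted distributions as z-scores.
#'
#' @param data A gait table.
#' @param n_repeats Number of permutation repeats (default 100).
#' @param train_fraction Fraction of animals per group used for training.
#' @param seed Integer seed; fixed seed gives an identical report.
#' @param permute `"labels"` (permute group labels across animals, default)
#'   or `"rows"` (jointly permute predictor rows, an equivalent null).
#' @inheritParams oscpls_fit
#' @return An object of class `oscpls_validation`: per-repeat tibble
#'   (`repeats`), summary means, the two t tests, z-scores of the full model,
#'   and the settings used. See [tidy.oscpls_validation()] and
#'   [glance.oscpls_validation()].
#' @export
oscpls_validate <- function(data, n_repeats = 100, train_fraction = 2 / 3,
                            seed = 1, n_components = 2, n_osc = 1,
                            group_col = "group",
                            id_cols = c("animal_id", "trial"),
                            permute = c("labels", "rows")) {
  permute <- match.arg(permute)
  if (n_repeats < 2) abort("`n_repeats` must be >= 2.")
  xy <- gait_xy(data, group_col, id_cols)
  animal <- xy$animal
  info <- dplyr::distinct(tibble(animal = animal, group = xy$y_raw))
  one_run <- function(y_raw_run, X_run) {
    is_train <- split_animals(animal, y_raw_run, train_fraction)
    y_train <- y_raw_run[is_train]
    if (length(unique(y_train)) < 2) return(c(NA_real_, NA_real_))
    yc <- y_train - mean(y_train)
    core <- withCallingHandlers(
      oscpls_core(X_run[is_train, , drop = FALSE], yc, n_components, n_osc),
      warning = function(w) invokeRestart("muffleWarning")
    )
    q2 <- q2_loo_matrix(X_run[is_train, , drop = FALSE], yc,
                        n_components, n_osc)
    y_test <- y_raw_run[!is_train] - mean(y_train)
    pred <- predict_core(core, X_run[!is_train, , drop = FALSE])
    rmsep_val <- sqrt(mean((y_test - pred)^2))
    c(q2, rmsep_val)
  }
  res <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
      # permuted run: shuffle group labels across animals (or rows of X)
      if (permute == "labels") {
        perm_map <- setNames(sample(info$group), info$animal)
        y_perm <- unname(perm_map[as.character(animal)])
        Xp <- xy$X
      } else {
        y_perm <- xy$y_raw
        Xp <- xy$X[sample(nrow(xy$X)), , drop = FALSE]
      }
      perm <- one_run(y_perm, Xp)
      nonperm <- one_run(xy$y_raw, xy$X)
      tibble(repeat_i = rep_i,
             q2_perm = perm[1], rmsep_perm = perm[2],
             q2 = nonperm[1], rmsep = nonperm[2])
    })
  })
  full_model <- oscpls_fit(data, n_components, n_osc, group_col, id_cols)
  full_q2 <- q2_loo(data, n_components, n_osc, group_col, id_cols)
  tt_q2 <- stats::t.test(res$q2, res$q2_perm)
  tt_rmsep <- stats::t.test(res$rmsep, res$rmsep_perm)
  structure(
    list(
      repeats = res,
      q2 = full_q2,
      rmsep_mean = mean(res$rmsep, na.rm = TRUE),
      q2_mean = mean(res$q2, na.rm = TRUE),
      q2_perm_mean = mean(res$q2_perm, na.rm = TRUE),
      rmsep_perm_mean = mean(res$rmsep_perm, na.rm = TRUE),
      t_q2 = tibble(t = unname(tt_q2$statistic), df = unname(tt_q2$parameter),
                    p = tt_q2$p.value),
      t_rmsep = tibble(t = unname(tt_rmsep$statistic),
                       df = unname(tt_rmsep$parameter),
                       p = tt_rmsep$p.value),
      z_q2 = (full_q2 - mean(res$q2_perm, na.rm = TRUE)) /
        stats::sd(res$q2_perm, na.rm = TRUE),
      model = full_model,
      n_repeats = n_repeats, train_fraction = train_fraction,
      seed = seed, permute = permute
    ),
    class = "oscpls_validation"
  )
}
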