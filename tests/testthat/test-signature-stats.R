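test_that("intensity normalization is linear, clipped and idempotent", {
  expect_equal(normalize_intensity(100, 10, 100), 1)
  expect_equal(normalize_intensity(10, 10, 100), 0)
  expect_equal(normalize_intensity(55, 10, 100), 0.5)
  expect_equal(normalize_intensity(5, 10, 100), 0)    # clips below
  expect_equal(normalize_intensity(200, 10, 100), 1)  # clips above
  expect_error(normalize_intensity(50, 100, 100), "exceed")
  # idempotent once on the [0, 1] scale with reference 1, background 0
  x <- normalize_intensity(c(20, 60, 90), 10, 100)
  expect_equal(normalize_intensity(x, 0, 1), x)
})

test_that("FG gating labels the rectangular gates and rejects overlap", {
  df <- tibble::tibble(fg = c(0.8, 0.3, 0.6), soma = c(300, 700, 600))
  out <- gate_fg(df)
  # third point: FG in the high range but soma too large for either gate
  expect_equal(out$fg_gate, c("FG-high", "FG-low", "ungated"))
  expect_error(fg_gate_config(fg_hi = 0.3, fg_lo_min = 0.5), "Overlapping")
  expect_error(fg_gate_config(soma_small = 500, soma_large = 400),
               "Overlapping")
})

test_that("default gates recover >= 95% of a synthetic bimodal population", {
  pop <- simulate_marker_population(n_gamma = 200, n_alpha = 200, seed = 5)
  gated <- gate_fg(pop)
  truth <- ifelse(pop$population == "gamma", "FG-high", "FG-low")
  agree <- mean(gated$fg_gate == truth)
  expect_gte(agree, 0.95)
})

test_that("pearson_corr matches its definition and flags degeneracy", {
  x <- 1:10
  expect_equal(pearson_corr(x, x), 1)
  expect_equal(pearson_corr(x, -x), -1)
  # invariance under positive affine maps, sign flip under negative slope
  withr::with_seed(6, {
    a <- rnorm(30); b <- rnorm(30)
    r <- pearson_corr(a, b)
    expect_equal(pearson_corr(2 * a + 3, b), r)
    expect_equal(pearson_corr(-2 * a + 3, b), -r)
  })
  expect_warning(r0 <- pearson_corr(rep(1, 5), 1:5), "variance")
  expect_true(is.na(r0))
  expect_error(pearson_corr(1:2, 1:2), "3")
})

test_that("correlated marker intensities show the expected association", {
  pop <- simulate_marker_population(n_gamma = 60, n_alpha = 33,
                                    marker_corr = 0.75, seed = 8)
  r <- pearson_corr(pop$marker1, pop$marker2)
  # bimodal population + within-group correlation: strong overall r
  expect_gt(r, 0.8)
})

test_that("group_compare is a pooled-variance Student t test", {
  gc <- group_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gc$t, -3.674, tolerance = 1e-3)
  expect_equal(gc$df, 4)
  expect_equal(gc$p, 0.0214, tolerance = 1e-2)
  expect_equal(gc$stars, "*")
  # brute-force oracle on random vectors
  withr::with_seed(7, {
    for (i in 1:5) {
      a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), mean = 0.5)
      gc <- group_compare(a, b)
      na <- length(a); nb <- length(b)
      sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
      t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
      expect_equal(gc$t, t_manual, tolerance = 1e-10)
      expect_equal(gc$p, 2 * pt(-abs(t_manual), na + nb - 2),
                   tolerance = 1e-10)
      expect_equal(gc$sem_a, sd(a) / sqrt(na))
    }
  })
  # identical groups: t = 0, p = 1
  gc0 <- group_compare(c(2, 2, 2), c(2, 2, 2))
  expect_equal(gc0$t, 0)
  expect_equal(gc0$p, 1)
  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("signature summary separates preset-like groups and not identical ones", {
  withr::with_seed(10, {
    gamma <- tibble::tibble(
      group = "gamma", rheobase_pa = rnorm(20, 220, 40),
      mean_ff_hz = rnorm(20, 50, 6), gain_hz_na = rnorm(20, 161, 20)
    )
    alpha <- tibble::tibble(
      group = "alpha", rheobase_pa = rnorm(20, 909, 120),
      mean_ff_hz = rnorm(20, 20, 4), gain_hz_na = rnorm(20, 33, 8)
    )
    ss <- signature_summary(dplyr::bind_rows(gamma, alpha), n_perm = 199)
    expect_gt(ss$separation_index, 1)
    expect_lt(ss$perm_p, 0.01)
    # two identical groups: index 0
    same <- dplyr::bind_rows(
      dplyr::mutate(gamma, group = "a"),
      dplyr::mutate(gamma, group = "b")
    )
    ss0 <- signature_summary(same, n_perm = 0)
    expect_lt(ss0$separation_index, 0.5)
    g <- glance(ss)
    expect_named(g, c("separation_index", "perm_p", "n_perm", "degenerate"))
  })
})
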