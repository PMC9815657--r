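test_that("condition summaries aggregate trials -> animal -> group", {
  scores <- tibble::tibble(
    animal_id = c("a1", "a1", "a2", "a2"),
    group = "control", condition = "beam_30mm",
    trial = c(1, 2, 1, 2), misses = c(2, 4, 0, 0), steps = 40
  )
  s <- summarize_condition(scores, "beam_30mm")
  expect_equal(s$mean, mean(c(3, 0)))  # animal means 3 and 0
  expect_equal(s$n_animals, 2)
  # all-zero misses: mean and SEM zero
  z <- dplyr::mutate(scores, misses = 0)
  sz <- summarize_condition(z, "beam_30mm")
  expect_equal(sz$mean, 0)
  expect_equal(sz$sem, 0)
  expect_error(summarize_condition(scores, "ladder"), "not present")
})

test_that("duplicating every trial leaves all summaries unchanged", {
  scores <- simulate_behavior_counts(seed = 3)
  doubled <- dplyr::bind_rows(scores, dplyr::mutate(scores, trial = trial + 100))
  for (cc in c("beam_30mm", "ladder")) {
    expect_equal(summarize_condition(doubled, cc),
                 summarize_condition(scores, cc))
  }
})

test_that("fold change reproduces the published ratios from the fixture", {
  bm <- behavior_means()
  expect_equal(fold_change(bm, "beam_30mm", mutant = "err23cko"), 18.0)
  expect_equal(fold_change(bm, "beam_25mm", mutant = "err23cko"), 55.0)
  expect_equal(fold_change(bm, "beam_20mm", mutant = "err23cko"), 79.0)
  expect_equal(fold_change(bm, "ladder", mutant = "err23cko"), 7.12)
  # equal means -> 1; zero control mean -> flagged NA
  eq <- tibble::tibble(condition = "c", group = c("control", "m"),
                       mean = c(3, 3))
  expect_equal(fold_change(eq, "c"), 1)
  z <- tibble::tibble(condition = "c", group = c("control", "m"),
                      mean = c(0, 3))
  expect_warning(fc <- fold_change(z, "c"), "undefined")
  expect_true(is.na(fc))
})

test_that("fold change is scale invariant", {
  scores <- simulate_behavior_counts(seed = 4)
  s1 <- summarize_condition(scores, "beam_25mm")
  s2 <- dplyr::mutate(s1, mean = mean * 7)
  expect_equal(fold_change(s2, "beam_25mm", mutant = "err23cko"),
               fold_change(s1, "beam_25mm", mutant = "err23cko"))
})

test_that("simulated counts are calibrated to the fixture means", {
  scores <- simulate_behavior_counts(seed = 1)
  bm <- behavior_means()
  for (cc in unique(bm$condition)) {
    s <- summarize_condition(scores, cc)
    for (g in s$group) {
      target <- bm$mean[bm$condition == cc & bm$group == g]
      got <- s$mean[s$group == g]
      tol <- 2 * max(s$sem[s$group == g], 0.5)
      expect_lt(abs(got - target), max(tol, 0.75))
    }
  }
  # mean 0 -> all counts 0
  cfg0 <- behavior_sim_config(
    group_means = tibble::tibble(condition = "c", group = c("g1", "g2"),
                                 mean = 0),
    n_animals = 3
  )
  expect_true(all(simulate_behavior_counts(cfg0, seed = 2)$misses == 0))
})

test_that("large dispersion approaches the Poisson variance", {
  cfg <- behavior_sim_config(
    group_means = tibble::tibble(condition = "c", group = "g", mean = 10),
    dispersion = 1e9, trials_per_animal = 400, n_animals = 5
  )
  x <- simulate_behavior_counts(cfg, seed = 6)$misses
  expect_equal(var(x) / mean(x), 1, tolerance = 0.1)
})

test_that("group comparison on animal means detects the planted difference", {
  scores <- simulate_behavior_counts(seed = 2)
  gc <- compare_conditions(scores, "beam_20mm")
  expect_lt(gc$p, 0.001)
  expect_s3_class(gc, "group_comparison")
  td <- tidy(gc)
  expect_equal(nrow(td), 2)
})
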