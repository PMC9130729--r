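test_that("a zero-rate control scenario keeps the initial cohort", {
  spec <- scenario_spec("frozen", replicates = 3, p0 = 100)
  summ <- run_scenario(spec, rates = rate_set(0, 0, 0, 0, 0, 0),
                       master_seed = 1)
  expect_true(all(summ$replicates$neurons == 46))
  expect_true(all(summ$replicates$divisions == 1))
})

test_that("duplicate scenario names are refused", {
  specs <- list(scenario_spec("a", replicates = 1, p0 = 10),
                scenario_spec("a", replicates = 1, p0 = 10))
  expect_error(run_battery(specs), "duplicate scenario names: a")
})

test_that("battery results are invariant to scenario ordering", {
  s1 <- scenario_spec("ctrl", replicates = 3, p0 = 100)
  s2 <- scenario_spec("trained", schedule = training_windows("12-30"),
                      replicates = 3, p0 = 100)
  fwd <- run_battery(list(s1, s2), master_seed = 7)
  rev <- run_battery(list(s2, s1), master_seed = 7)
  expect_equal(fwd$ctrl$replicates, rev$ctrl$replicates)
  expect_equal(fwd$trained$replicates, rev$trained$replicates)
})

test_that("increase ratio is 1 for identical conditions and guards inputs", {
  spec <- scenario_spec("x", replicates = 5, p0 = 100)
  summ <- run_scenario(spec, master_seed = 3)
  r <- neuronal_increase_ratio(summ, summ, n_boot = 100, seed = 1)
  expect_equal(r$ratio, 1.0)
  expect_length(r$normalized, 5)

  with_death <- run_scenario(scenario_spec("y", death = death_model(),
                                           replicates = 2, p0 = 50),
                             master_seed = 1)
  expect_error(neuronal_increase_ratio(with_death, summ), "death setting")
  long <- run_scenario(scenario_spec("z", horizon = 40, replicates = 2,
                                     p0 = 50), master_seed = 1)
  expect_error(neuronal_increase_ratio(long, summ), "horizon")
})

test_that("training raises the endpoint neuron count", {
  ctrl <- run_scenario(scenario_spec("ctrl", replicates = 8, p0 = 500),
                       master_seed = 11)
  trained <- run_scenario(scenario_spec("tr", replicates = 8, p0 = 500,
                                        schedule = training_windows("12-30")),
                          master_seed = 11)
  r <- neuronal_increase_ratio(trained, ctrl, n_boot = 200, seed = 2)
  expect_gt(r$ratio, 1)
  expect_gt(r$ci[1], 1)
})

test_that("Welch comparison matches the hand-computed statistic", {
  # fixed small samples; Welch t = (mx - my) / sqrt(sx2/nx + sy2/ny)
  x <- c(21.1, 19.8, 23.4, 20.2, 22.5)
  y <- c(18.0, 17.2, 19.5, 16.8)
  mx <- mean(x); my <- mean(y)
  vx <- var(x) / 5; vy <- var(y) / 4
  t_hand <- (mx - my) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 4 + vy^2 / 3)
  w <- welch_compare(x, y)
  expect_equal(w$statistic, t_hand, tolerance = 1e-10)
  expect_equal(w$df, df_hand, tolerance = 1e-10)
  expect_equal(w$p_value, 2 * stats::pt(-abs(t_hand), df_hand),
               tolerance = 1e-10)
})

test_that("permutation test separates shifted samples and not identical ones", {
  set.seed(31)
  x <- rnorm(20)
  same <- permutation_test(x, x, n_perm = 500, seed = 1)
  expect_gt(same$p_value, 0.5)
  shifted <- permutation_test(x, x + 3, n_perm = 500, seed = 1)
  expect_lt(shifted$p_value, 0.01)
})

test_that("long-run additivity is false for a frozen population", {
  lr <- long_run_additivity(rates = rate_set(0, 0, 0, 0, 0, 0),
                            p0 = 100, horizon = 60, replicates = 3,
                            master_seed = 5)
  expect_false(lr$additive)
  expect_equal(lr$mean_n_day30, lr$mean_n_horizon)
})

test_that("seed derivation is stable, name-sensitive and in integer range", {
  expect_identical(derive_seed(7, "control", 1), derive_seed(7, "control", 1))
  expect_false(derive_seed(7, "control", 1) == derive_seed(7, "trained", 1))
  expect_false(derive_seed(7, "control", 1) == derive_seed(8, "control", 1))
  s <- derive_seed(2^30, paste(rep("x", 100), collapse = ""), 10^6)
  expect_true(s >= 1 && s <= 2147483647)
})
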