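co1000 <- init_labeled_cohort(1000, default_proportions())

test_that("mean-field trajectory starts at the cohort and is exact at t=0", {
  et <- expected_trajectory(co1000, reference_rates())
  expect_equal(unlist(et$df[1, c("r", "o", "n")]),
               c(r = 500, o = 1040, n = 460))
})

test_that("all-zero rates give a constant trajectory", {
  et <- expected_trajectory(co1000, rate_set(0, 0, 0, 0, 0, 0), horizon = 50)
  expect_true(all(et$df$o == 1040) && all(et$df$n == 460))
  expect_equal(expected_divisions(co1000, rate_set(0, 0, 0, 0, 0, 0)), 1.0)
})

test_that("30-day control endpoints match the closed-form solution", {
  # one interval, beta = 0.028, o* = 125: hand-evaluated closed form
  e <- exp(-0.028 * 30)
  o30 <- 125 + (1040 - 125) * e
  int_o <- 125 * 30 + (1040 - 125) * (1 - e) / 0.028
  n30 <- 460 + (0.018 + 2 * 0.004 + 0.013) * int_o
  et <- expected_trajectory(co1000, reference_rates())
  expect_equal(tail(et$df$o, 1), o30, tolerance = 1e-10)
  expect_equal(tail(et$df$n, 1), n30, tolerance = 1e-10)
  expect_equal(et$int_o, int_o, tolerance = 1e-10)
  # neuron fraction ~56.6% and divisions/lineage ~1.73
  expect_equal(n30 / (500 + o30 + n30), 0.566, tolerance = 0.001)
  expect_equal(expected_divisions(co1000, reference_rates()),
               1 + (0.007 * 500 * 30 + 0.028 * int_o) / 1000,
               tolerance = 1e-10)
  expect_equal(expected_divisions(co1000, reference_rates()), 1.73,
               tolerance = 0.001)
})

test_that("oracle agrees with an independent numerical integrator", {
  skip_if_not_installed("deSolve")
  cases <- list(
    list(rates = reference_rates(), schedule = NULL),
    list(rates = reference_rates(), schedule = training_windows("12-30")),
    list(rates = reference_rates(), schedule = training_windows("3-14")))
  set.seed(19)
  cases <- c(cases, lapply(1:3, function(i) {
    list(rates = random_stable_rates(lambda = 3),
         schedule = training_schedule(c(5, 20), lambda = 3))
  }))
  co <- init_labeled_cohort(100, default_proportions())
  for (cs in cases) {
    et <- expected_trajectory(co, cs$rates, cs$schedule)
    num <- ode_numeric(co, cs$rates, cs$schedule)
    # 1e-8 relative on a cohort of ~100 cells
    expect_lt(max(abs(et$df$o - num$o)), 1e-6)
    expect_lt(max(abs(et$df$n - num$n)), 1e-6)
  }
})

test_that("training raises expected divisions and neurons monotonically", {
  base <- expected_divisions(co1000, reference_rates())
  lam3 <- expected_divisions(co1000, reference_rates(),
                             training_schedule(c(0, 30), lambda = 3))
  expect_gt(lam3, base)
  n_base <- tail(expected_trajectory(co1000, reference_rates())$df$n, 1)
  n_lam <- tail(expected_trajectory(co1000, reference_rates(),
                                    training_schedule(c(0, 30),
                                                      lambda = 3))$df$n, 1)
  expect_gt(n_lam, n_base)
})

test_that("an unstable regime is reported with the offending interval", {
  # stable at baseline (beta = 0.004) but not under a threefold factor
  r_unstable3 <- rate_set(0.007, 0.017, 0.03, 0.018, 0.004, 0.013)
  expect_error(
    expected_trajectory(co1000, r_unstable3, training_windows("12-30")),
    "unstable regime on \\[12, 30\\)")
})

test_that("deterministic death accounting splits faced and unfaced cohorts", {
  dm <- death_model(p_death = 0.550, checkpoint_age = 15)
  alive <- expected_alive_neurons(co1000, reference_rates(), death = dm)
  et <- expected_trajectory(co1000, reference_rates(), horizon = 30)
  n30 <- tail(et$df$n, 1)
  n15 <- et$df$n[et$df$day == 15]
  # neurons born by day 15 have faced the draw by day 30; later ones not
  expect_equal(alive, 0.45 * n15 + (n30 - n15), tolerance = 1e-8)
  # p_death = 0 changes nothing
  expect_equal(expected_alive_neurons(co1000, reference_rates(),
                                      death = death_model(p_death = 0)),
               n30, tolerance = 1e-8)
})
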