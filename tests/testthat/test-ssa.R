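co1000 <- init_labeled_cohort(1000, default_proportions())
co_small <- init_labeled_cohort(100, default_proportions())

test_that("no reactions means nothing happens", {
  sim <- simulate_cohort(co_small, rate_set(0, 0, 0, 0, 0, 0),
                         horizon = 30, seed = 1)
  expect_true(all(sim$trajectory$r == co_small$r0))
  expect_true(all(sim$trajectory$o == co_small$o0))
  expect_true(all(sim$trajectory$n == co_small$n0))
  expect_identical(nrow(sim$events), 0L)
  expect_equal(divisions_per_lineage(sim$ledger), 1.0)
})

test_that("same seed and configuration give bit-identical results", {
  a <- simulate_cohort(co_small, reference_rates(),
                       training_windows("12-30"), death_model(),
                       horizon = 30, seed = 99)
  b <- simulate_cohort(co_small, reference_rates(),
                       training_windows("12-30"), death_model(),
                       horizon = 30, seed = 99)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$events, b$events)
  expect_identical(a$ledger, b$ledger)
})

test_that("a unit learning factor is the identity on the event stream", {
  lam1 <- simulate_cohort(co_small, reference_rates(),
                          training_schedule(c(3, 14), lambda = 1),
                          horizon = 30, seed = 5)
  ctrl <- simulate_cohort(co_small, reference_rates(), NULL,
                          horizon = 30, seed = 5)
  expect_identical(lam1$trajectory, ctrl$trajectory)
  expect_identical(lam1$events, ctrl$events)
})

test_that("the labeled reservoir is never consumed", {
  set.seed(3)
  for (i in 1:5) {
    rr <- random_stable_rates(lambda = 3)
    sch <- if (i %% 2 == 0) training_schedule(c(2, 9), lambda = 3) else NULL
    sim <- simulate_cohort(co_small, rr, sch, horizon = 20,
                           seed = 100 + i)
    expect_true(all(sim$trajectory$r == co_small$r0))
  }
})

test_that("without death the labeled neuron count never decreases", {
  set.seed(4)
  for (i in 1:5) {
    sim <- simulate_cohort(co_small, random_stable_rates(), horizon = 30,
                           seed = 200 + i)
    expect_true(all(diff(sim$trajectory$n) >= 0))
  }
})

test_that("ensemble means track the mean-field oracle at day 30", {
  n_rep <- 20
  ends <- t(vapply(seq_len(n_rep), function(i) {
    sim <- simulate_cohort(co1000, reference_rates(), horizon = 30,
                           seed = 1000 + i)
    counts_at(sim, 30)
  }, numeric(3)))
  exp30 <- predict(expected_trajectory(co1000, reference_rates()), 30)
  for (col in c("o", "n")) {
    se <- stats::sd(ends[, col]) / sqrt(n_rep)
    expect_lt(abs(mean(ends[, col]) - exp30[[col]]), 3 * se)
  }
  expect_true(all(ends[, "r"] == 500))
})

test_that("mean divisions per lineage grows with the horizon", {
  s15 <- simulate_cohort(co_small, reference_rates(), horizon = 15, seed = 8)
  s60 <- simulate_cohort(co_small, reference_rates(), horizon = 60, seed = 8)
  expect_gt(divisions_per_lineage(s60$ledger),
            divisions_per_lineage(s15$ledger))
  expect_gte(divisions_per_lineage(s15$ledger), 1)
})

test_that("the checkpoint kills nobody at p_death = 0 and everybody at 1", {
  pair0 <- lapply(c(TRUE, FALSE), function(on) {
    simulate_cohort(co_small, reference_rates(),
                    death = death_model(p_death = 0, enabled = on),
                    horizon = 30, seed = 12)
  })
  expect_equal(survival_fraction(pair0[[1]], pair0[[2]]), 100)

  # zero rates: the initial neurons all face the day-15 checkpoint and die
  dead <- simulate_cohort(co_small, rate_set(0, 0, 0, 0, 0, 0),
                          death = death_model(p_death = 1),
                          horizon = 30, seed = 13)
  alive <- simulate_cohort(co_small, rate_set(0, 0, 0, 0, 0, 0),
                           horizon = 30, seed = 13)
  expect_equal(survival_fraction(dead, alive), 0)
  expect_equal(counts_at(dead, 14)[["n"]], co_small$n0)  # not before day 15
})

test_that("survival is undefined without neurons, not a crash", {
  co_no_n <- init_labeled_cohort(50, division_proportions(1, 0, 0, 0))
  a <- simulate_cohort(co_no_n, rate_set(0, 0, 0, 0, 0, 0),
                       death = death_model(), horizon = 30, seed = 1)
  b <- simulate_cohort(co_no_n, rate_set(0, 0, 0, 0, 0, 0),
                       horizon = 30, seed = 1)
  expect_warning(sf <- survival_fraction(a, b), "undefined")
  expect_true(is.na(sf))
})

test_that("rescue lowers checkpoint mortality inside a training window", {
  # all checkpoints (day 15) fall inside the 12-30 window: death 0.55 -> 0.055
  n_rep <- 40
  surv <- function(sch) {
    vapply(seq_len(n_rep), function(i) {
      sim <- simulate_cohort(co_small, rate_set(0, 0, 0, 0, 0, 0),
                             schedule = sch, death = death_model(),
                             horizon = 30, seed = 500 + i)
      counts_at(sim, 30)[["n"]]
    }, numeric(1))
  }
  rescued <- surv(training_windows("12-30"))
  unrescued <- surv(NULL)
  expect_gt(mean(rescued), mean(unrescued))
  expect_equal(mean(rescued) / co_small$n0, 1 - 0.055, tolerance = 0.05)
  expect_equal(mean(unrescued) / co_small$n0, 1 - 0.550, tolerance = 0.10)
})

test_that("stochastic census reproduces the analytic division proportions", {
  est <- estimate_division_proportions(reference_rates(), r_init = 4000,
                                       min_divisions = 10000, seed = 21)
  ana <- division_proportions_analytic(reference_rates())
  se <- attr(est, "se")
  for (k in c("d1", "d3", "d4", "d5")) {
    i <- match(k, c("d1", "d3", "d4", "d5"))
    expect_lt(abs(est[[k]] - ana[[k]]), 3 * se[i] + 1e-9)
  }
  expect_gte(attr(est, "n_divisions"), 10000)
})

test_that("census with only reservoir seeding yields pure type-1 divisions", {
  est <- estimate_division_proportions(rate_set(0.01, 0.02, 0, 0, 0, 0.01),
                                       r_init = 500, min_divisions = 500,
                                       seed = 2)
  expect_equal(unlist(est)[c("d1", "d3", "d4", "d5")],
               c(d1 = 1, d3 = 0, d4 = 0, d5 = 0))
})

test_that("a census with too few events warns", {
  expect_warning(
    estimate_division_proportions(reference_rates(), r_init = 50,
                                  duration = 2, seed = 3),
    "unreliable")
})

test_that("invalid schedules are refused before simulating", {
  expect_error(training_schedule(rbind(c(5, 3))), "start < end")
  expect_error(training_schedule(rbind(c(0, 10), c(8, 20))), "overlap")
  expect_error(training_schedule(c(-1, 5)), ">= 0")
  expect_error(simulate_cohort(co_small, reference_rates(),
                               training_schedule(c(40, 50)), horizon = 30),
               "beyond the horizon")
  expect_error(simulate_cohort(co_small, reference_rates(), horizon = 0),
               "positive")
})
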