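#' Division proportions used to seed labeled cohorts
#'
#' The steady-state census of the reference rates, rounded to two
#' decimals: half of all divisions are reservoir seedings, with the
#' remainder split between amplifying (0.11), asymmetric neurogenic (0.32)
#' and terminal symmetric neurogenic (0.07) divisions. These are the
#' proportions used to build labeled cohorts in the default scenarios; the
#' unrounded analytic values are available from
#' [division_proportions_analytic()].
#'
#' @return A [division_proportions()] object (0.5, 0.11, 0.32, 0.07).
#' @export
default_proportions <- function() {
  division_proportions(d1 = 0.5, d3 = 0.11, d4 = 0.32, d5 = 0.07)
}

#' Define a named simulation scenario
#'
#' @param name Unique scenario name.
#' @param horizon Days to simulate. Default 30.
#' @param schedule A [training_schedule()] or `NULL` (control).
#' @param death A [death_model()]; default disabled.
#' @param rate_multiplier Multiplier on the division/differentiation rates
#'   k1, k3, k4, k5, k6 (never k2); 2 gives the "doubled rates" condition.
#' @param replicates Number of stochastic replicates. Default 20.
#' @param p0 Labeling divisions for the cohort. Default 1000.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, horizon = 30, schedule = NULL,
                          death = no_death(), rate_multiplier = 1,
                          replicates = 20, p0 = 1000) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(replicates) || replicates < 1) {
    stop("replicates must be >= 1")
  }
  if (!is.numeric(rate_multiplier) || rate_multiplier <= 0) {
    stop("rate_multiplier must be positive")
  }
  structure(list(name = name, horizon = horizon, schedule = schedule,
                 death = death, rate_multiplier = rate_multiplier,
                 replicates = as.integer(replicates), p0 = p0),
            class = "scenario_spec")
}

scaled_rates <- function(rates, mult) {
  if (mult == 1) return(rates)
  rate_set(k1 = rates$k1 * mult, k2 = rates$k2, k3 = rates$k3 * mult,
           k4 = rates$k4 * mult, k5 = rates$k5 * mult, k6 = rates$k6 * mult)
}

#' Run one scenario
#'
#' Simulates `replicates` independent cohorts and collects per-replicate
#' endpoints: alive labeled neurons at the horizon, labeled neuron
#' fraction `n / (r + o + n)`, and mean divisions per lineage.
#'
#' @param spec A [scenario_spec()].
#' @param rates Baseline [rate_set()]; the scenario's `rate_multiplier` is
#'   applied to k1, k3-k6.
#' @param proportions Division proportions for cohort initialisation.
#' @param master_seed Integer master seed; replicate seeds derive from it
#'   and the scenario name via [derive_seed()].
#' @return An object of class `scenario_summary`: `name`, `spec`,
#'   `replicates` (data.frame `replicate`, `seed`, `neurons`, `fraction`,
#'   `divisions`), and condition means/SDs.
#' @export
run_scenario <- function(spec, rates = default_rates(),
                         proportions = default_proportions(),
                         master_seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  rr <- scaled_rates(rates, spec$rate_multiplier)
  cohort <- init_labeled_cohort(spec$p0, proportions)
  n_rep <- spec$replicates
  seeds <- vapply(seq_len(n_rep),
                  function(i) derive_seed(master_seed, spec$name, i),
                  integer(1))
  neurons <- fraction <- divisions <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sim <- simulate_cohort(cohort, rr, schedule = spec$schedule,
                           death = spec$death, horizon = spec$horizon,
                           seed = seeds[i])
    cts <- counts_at(sim, spec$horizon)
    neurons[i] <- cts[["n"]]
    fraction[i] <- cts[["n"]] / sum(cts)
    divisions[i] <- divisions_per_lineage(sim$ledger)
  }
  structure(list(
    name = spec$name, spec = spec, master_seed = master_seed,
    replicates = data.frame(replicate = seq_len(n_rep), seed = seeds,
                            neurons = neurons, fraction = fraction,
                            divisions = divisions),
    mean_neurons = mean(neurons), sd_neurons = stats::sd(neurons),
    mean_fraction = mean(fraction), sd_fraction = stats::sd(fraction),
    mean_divisions = mean(divisions), sd_divisions = stats::sd(divisions)),
    class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s' (%d replicates, horizon %g d): neurons %.1f +/- %.1f, fraction %.3f, divisions/lineage %.3f\n",
    x$name, nrow(x$replicates), x$spec$horizon,
    x$mean_neurons, x$sd_neurons, x$mean_fraction, x$mean_divisions))
  invisible(x)
}

#' The default scenario battery
#'
#' Control and the two training periods (3-14 and 12-30 days
#' post-labeling), each with and without the neuronal-death checkpoint,
#' plus the doubled-learning-factor and doubled-rates variants (with
#' death) and a 500-day control long run with death.
#'
#' @param replicates Replicates per scenario. Default 20.
#' @param p0 Labeling divisions per cohort. Default 1000.
#' @param lambda Learning factor for the trained scenarios. Default 3.
#' @return Named list of [scenario_spec()] objects.
#' @export
default_battery <- function(replicates = 20, p0 = 1000, lambda = 3) {
  dm <- death_model()
  sch <- function(period, lam = lambda) training_windows(period, lambda = lam)
  specs <- list(
    scenario_spec("control", replicates = replicates, p0 = p0),
    scenario_spec("trained_3-14", schedule = sch("3-14"),
                  replicates = replicates, p0 = p0),
    scenario_spec("trained_12-30", schedule = sch("12-30"),
                  replicates = replicates, p0 = p0),
    scenario_spec("control+death", death = dm,
                  replicates = replicates, p0 = p0),
    scenario_spec("trained_3-14+death", schedule = sch("3-14"), death = dm,
                  replicates = replicates, p0 = p0),
    scenario_spec("trained_12-30+death", schedule = sch("12-30"), death = dm,
                  replicates = replicates, p0 = p0),
    scenario_spec("2xlambda_12-30+death", schedule = sch("12-30", 2 * lambda),
                  death = dm, replicates = replicates, p0 = p0),
    scenario_spec("2xk_12-30+death", schedule = sch("12-30"), death = dm,
                  rate_multiplier = 2, replicates = replicates, p0 = p0),
    scenario_spec("control_500d+death", horizon = 500, death = dm,
                  replicates = replicates, p0 = p0))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Run a battery of scenarios
#'
#' Results are deterministic given the master seed and invariant to the
#' order of the specs (seeds derive from scenario names).
#'
#' @param specs List of [scenario_spec()] objects with unique names.
#' @inheritParams run_scenario
#' @return Named list of [run_scenario()] summaries, class
#'   `scenario_battery`.
#' @export
run_battery <- function(specs, rates = default_rates(),
                        proportions = default_proportions(),
                        master_seed = 1) {
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate scenario names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  out <- lapply(specs, run_scenario, rates = rates,
                proportions = proportions, master_seed = master_seed)
  names(out) <- nm
  structure(out, class = "scenario_battery", master_seed = master_seed)
}

#' Learning-induced neuronal increase ratio
#'
#' Ratio of mean endpoint labeled-neuron counts, trained over control,
#' with a bootstrap interval over replicates. The control-normalised
#' per-replicate counts are also returned, since period contrasts can be
#' read either on raw counts or on counts normalised to the control mean.
#'
#' @param trained,control `scenario_summary` objects sharing horizon and
#'   death setting.
#' @param n_boot Bootstrap resamples. Default 1000.
#' @param seed Optional integer seed for the bootstrap.
#' @return List with `ratio`, `ci` (2.5/97.5 percentiles), and
#'   `normalized` (trained endpoints divided by the control mean).
#' @export
neuronal_increase_ratio <- function(trained, control, n_boot = 1000,
                                    seed = NULL) {
  stopifnot(inherits(trained, "scenario_summary"),
            inherits(control, "scenario_summary"))
  if (trained$spec$horizon != control$spec$horizon) {
    stop("trained and control scenarios must share the same horizon")
  }
  if (trained$spec$death$enabled != control$spec$death$enabled) {
    stop("trained and control scenarios must share the same death setting")
  }
  if (control$mean_neurons == 0) {
    stop("control mean neuron count is zero; ratio undefined")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  xt <- trained$replicates$neurons
  xc <- control$replicates$neurons
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(sample(xt, replace = TRUE)) / mean(sample(xc, replace = TRUE))
  }, numeric(1))
  list(ratio = mean(xt) / mean(xc),
       ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       boot = boot,
       normalized = xt / mean(xc))
}

#' Long-run additivity of adult neurogenesis
#'
#' Runs the control condition with the death checkpoint over a long
#' horizon (default 500 days) and asks whether the ensemble-mean alive
#' labeled neuron count at the end exceeds the day-30 value, i.e. whether
#' neuronal addition keeps outpacing checkpoint death.
#'
#' @param rates A [rate_set()].
#' @param proportions Division proportions for the cohort.
#' @param p0 Labeling divisions. Default 1000.
#' @param horizon Long-run horizon in days. Default 500.
#' @param death A [death_model()]; must be enabled.
#' @param replicates Number of replicates. Default 20.
#' @param master_seed Integer master seed.
#' @return List with `additive` (logical), `mean_n_day30`,
#'   `mean_n_horizon`, and `trajectory` (ensemble-mean daily counts).
#' @export
long_run_additivity <- function(rates = default_rates(),
                                proportions = default_proportions(),
                                p0 = 1000, horizon = 500,
                                death = death_model(), replicates = 20,
                                master_seed = 1) {
  cohort <- init_labeled_cohort(p0, proportions)
  days <- seq(0, horizon)
  acc <- matrix(0, nrow = length(days), ncol = 3,
                dimnames = list(NULL, c("r", "o", "n")))
  n30 <- numeric(replicates)
  for (i in seq_len(replicates)) {
    sim <- simulate_cohort(cohort, rates, death = death, horizon = horizon,
                           seed = derive_seed(master_seed, "long_run", i))
    tr <- sim$trajectory[seq_along(days), ]
    acc <- acc + as.matrix(tr[, c("r", "o", "n")])
    n30[i] <- counts_at(sim, 30)[["n"]]
  }
  acc <- acc / replicates
  traj <- data.frame(day = days, acc)
  list(additive = traj$n[traj$day == horizon] > mean(n30),
       mean_n_day30 = mean(n30),
       mean_n_horizon = traj$n[traj$day == horizon],
       trajectory = traj)
}
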