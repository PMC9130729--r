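#' Mean-field expectation of the labeled cohort
#'
#' The expected labeled counts obey a linear system on every interval of
#' constant rates: the reservoir is conserved (`r(t) = r0`), the operative
#' pool follows `do/dt = k1'*r0 - beta*o` with
#' `beta = k2 + k5' + k6' - k3'` (primes denote the learning factor applied
#' to k1, k3, k4, k5, k6 inside a training window, never to k2), and
#' neurons accumulate as `dn/dt = (k4' + 2*k5' + k6')*o`. On each interval
#' the solution is closed-form:
#' `o(t0 + s) = o* + (o(t0) - o*)*exp(-beta*s)` with `o* = k1'*r0/beta`,
#' and `n` integrates `o` exactly. The full trajectory is assembled
#' piecewise across the training-window boundaries.
#'
#' This oracle is used to validate the stochastic engine (ensemble means
#' must converge to it) and to compute expected endpoints cheaply; it
#' carries no fluctuation information.
#'
#' @param cohort A [init_labeled_cohort()] cohort.
#' @param rates A [rate_set()].
#' @param schedule A [training_schedule()] or `NULL` for control.
#' @param horizon Simulation horizon in days.
#' @param times Days at which to tabulate the expectation; default daily.
#' @return An object of class `expected_trajectory`: a list with `df`
#'   (data.frame `day`, `r`, `o`, `n`, `source = "ode"`), the per-interval
#'   closed-form parameters, the accumulated division integral and
#'   `int_o` (the integral of `o` over `[0, horizon]`).
#' @examples
#' d <- division_proportions_analytic(default_rates())
#' et <- expected_trajectory(init_labeled_cohort(1000, d), default_rates())
#' tail(et$df, 1)
#' @export
expected_trajectory <- function(cohort, rates, schedule = NULL,
                                horizon = 30, times = NULL) {
  stopifnot(inherits(cohort, "labeled_cohort"), inherits(rates, "rate_set"))
  if (is.null(schedule)) schedule <- training_schedule(NULL)
  stopifnot(inherits(schedule, "training_schedule"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("horizon must be a single positive number of days")
  }
  if (is.null(times)) times <- seq(0, horizon, by = 1)

  bounds <- unique(c(0, window_breakpoints(schedule, horizon), horizon))
  n_int <- length(bounds) - 1L
  iv <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
  iv$lambda <- vapply(seq_len(n_int), function(i) {
    if (in_training_window(schedule, (iv$start[i] + iv$end[i]) / 2)) {
      schedule$lambda
    } else 1
  }, numeric(1))

  r0 <- cohort$r0
  o_cur <- as.numeric(cohort$o0)
  n_cur <- as.numeric(cohort$n0)
  int_o <- 0
  div_integral <- 0
  iv$beta <- iv$ostar <- iv$c_n <- iv$o_start <- iv$n_start <- NA_real_
  iv$a_in <- iv$int_o_start <- NA_real_

  for (i in seq_len(n_int)) {
    lam <- iv$lambda[i]
    beta <- rates$k2 + lam * (rates$k5 + rates$k6 - rates$k3)
    if (beta < 0) {
      stop(sprintf(
        "unstable regime on [%g, %g): k2 + k5' + k6' - k3' = %g is negative",
        iv$start[i], iv$end[i], beta))
    }
    a_in <- lam * rates$k1 * r0
    c_n <- lam * (rates$k4 + 2 * rates$k5 + rates$k6)
    iv$beta[i] <- beta; iv$a_in[i] <- a_in; iv$c_n[i] <- c_n
    iv$ostar[i] <- if (beta > 0) a_in / beta else NA_real_
    iv$o_start[i] <- o_cur; iv$n_start[i] <- n_cur
    iv$int_o_start[i] <- int_o
    delta <- iv$end[i] - iv$start[i]
    seg_int <- o_segment(iv[i, ], delta)$int_o
    n_cur <- n_cur + c_n * seg_int
    div_integral <- div_integral +
      a_in * delta + lam * (rates$k3 + rates$k4 + rates$k5) * seg_int
    int_o <- int_o + seg_int
    o_cur <- o_segment(iv[i, ], delta)$o
  }

  et <- structure(list(intervals = iv, cohort = cohort, rates = rates,
                       schedule = schedule, horizon = horizon,
                       int_o = int_o, div_integral = div_integral),
                  class = "expected_trajectory")
  et$df <- predict(et, times)
  et
}

# Closed-form operative pool and its running integral, s days into one
# constant-rate segment. beta = 0 degenerates to linear growth (constant o
# when the inflow a_in is also zero, e.g. all rates zero).
o_segment <- function(seg, s) {
  if (seg$beta[1] > 0) {
    beta <- seg$beta[1]; ostar <- seg$ostar[1]
    list(o = ostar + (seg$o_start[1] - ostar) * exp(-beta * s),
         int_o = ostar * s +
           (seg$o_start[1] - ostar) * (1 - exp(-beta * s)) / beta)
  } else {
    list(o = seg$o_start[1] + seg$a_in[1] * s,
         int_o = seg$o_start[1] * s + seg$a_in[1] * s^2 / 2)
  }
}

#' Evaluate the mean-field expectation at arbitrary times
#'
#' @param object An [expected_trajectory()].
#' @param times Numeric vector of days within `[0, horizon]`.
#' @param ... Unused.
#' @return data.frame with columns `day`, `r`, `o`, `n`, `source`.
#' @export
predict.expected_trajectory <- function(object, times, ...) {
  iv <- object$intervals
  stopifnot(all(times >= 0 - 1e-12), all(times <= object$horizon + 1e-12))
  tt <- pmin(pmax(times, 0), object$horizon)
  idx <- pmin(pmax(findInterval(tt, iv$start), 1L), nrow(iv))
  s <- tt - iv$start[idx]
  seg <- vapply(seq_along(idx), function(j) {
    unlist(o_segment(iv[idx[j], ], s[j]))
  }, numeric(2))
  n <- iv$n_start[idx] + iv$c_n[idx] * seg["int_o", ]
  data.frame(day = times, r = object$cohort$r0, o = seg["o", ], n = n,
             source = "ode")
}

# Integral of o over [0, t], exact piecewise closed form.
int_o_upto <- function(object, t) {
  iv <- object$intervals
  idx <- pmin(pmax(findInterval(t, iv$start), 1L), nrow(iv))
  iv$int_o_start[idx] + o_segment(iv[idx, ], t - iv$start[idx])$int_o
}

#' Expected mean divisions per labeled lineage
#'
#' Each of the `p0` labeling divisions founds a lineage whose division
#' count starts at 1 (the labeling division itself). Subsequent divisions
#' occur at population rate `k1'*r0` (reservoir seeding) plus
#' `(k3' + k4' + k5')*o(t)` (operative divisions), so the expected mean
#' count at the horizon is
#' `1 + (integral of k1'*r0 + (k3'+k4'+k5')*o(t) dt) / p0`,
#' accumulated piecewise over the training windows.
#'
#' @inheritParams expected_trajectory
#' @return Expected mean number of divisions per lineage (>= 1).
#' @examples
#' d <- division_proportions_analytic(default_rates())
#' expected_divisions(init_labeled_cohort(1000, d), default_rates())  # ~1.73
#' @export
expected_divisions <- function(cohort, rates, schedule = NULL, horizon = 30) {
  et <- expected_trajectory(cohort, rates, schedule, horizon,
                            times = c(0, horizon))
  1 + et$div_integral / cohort$p0
}

#' Expected alive labeled neurons under the death checkpoint
#'
#' Deterministic approximation used for validation bands only: every neuron
#' born at time `b <= t - checkpoint_age` has faced its checkpoint by time
#' `t` and survives with probability `1 - p_eff(b + checkpoint_age)`, where
#' `p_eff` is `p_death` divided by the rescue factor when the checkpoint
#' day lies inside a training window; younger neurons have not faced the
#' draw. The birth flux `(k4' + 2 k5' + k6')*o(s)` is integrated exactly,
#' splitting at every point where the survival weight changes.
#'
#' @inheritParams expected_trajectory
#' @param death A [death_model()].
#' @param t Evaluation day.
#' @return Expected number of alive labeled neurons at `t`.
#' @export
expected_alive_neurons <- function(cohort, rates, schedule = NULL,
                                   death = death_model(), t = 30) {
  if (is.null(schedule)) schedule <- training_schedule(NULL)
  et <- expected_trajectory(cohort, rates, schedule, horizon = t)
  if (!death$enabled) return(predict(et, t)$n)
  ca <- death$checkpoint_age
  surv <- function(day) {
    p <- death$p_death
    if (in_training_window(schedule, day)) p <- p / schedule$rescue_factor
    1 - p
  }
  # initial neurons: age 0 at labeling, checkpoint at day ca
  n_alive <- cohort$n0 * if (t >= ca) surv(ca) else 1
  # birth-time breakpoints: rate-regime bounds, the faced/unfaced split at
  # t - ca, and window edges shifted by -ca (where the rescue weight flips)
  b <- c(et$intervals$start, et$intervals$end, t - ca,
         as.numeric(t(schedule$windows)) - ca)
  b <- sort(unique(pmin(pmax(b, 0), t)))
  for (i in seq_len(length(b) - 1L)) {
    lo <- b[i]; hi <- b[i + 1L]
    if (hi <= lo) next
    mid <- (lo + hi) / 2
    idx <- pmin(pmax(findInterval(mid, et$intervals$start), 1L),
                nrow(et$intervals))
    births <- et$intervals$c_n[idx] * (int_o_upto(et, hi) - int_o_upto(et, lo))
    w <- if (mid <= t - ca) surv(mid + ca) else 1
    n_alive <- n_alive + births * w
  }
  n_alive
}
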