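# Shared fixtures for the nscdyn test suite. Everything is generated in
# code; no data files are read.

reference_rates <- function() default_rates()

# Random rate sets with a safely positive operative-pool loss rate, both
# at baseline and (optionally) under a learning factor.
random_stable_rates <- function(lambda = 1) {
  repeat {
    k <- stats::runif(6, 0.001, 0.03)
    beta0 <- k[2] + k[5] + k[6] - k[3]
    beta_l <- k[2] + lambda * (k[5] + k[6] - k[3])
    if (beta0 > 0.002 && beta_l > 0.002) {
      return(rate_set(k[1], k[2], k[3], k[4], k[5], k[6]))
    }
  }
}

random_proportions <- function() {
  w <- stats::runif(4)
  w <- w / sum(w)
  division_proportions(w[1], w[2], w[3], w[4])
}

# Independent numerical integration of the mean-field system with deSolve,
# restarted at every training-window boundary so the discontinuous rates
# are handled exactly. Returns counts at `times` (which must include 0).
ode_numeric <- function(cohort, rates, schedule = NULL, horizon = 30,
                        times = seq(0, horizon)) {
  if (is.null(schedule)) schedule <- training_schedule(NULL)
  bounds <- unique(c(0, nscdyn:::window_breakpoints(schedule, horizon),
                     horizon))
  y <- c(o = as.numeric(cohort$o0), n = as.numeric(cohort$n0))
  out <- data.frame(day = 0, o = y[["o"]], n = y[["n"]])
  for (i in seq_len(length(bounds) - 1L)) {
    lam <- if (nscdyn:::in_training_window(schedule,
                                           (bounds[i] + bounds[i + 1]) / 2)) {
      schedule$lambda
    } else 1
    rhs <- function(t, y, p) {
      list(c(lam * rates$k1 * cohort$r0 -
               (rates$k2 + lam * (rates$k5 + rates$k6 - rates$k3)) * y[1],
             lam * (rates$k4 + 2 * rates$k5 + rates$k6) * y[1]))
    }
    tt <- sort(unique(c(bounds[i], times[times > bounds[i] &
                                           times <= bounds[i + 1]],
                        bounds[i + 1])))
    sol <- deSolve::lsoda(y, tt, rhs, parms = NULL,
                          rtol = 1e-12, atol = 1e-12)
    y <- c(o = unname(sol[nrow(sol), "o"]), n = unname(sol[nrow(sol), "n"]))
    keep <- sol[-1, , drop = FALSE]
    out <- rbind(out, data.frame(day = keep[, "time"], o = keep[, "o"],
                                 n = keep[, "n"]))
  }
  out <- out[!duplicated(out$day), ]
  out[out$day %in% times, ]
}
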