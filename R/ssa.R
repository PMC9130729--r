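#' Event-driven stochastic simulation of a labeled NSC cohort
#'
#' Exact continuous-time simulation of the six-reaction network for the
#' labeled cohort only (the unlabeled background is outside the model's
#' scope). Population-level propensities are used: reaction 1 fires at
#' total rate `k1'*r0` (the reservoir is never consumed, so the labeled
#' reservoir count is constant), and each labeled operative cell fires
#' reactions 2-6 at rates `k2, k3', k4', k5', k6'`. Primed rates carry the
#' learning factor inside training windows; `k2` never does. Propensities
#' are piecewise constant, and pending exponential waiting times are
#' redrawn at window boundaries and checkpoint days (valid by
#' memorylessness).
#'
#' Per-cell identity is kept only where it matters: every operative and
#' reservoir cell carries its lineage id (one lineage per labeling
#' division) so division counts can be attributed, and every neuron
#' records its birth time and lineage for the maturation death checkpoint.
#' A neuron faces a single Bernoulli death draw when its age reaches
#' `death$checkpoint_age`; the death probability is divided by the rescue
#' factor when that calendar day lies inside a training window.
#'
#' @param cohort A [init_labeled_cohort()] cohort.
#' @param rates A [rate_set()].
#' @param schedule A [training_schedule()] or `NULL` for control.
#' @param death A [death_model()]; default disabled.
#' @param horizon Days to simulate (> 0).
#' @param seed Integer seed; same seed and configuration give bit-identical
#'   output. `NULL` leaves the RNG state untouched.
#' @return An object of class `nsc_sim`: a list with
#'   * `trajectory`: data.frame `day`, `r`, `o`, `n` (alive), sampled daily
#'     and at the horizon;
#'   * `events`: data.frame `time`, `reaction` (1-6; 7 = checkpoint death),
#'     `lineage`;
#'   * `ledger`: class `cell_ledger` with `lineage_divisions` (length `p0`,
#'     labeling division included) and a `neurons` data.frame
#'     (`birth`, `lineage`, `alive`, `checkpoint_resolved`);
#'   * `meta`: the full configuration and seed.
#' @examples
#' d <- division_proportions(0.5, 0.11, 0.32, 0.07)
#' sim <- simulate_cohort(init_labeled_cohort(100, d), default_rates(),
#'                        horizon = 30, seed = 1)
#' tail(sim$trajectory, 1)
#' @export
simulate_cohort <- function(cohort, rates, schedule = NULL, death = no_death(),
                            horizon = 30, seed = NULL) {
  stopifnot(inherits(cohort, "labeled_cohort"), inherits(rates, "rate_set"))
  if (is.null(schedule)) schedule <- training_schedule(NULL)
  stopifnot(inherits(schedule, "training_schedule"),
            inherits(death, "death_model"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("horizon must be a single positive number of days")
  }
  if (nrow(schedule$windows) > 0L &&
      any(schedule$windows[, "start"] >= horizon)) {
    stop("training window starts at or beyond the horizon")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!exists(".Random.seed", envir = .GlobalEnv)) stats::runif(1)

  # Checkpoint survival draws come from a dedicated RNG substream derived
  # from the seed, so the reaction event stream is identical between
  # death-enabled and death-free runs of the same seed (and p_death = 0
  # reproduces the death-free run exactly).
  death_state <- NULL
  if (death$enabled) {
    death_seed <- derive_seed(
      if (is.null(seed)) floor(stats::runif(1) * 2^30) else seed,
      "checkpoint-stream")
    main_state <- get(".Random.seed", envir = .GlobalEnv)
    set.seed(death_seed)
    death_state <- get(".Random.seed", envir = .GlobalEnv)
    assign(".Random.seed", main_state, envir = .GlobalEnv)
  }

  p0 <- cohort$p0; r0 <- cohort$r0
  # Lineage composition at labeling: r0 type-1 lineages contribute {r, o};
  # type-5 lineages {n, n}; type-4 {o, n}; the rest are type-3 {o, o}.
  # L4 + 2*L5 = n0 makes the operative count come out to o0 exactly.
  L1 <- r0
  L5 <- as.integer(round(p0 * cohort$d$d5))
  L4 <- cohort$n0 - 2L * L5
  L3 <- p0 - L1 - L4 - L5
  if (min(L3, L4, L5) < 0L) {
    stop("cohort counts are inconsistent with the division proportions")
  }
  id1 <- seq_len(L1)
  id3 <- seq_len(L3) + L1
  id4 <- seq_len(L4) + L1 + L3
  id5 <- seq_len(L5) + L1 + L3 + L4

  o_lin <- c(id1, rep(id3, each = 2L), id4)
  o_count <- length(o_lin)
  stopifnot(o_count == cohort$o0)
  o_cap <- max(64L, 2L * o_count)
  o_lin <- c(o_lin, integer(o_cap - o_count))

  # neuron ledger, birth order (checkpoints are therefore time-ordered)
  n_cap <- max(64L, 4L * cohort$n0 + 64L)
  nb_birth <- numeric(n_cap); nb_lin <- integer(n_cap)
  nb_alive <- logical(n_cap); nb_resolved <- logical(n_cap)
  n_total <- cohort$n0
  if (n_total > 0L) {
    nb_birth[seq_len(n_total)] <- 0
    nb_lin[seq_len(n_total)] <- c(id4, rep(id5, each = 2L))
    nb_alive[seq_len(n_total)] <- TRUE
  }
  grow_neurons <- function(need) {
    while (n_total + need > n_cap) {
      n_cap <<- 2L * n_cap
      length(nb_birth) <<- n_cap; length(nb_lin) <<- n_cap
      length(nb_alive) <<- n_cap; length(nb_resolved) <<- n_cap
      nb_alive[is.na(nb_alive)] <<- FALSE
      nb_resolved[is.na(nb_resolved)] <<- FALSE
      nb_lin[is.na(nb_lin)] <<- 0L
    }
  }

  lineage_div <- rep(1L, p0)

  ev_cap <- 1024L
  ev_time <- numeric(ev_cap); ev_rx <- integer(ev_cap); ev_lin <- integer(ev_cap)
  ev_n <- 0L
  log_event <- function(tm, rx, lid) {
    if (ev_n == ev_cap) {
      ev_cap <<- 2L * ev_cap
      length(ev_time) <<- ev_cap; length(ev_rx) <<- ev_cap
      length(ev_lin) <<- ev_cap
    }
    ev_n <<- ev_n + 1L
    ev_time[ev_n] <<- tm; ev_rx[ev_n] <<- rx; ev_lin[ev_n] <<- lid
  }

  # lambda = 1 leaves every propensity unchanged, so window boundaries are
  # not rate breakpoints (rescue at checkpoints still sees the windows)
  wb <- if (schedule$lambda == 1) numeric(0)
        else window_breakpoints(schedule, horizon)
  wb_ptr <- 1L
  cp_ptr <- 1L
  ca <- death$checkpoint_age
  k2 <- rates$k2
  k_base <- c(rates$k3, rates$k4, rates$k5, rates$k6)

  t <- 0
  lam <- if (in_training_window(schedule, t)) schedule$lambda else 1
  a1 <- lam * rates$k1 * r0
  ko <- c(k2, lam * k_base)          # per-cell rates for reactions 2..6
  ko_sum <- sum(ko)
  ko_cum <- cumsum(ko)

  # The pending reaction time survives checkpoint stops (deaths change no
  # propensity) and is redrawn only after a reaction fires or the rates
  # change at a window boundary.
  t_react <- NA_real_
  repeat {
    if (is.na(t_react)) {
      atot <- a1 + o_count * ko_sum
      t_react <- if (atot > 0) t + stats::rexp(1) / atot else Inf
    }
    t_wb <- if (wb_ptr <= length(wb)) wb[wb_ptr] else Inf
    t_cp <- if (death$enabled && cp_ptr <= n_total) nb_birth[cp_ptr] + ca
            else Inf
    t_stop <- min(t_wb, t_cp, horizon)

    if (t_react < t_stop) {
      t <- t_react
      u <- stats::runif(1) * atot
      if (u < a1) {
        lid <- if (r0 == 1L) 1L else sample.int(r0, 1L)   # reservoir lineages are 1..r0
        lineage_div[lid] <- lineage_div[lid] + 1L
        o_count <- o_count + 1L
        if (o_count > o_cap) {
          o_cap <- 2L * o_cap; length(o_lin) <- o_cap
        }
        o_lin[o_count] <- lid
        log_event(t, 1L, lid)
      } else {
        oi <- sample.int(o_count, 1L)
        lid <- o_lin[oi]
        v <- (u - a1) / o_count
        rx <- 1L + findInterval(v, ko_cum, left.open = TRUE) + 1L  # 2..6
        if (rx == 2L) {                      # oNSC death
          o_lin[oi] <- o_lin[o_count]; o_count <- o_count - 1L
        } else if (rx == 3L) {               # o -> o + o
          lineage_div[lid] <- lineage_div[lid] + 1L
          o_count <- o_count + 1L
          if (o_count > o_cap) { o_cap <- 2L * o_cap; length(o_lin) <- o_cap }
          o_lin[o_count] <- lid
        } else if (rx == 4L) {               # o -> o + n
          lineage_div[lid] <- lineage_div[lid] + 1L
          grow_neurons(1L); n_total <- n_total + 1L
          nb_birth[n_total] <- t; nb_lin[n_total] <- lid
          nb_alive[n_total] <- TRUE
        } else if (rx == 5L) {               # o -> n + n
          lineage_div[lid] <- lineage_div[lid] + 1L
          o_lin[oi] <- o_lin[o_count]; o_count <- o_count - 1L
          grow_neurons(2L)
          nb_birth[n_total + 1:2] <- t; nb_lin[n_total + 1:2] <- lid
          nb_alive[n_total + 1:2] <- TRUE
          n_total <- n_total + 2L
        } else {                             # o -> n
          o_lin[oi] <- o_lin[o_count]; o_count <- o_count - 1L
          grow_neurons(1L); n_total <- n_total + 1L
          nb_birth[n_total] <- t; nb_lin[n_total] <- lid
          nb_alive[n_total] <- TRUE
        }
        log_event(t, rx, lid)
      }
      t_react <- NA_real_
    } else if (t_cp <= t_stop && t_cp <= horizon) {
      # resolve every unresolved checkpoint falling due at this instant
      t <- t_cp
      p_eff <- death$p_death
      if (in_training_window(schedule, t)) p_eff <- p_eff / schedule$rescue_factor
      main_state <- get(".Random.seed", envir = .GlobalEnv)
      assign(".Random.seed", death_state, envir = .GlobalEnv)
      while (cp_ptr <= n_total && nb_birth[cp_ptr] + ca <= t) {
        if (nb_alive[cp_ptr] && !nb_resolved[cp_ptr]) {
          if (stats::runif(1) < p_eff) {
            nb_alive[cp_ptr] <- FALSE
            log_event(t, 7L, nb_lin[cp_ptr])
          }
        }
        nb_resolved[cp_ptr] <- TRUE
        cp_ptr <- cp_ptr + 1L
      }
      death_state <- get(".Random.seed", envir = .GlobalEnv)
      assign(".Random.seed", main_state, envir = .GlobalEnv)
    } else if (t_wb < horizon) {
      t <- t_wb; wb_ptr <- wb_ptr + 1L
      lam <- if (in_training_window(schedule, t)) schedule$lambda else 1
      a1 <- lam * rates$k1 * r0
      ko <- c(k2, lam * k_base)
      ko_sum <- sum(ko); ko_cum <- cumsum(ko)
      t_react <- NA_real_
    } else {
      break
    }
  }

  ev_idx <- seq_len(ev_n)
  events <- data.frame(time = ev_time[ev_idx], reaction = ev_rx[ev_idx],
                       lineage = ev_lin[ev_idx])

  days <- unique(c(seq(0, floor(horizon)), horizon))
  d_o <- c(0L, 1L, -1L, 1L, 0L, -1L, -1L, 0L)[events$reaction + 1L]
  d_n <- c(0L, 0L, 0L, 0L, 1L, 2L, 1L, -1L)[events$reaction + 1L]
  pos <- findInterval(days, events$time)
  traj <- data.frame(
    day = days,
    r = r0,
    o = cohort$o0 + c(0, cumsum(d_o))[pos + 1L],
    n = cohort$n0 + c(0, cumsum(d_n))[pos + 1L])

  nidx <- seq_len(n_total)
  ledger <- structure(list(
    lineage_divisions = lineage_div,
    neurons = data.frame(birth = nb_birth[nidx], lineage = nb_lin[nidx],
                         alive = nb_alive[nidx],
                         checkpoint_resolved = nb_resolved[nidx])),
    class = "cell_ledger")

  structure(list(trajectory = traj, events = events, ledger = ledger,
                 meta = list(cohort = cohort, rates = rates,
                             schedule = schedule, death = death,
                             horizon = horizon, seed = seed)),
            class = "nsc_sim")
}

#' Labeled counts at a given day
#'
#' @param sim An `nsc_sim` object.
#' @param t A day present in the sampled trajectory.
#' @return Named numeric vector `r`, `o`, `n`.
#' @export
counts_at <- function(sim, t) {
  stopifnot(inherits(sim, "nsc_sim"))
  row <- sim$trajectory[abs(sim$trajectory$day - t) < 1e-9, , drop = FALSE]
  if (nrow(row) == 0L) stop("day ", t, " is not in the sampled trajectory")
  c(r = row$r[1], o = row$o[1], n = row$n[1])
}

#' Mean divisions per labeling lineage
#'
#' Arithmetic mean of the per-lineage division counts over all `p0`
#' lineages, counting the labeling division itself as 1.
#'
#' @param ledger A `cell_ledger` from [simulate_cohort()].
#' @return Mean divisions per lineage (>= 1).
#' @export
divisions_per_lineage <- function(ledger) {
  stopifnot(inherits(ledger, "cell_ledger"))
  if (length(ledger$lineage_divisions) == 0L) {
    stop("empty ledger: no lineages were simulated")
  }
  mean(ledger$lineage_divisions)
}

#' Neuronal survival under the death checkpoint
#'
#' Ratio (as a percentage) of alive labeled neurons in a death-enabled run
#' to labeled neurons in its paired death-free run at day `t`. The two runs
#' must share cohort, rates, schedule and horizon; pairing is by replicate.
#'
#' @param with_death,without_death `nsc_sim` objects.
#' @param t Evaluation day (default the common horizon).
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) when the
#'   death-free run has no neurons at `t`.
#' @export
survival_fraction <- function(with_death, without_death, t = NULL) {
  stopifnot(inherits(with_death, "nsc_sim"), inherits(without_death, "nsc_sim"))
  if (with_death$meta$horizon != without_death$meta$horizon) {
    stop("paired runs must share the same horizon")
  }
  if (is.null(t)) t <- with_death$meta$horizon
  num <- counts_at(with_death, t)[["n"]]
  den <- counts_at(without_death, t)[["n"]]
  if (den == 0) {
    warning("no labeled neurons in the death-free run at day ", t,
            "; survival is undefined")
    return(NA_real_)
  }
  100 * num / den
}

#' Steady-state stochastic census of division proportions
#'
#' Simulates the full (unlabeled) two-pool network at its stationary
#' composition — a reservoir of `r_init` cells and an operative pool at
#' the equilibrium ratio — and classifies every division event (reactions
#' 1, 3, 4, 5) by type. The empirical fractions estimate the division
#' proportions used to initialise labeled cohorts; they converge to
#' [division_proportions_analytic()] as the number of events grows.
#'
#' @param rates A [rate_set()].
#' @param r_init Reservoir size (constant). Default 4000.
#' @param duration Census length in days; `NULL` (default) runs until
#'   `min_divisions` division events have accrued.
#' @param min_divisions Minimum number of division events when `duration`
#'   is `NULL`. Default 10000.
#' @param seed Integer seed or `NULL`.
#' @param o_init Initial operative pool; default the analytic equilibrium.
#' @return A [division_proportions()] object with attributes
#'   `n_divisions`, `se` (binomial standard errors) and `counts`; a
#'   `low_counts` warning attribute is attached below 100 events.
#' @export
estimate_division_proportions <- function(rates, r_init = 4000,
                                          duration = NULL,
                                          min_divisions = 10000,
                                          seed = NULL, o_init = NULL) {
  stopifnot(inherits(rates, "rate_set"))
  eq <- equilibrium_ratio(rates, r_eq = r_init)
  if (is.null(o_init)) o_init <- as.integer(round(eq$o_eq))
  if (!is.null(seed)) set.seed(as.integer(seed))

  o <- as.integer(o_init)
  tally <- integer(6)
  t <- 0
  k <- unlist(rates)
  repeat {
    a <- c(k[1] * r_init, k[2:6] * o)
    atot <- sum(a)
    if (atot <= 0) break
    t <- t + stats::rexp(1) / atot
    if (!is.null(duration) && t > duration) break
    rx <- findInterval(stats::runif(1) * atot, cumsum(a),
                       left.open = TRUE) + 1L
    tally[rx] <- tally[rx] + 1L
    if (rx == 2L || rx == 5L || rx == 6L) o <- o - 1L
    if (rx == 1L || rx == 3L) o <- o + 1L
    if (is.null(duration) && sum(tally[c(1L, 3L, 4L, 5L)]) >= min_divisions) {
      break
    }
    if (o <= 0L) { o <- 0L }   # pool can empty transiently; r keeps seeding
  }
  div <- tally[c(1L, 3L, 4L, 5L)]
  n_div <- sum(div)
  if (n_div == 0L) stop("no division activity: census recorded no divisions")
  p <- div / n_div
  out <- division_proportions(d1 = p[1], d3 = p[2], d4 = p[3], d5 = p[4])
  attr(out, "n_divisions") <- n_div
  attr(out, "se") <- sqrt(p * (1 - p) / n_div)
  attr(out, "counts") <- tally
  if (n_div < 100L) {
    attr(out, "low_counts") <- TRUE
    warning("only ", n_div, " division events; proportions are unreliable")
  }
  out
}
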