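#' Run configuration
#'
#' Bundles everything a simulation run needs — rates, cohort size,
#' horizon, schedule, death model, replicate count and master seed — so
#' that a run is reproducible from its serialized configuration alone.
#'
#' @param rates A [rate_set()].
#' @param p0 Labeling divisions. Default 1000.
#' @param horizon Days. Default 30.
#' @param schedule A [training_schedule()] or `NULL`.
#' @param death A [death_model()].
#' @param replicates Replicate count. Default 20.
#' @param master_seed Integer master seed. Default 1.
#' @return An object of class `run_config`.
#' @export
run_config <- function(rates = default_rates(), p0 = 1000, horizon = 30,
                       schedule = NULL, death = no_death(),
                       replicates = 20, master_seed = 1) {
  stopifnot(inherits(rates, "rate_set"), inherits(death, "death_model"))
  if (!is.null(schedule)) stopifnot(inherits(schedule, "training_schedule"))
  structure(list(rates = rates, p0 = p0, horizon = horizon,
                 schedule = schedule, death = death,
                 replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output file path (`.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    rates = lapply(unclass(config$rates), as.numeric),
    p0 = config$p0, horizon = config$horizon,
    replicates = config$replicates, master_seed = config$master_seed,
    death = list(enabled = config$death$enabled,
                 p_death = config$death$p_death,
                 checkpoint_age = config$death$checkpoint_age))
  if (!is.null(config$schedule)) {
    w <- config$schedule$windows
    x$schedule <- list(
      lambda = config$schedule$lambda,
      rescue_factor = config$schedule$rescue_factor,
      windows = lapply(seq_len(nrow(w)), function(i) as.numeric(w[i, ])))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML (or JSON)
#'
#' Validates the schema and reports missing or malformed keys by name;
#' `read_run_config(write_run_config(x, f))` is the identity.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(x$rates)) stop("config is missing the 'rates' block")
  for (key in paste0("k", 1:6)) {
    if (is.null(x$rates[[key]])) {
      stop("config 'rates' block is missing required rate '", key, "'")
    }
  }
  rates <- do.call(rate_set, lapply(x$rates[paste0("k", 1:6)], as.numeric))
  for (key in c("p0", "horizon")) {
    if (is.null(x[[key]])) stop("config is missing required key '", key, "'")
  }
  schedule <- NULL
  if (!is.null(x$schedule)) {
    for (key in c("lambda", "windows")) {
      if (is.null(x$schedule[[key]])) {
        stop("config 'schedule' block is missing required key '", key, "'")
      }
    }
    wl <- x$schedule$windows
    if (is.data.frame(wl) || is.matrix(wl)) wl <- as.matrix(wl)
    else if (is.list(wl)) wl <- do.call(rbind, lapply(wl, as.numeric))
    else wl <- matrix(as.numeric(wl), ncol = 2, byrow = TRUE)
    schedule <- training_schedule(
      windows = wl, lambda = as.numeric(x$schedule$lambda),
      rescue_factor = as.numeric(x$schedule$rescue_factor %||% 10))
  }
  death <- if (is.null(x$death)) no_death() else {
    death_model(p_death = as.numeric(x$death$p_death %||% 0.550),
                checkpoint_age = as.numeric(x$death$checkpoint_age %||% 15),
                enabled = isTRUE(x$death$enabled))
  }
  run_config(rates = rates, p0 = as.numeric(x$p0),
             horizon = as.numeric(x$horizon), schedule = schedule,
             death = death,
             replicates = as.integer(x$replicates %||% 20L),
             master_seed = as.integer(x$master_seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation trajectories as tidy CSV
#'
#' One row per replicate per sampled day, columns `replicate`, `day`,
#' `r`, `o`, `n`, `condition`, `source` (`"ssa"` or `"ode"`).
#'
#' @param sims A list of `nsc_sim` objects (or a single one).
#' @param path Output CSV path.
#' @param condition Condition label. Default `"control"`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sims, path, condition = "control") {
  if (inherits(sims, "nsc_sim")) sims <- list(sims)
  rows <- lapply(seq_along(sims), function(i) {
    tr <- sims[[i]]$trajectory
    data.frame(replicate = i, day = tr$day, r = tr$r, o = tr$o, n = tr$n,
               condition = condition, source = "ssa")
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Persist a battery summary as JSON
#'
#' Records, per scenario, the configuration echo (horizon, lambda,
#' windows, death model, replicate seeds) and the per-replicate endpoints,
#' so every output is regenerable from the file alone.
#'
#' @param battery A `scenario_battery` from [run_battery()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_battery_summary <- function(battery, path) {
  stopifnot(inherits(battery, "scenario_battery"))
  out <- list(master_seed = attr(battery, "master_seed"),
              scenarios = lapply(unclass(battery), function(s) {
    sp <- s$spec
    list(name = s$name,
         horizon = sp$horizon,
         replicates = nrow(s$replicates),
         p0 = sp$p0,
         rate_multiplier = sp$rate_multiplier,
         lambda = if (is.null(sp$schedule)) 1 else sp$schedule$lambda,
         windows = if (is.null(sp$schedule)) list() else {
           w <- sp$schedule$windows
           lapply(seq_len(nrow(w)), function(i) as.numeric(w[i, ]))
         },
         death = list(enabled = sp$death$enabled,
                      p_death = sp$death$p_death,
                      checkpoint_age = sp$death$checkpoint_age),
         seeds = s$replicates$seed,
         endpoints = s$replicates[, c("neurons", "fraction", "divisions")],
         mean_neurons = s$mean_neurons, sd_neurons = s$sd_neurons,
         mean_fraction = s$mean_fraction,
         mean_divisions = s$mean_divisions)
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
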