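#' Training schedule with a learning factor
#'
#' During training the learning factor `lambda` multiplies the rates of
#' division and differentiation (k1, k3, k4, k5, k6) inside each training
#' window; the operative-pool death rate k2 is never scaled. Neuronal death
#' at the maturation checkpoint is rescued (divided by `rescue_factor`)
#' when a neuron's checkpoint day falls inside a window.
#'
#' Windows are half-open day intervals `[start, end)`, must be sorted and
#' non-overlapping. `training_windows("3-14")` and `training_windows("12-30")`
#' give the two training periods used throughout: two and three weeks of
#' training respectively. `session_blocks = TRUE` splits each window into
#' 5-days-on / 2-days-off session blocks mirroring the week structure of the
#' behavioural protocol; contiguous windows are the default.
#'
#' @param windows A numeric matrix (or list of length-2 vectors) of
#'   `[start, end)` day intervals; `NULL` or an empty set means no training.
#' @param lambda Learning factor, >= 1. Default 3.
#' @param rescue_factor Divisor on the checkpoint death probability during
#'   training, >= 1. Default 10.
#' @param session_blocks If `TRUE`, each window is replaced by repeated
#'   5-day-on/2-day-off blocks clipped to the window.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(windows = NULL, lambda = 3, rescue_factor = 10,
                              session_blocks = FALSE) {
  if (is.null(windows) || (is.matrix(windows) && nrow(windows) == 0L) ||
      (is.list(windows) && length(windows) == 0L)) {
    w <- matrix(numeric(0), ncol = 2)
  } else {
    if (is.list(windows)) windows <- do.call(rbind, windows)
    if (is.numeric(windows) && is.null(dim(windows)) && length(windows) == 2L) {
      windows <- matrix(windows, ncol = 2)
    }
    w <- matrix(as.numeric(windows), ncol = 2)
  }
  colnames(w) <- c("start", "end")
  if (nrow(w) > 0L) {
    if (any(w[, "end"] <= w[, "start"])) {
      stop("each training window must satisfy start < end")
    }
    if (any(w[, "start"] < 0)) stop("training windows must start at day >= 0")
    if (is.unsorted(w[, "start"], strictly = TRUE) && nrow(w) > 1L) {
      stop("training windows must be sorted by start day")
    }
    if (nrow(w) > 1L && any(w[-nrow(w), "end"] > w[-1L, "start"])) {
      stop("training windows must not overlap")
    }
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 1) {
    stop("lambda must be a single number >= 1")
  }
  if (!is.numeric(rescue_factor) || length(rescue_factor) != 1L ||
      rescue_factor < 1) {
    stop("rescue_factor must be a single number >= 1")
  }
  if (isTRUE(session_blocks) && nrow(w) > 0L) {
    blocks <- list()
    for (i in seq_len(nrow(w))) {
      s <- w[i, "start"]
      while (s < w[i, "end"]) {
        blocks[[length(blocks) + 1L]] <- c(s, min(s + 5, w[i, "end"]))
        s <- s + 7
      }
    }
    w <- do.call(rbind, blocks)
    colnames(w) <- c("start", "end")
  }
  structure(list(windows = w, lambda = lambda, rescue_factor = rescue_factor),
            class = "training_schedule")
}

#' @rdname training_schedule
#' @param period `"3-14"`, `"12-30"`, or a length-2 numeric vector.
#' @param ... Passed on to [training_schedule()].
#' @export
training_windows <- function(period, ...) {
  w <- switch(as.character(period)[1],
              "3-14" = c(3, 14),
              "12-30" = c(12, 30),
              {
                if (is.numeric(period) && length(period) == 2L) period
                else stop("unknown training period: ", period)
              })
  training_schedule(windows = matrix(w, ncol = 2), ...)
}

# TRUE when day t lies inside any half-open training window [start, end).
in_training_window <- function(schedule, t) {
  w <- schedule$windows
  if (nrow(w) == 0L) return(FALSE)
  any(w[, "start"] <= t & t < w[, "end"])
}

# Sorted boundary times (window starts and ends) strictly inside (0, horizon).
window_breakpoints <- function(schedule, horizon) {
  b <- as.numeric(t(schedule$windows))
  sort(unique(b[b > 0 & b < horizon]))
}

#' Neuronal death checkpoint
#'
#' Adult-born neurons mature over `checkpoint_age` days and then face a
#' single Bernoulli survival decision: death with probability `p_death`,
#' reduced to `p_death / rescue_factor` when the checkpoint day lies inside
#' a training window (activity-dependent rescue). The initial labeled
#' neurons have age 0 at labeling, so their checkpoint falls on day
#' `checkpoint_age`; neurons younger than `checkpoint_age` at the horizon
#' never face the draw.
#'
#' @param p_death Death probability in `[0, 1]`. Default 0.550.
#' @param checkpoint_age Age (days) at which the draw occurs. Default 15.
#' @param enabled If `FALSE` the checkpoint is skipped entirely.
#' @return An object of class `death_model`.
#' @export
death_model <- function(p_death = 0.550, checkpoint_age = 15, enabled = TRUE) {
  if (!is.numeric(p_death) || length(p_death) != 1L ||
      p_death < 0 || p_death > 1) {
    stop("p_death must be a single probability in [0, 1]")
  }
  if (!is.numeric(checkpoint_age) || length(checkpoint_age) != 1L ||
      checkpoint_age <= 0) {
    stop("checkpoint_age must be a single positive number of days")
  }
  structure(list(p_death = p_death, checkpoint_age = checkpoint_age,
                 enabled = isTRUE(enabled)),
            class = "death_model")
}

#' @rdname death_model
#' @export
no_death <- function() death_model(enabled = FALSE)
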