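#' Derive a reproducible child seed
#'
#' All randomness flows from one master seed. A scenario's seed is the
#' master seed plus a polynomial-rolling hash of its name (mod 2^31 - 1),
#' so battery results depend on scenario names, never on execution order;
#' replicate seeds are the scenario seed plus the replicate index.
#'
#' @param master Integer master seed.
#' @param name Character scenario name ("" for none).
#' @param index Replicate index (0 for the scenario-level seed).
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(master, name = "", index = 0L) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 31 + ch) %% m
  as.integer((as.numeric(master) %% m + h + as.numeric(index)) %% m + 1)
}

#' Welch two-sample comparison
#'
#' Thin wrapper around [stats::t.test()] with unequal variances, returning
#' a flat record for summary tables.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_compare <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Permutation test on a difference of means
#'
#' Two-sided test of equal location by random relabelling of the pooled
#' sample.
#'
#' @param x,y Numeric samples.
#' @param n_perm Number of permutations. Default 2000.
#' @param seed Optional integer seed.
#' @return List with `observed` (mean(x) - mean(y)) and `p_value`.
#' @export
permutation_test <- function(x, y, n_perm = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  nx <- length(x)
  more_extreme <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), nx)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= abs(obs) - 1e-12) {
      more_extreme <- more_extreme + 1L
    }
  }
  list(observed = obs, p_value = (more_extreme + 1) / (n_perm + 1))
}
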