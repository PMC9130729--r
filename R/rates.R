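#' Reaction rates of the pallial NSC network
#'
#' The model tracks two neural-stem-cell (NSC) pools and post-mitotic
#' neurons. Reservoir NSCs (r) self-renew while seeding the operative pool;
#' operative NSCs (o) divide, differentiate or die; neurons (n) accumulate.
#' The six reactions and their per-day rates are
#'
#' 1. `r -> r + o` (rate `k1`): reservoir NSC seeds an operative NSC without
#'    leaving the reservoir.
#' 2. `o -> 0`     (rate `k2`): operative NSC death.
#' 3. `o -> o + o` (rate `k3`): amplifying division.
#' 4. `o -> o + n` (rate `k4`): asymmetric neurogenic division.
#' 5. `o -> n + n` (rate `k5`): terminal symmetric neurogenic division.
#' 6. `o -> n`     (rate `k6`): direct differentiation (not a division).
#'
#' Reactions 1, 3, 4 and 5 are cell divisions; 2 and 6 are not.
#'
#' @param k1,k2,k3,k4,k5,k6 Non-negative per-day rate constants.
#' @return An object of class `rate_set`.
#' @seealso [default_rates()], [equilibrium_ratio()],
#'   [division_proportions_analytic()]
#' @export
rate_set <- function(k1, k2, k3, k4, k5, k6) {
  k <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6)
  if (!is.numeric(k) || length(k) != 6L || anyNA(k)) {
    stop("all six rates k1..k6 must be supplied as single numbers")
  }
  if (any(k < 0)) stop("rates must be non-negative")
  structure(as.list(k), class = "rate_set")
}

#' Published reference rates for the adult pallium
#'
#' Rates of division, differentiation and death of pallial NSCs estimated
#' from intravital clonal imaging of the adult zebrafish telencephalon
#' (Than-Trong et al. 2020), used as fixed constants throughout: no rate
#' inference is performed in this package.
#'
#' @return A [rate_set()] with k1 = 0.007, k2 = 0.017, k3 = 0.006,
#'   k4 = 0.018, k5 = 0.004, k6 = 0.013 per day.
#' @export
default_rates <- function() {
  rate_set(k1 = 0.007, k2 = 0.017, k3 = 0.006, k4 = 0.018,
           k5 = 0.004, k6 = 0.013)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("NSC reaction rates (per day):\n")
  print(unlist(x))
  invisible(x)
}

# Net loss rate of the operative pool: gain k1*r + k3*o, loss (k2+k5+k6)*o,
# so do/dt = k1*r - beta*o with beta = k2 + k5 + k6 - k3.
stability_denominator <- function(rates) {
  rates$k2 + rates$k5 + rates$k6 - rates$k3
}

#' Stationary operative-to-reservoir ratio
#'
#' The reservoir is conserved (reaction 1 does not consume the reservoir
#' cell and nothing kills reservoir cells), so dr/dt = 0 and r stays at its
#' initial value. The operative pool obeys the mass balance
#' `do/dt = k1*r - (k2 + k5 + k6 - k3)*o`; at stationarity
#' `o_eq / r_eq = k1 / (k2 + k5 + k6 - k3)`, finite only when the
#' denominator is positive.
#'
#' @param rates A [rate_set()].
#' @param r_eq Reference reservoir size (cells); defaults to 1 so the ratio
#'   is the per-reservoir-cell equilibrium.
#' @return A list of class `equilibrium_state` with elements `ratio_o_to_r`,
#'   `r_eq` and `o_eq`.
#' @examples
#' equilibrium_ratio(default_rates())$ratio_o_to_r  # 0.25
#' @export
equilibrium_ratio <- function(rates, r_eq = 1) {
  stopifnot(inherits(rates, "rate_set"))
  beta <- stability_denominator(rates)
  if (beta <= 0) {
    stop("no stable equilibrium: k2 + k5 + k6 - k3 = ", format(beta),
         " is not positive, the operative pool grows without bound")
  }
  ratio <- rates$k1 / beta
  structure(list(ratio_o_to_r = ratio, r_eq = r_eq, o_eq = ratio * r_eq),
            class = "equilibrium_state")
}

#' Division proportions
#'
#' Fractions of all cell-division events attributable to reactions 1
#' (reservoir seeding), 3 (amplifying), 4 (asymmetric) and 5 (terminal
#' symmetric). Reactions 2 and 6 are not divisions and carry no proportion.
#'
#' @param d1,d3,d4,d5 Fractions in `[0, 1]` summing to 1.
#' @return An object of class `division_proportions`.
#' @export
division_proportions <- function(d1, d3, d4, d5) {
  d <- c(d1 = d1, d3 = d3, d4 = d4, d5 = d5)
  if (!is.numeric(d) || length(d) != 4L || anyNA(d)) {
    stop("d1, d3, d4, d5 must be single numbers")
  }
  if (any(d < 0) || any(d > 1)) stop("division proportions must lie in [0, 1]")
  if (abs(sum(d) - 1) > 1e-8) {
    stop("division proportions must sum to 1 (got ", format(sum(d)), ")")
  }
  structure(as.list(d), class = "division_proportions")
}

#' Analytic division proportions at equilibrium
#'
#' At the stationary state each division reaction fires at a constant
#' population rate: reaction 1 at `k1*r_eq`, reactions 3, 4, 5 at
#' `k3*o_eq`, `k4*o_eq`, `k5*o_eq`. The division proportions are these four
#' weights normalised to sum 1. They are invariant to rescaling all six
#' rates by a common factor.
#'
#' @param rates A [rate_set()] with a positive stability denominator.
#' @return A [division_proportions()] object.
#' @examples
#' division_proportions_analytic(default_rates())
#' @export
division_proportions_analytic <- function(rates) {
  eq <- equilibrium_ratio(rates, r_eq = 1)
  w <- c(rates$k1 * eq$r_eq,
         rates$k3 * eq$o_eq,
         rates$k4 * eq$o_eq,
         rates$k5 * eq$o_eq)
  if (sum(w) == 0) stop("no division activity: all division weights are zero")
  p <- w / sum(w)
  division_proportions(d1 = p[1], d3 = p[2], d4 = p[3], d5 = p[4])
}

#' Initialize a thymidine-analog-labeled cohort
#'
#' A BrdU/EdU pulse labels cells during S-phase, so each of the `p0`
#' labeling divisions produces exactly two labeled daughters whose fates
#' follow the division proportions: a type-1 division leaves one labeled
#' reservoir cell and one labeled operative cell, type 3 two operative,
#' type 4 one operative and one neuron, type 5 two neurons. Hence
#' `r0 = p0*d1`, `o0 = p0*(d1 + 2*d3 + d4)`, `n0 = p0*(d4 + 2*d5)`.
#'
#' Rounding policy: `r0` and `o0` are rounded to the nearest integer and
#' `n0 = 2*p0 - r0 - o0`, so the two-daughters-per-division total is
#' conserved exactly for every input.
#'
#' @param p0 Number of labeling divisions (positive integer).
#' @param d A [division_proportions()] object.
#' @return A list of class `labeled_cohort` with integer counts `r0`, `o0`,
#'   `n0` and the generating `p0` and `d`.
#' @examples
#' init_labeled_cohort(1000, division_proportions(0.5, 0.11, 0.32, 0.07))
#' @export
init_labeled_cohort <- function(p0, d) {
  stopifnot(inherits(d, "division_proportions"))
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 <= 0) {
    stop("p0 must be a single positive number of labeling divisions")
  }
  p0 <- as.integer(round(p0))
  r0 <- as.integer(round(p0 * d$d1))
  o0 <- as.integer(round(p0 * (d$d1 + 2 * d$d3 + d$d4)))
  n0 <- 2L * p0 - r0 - o0
  if (n0 < 0L) stop("rounding produced a negative neuron count; use a larger p0")
  structure(list(r0 = r0, o0 = o0, n0 = n0, p0 = p0, d = d),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf(
    "Labeled cohort from %d labeling divisions: r0 = %d, o0 = %d, n0 = %d\n",
    x$p0, x$r0, x$o0, x$n0))
  invisible(x)
}
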