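#' Ecocline fecundity penalty
#'
#' Environmental productivity declines linearly from the core habitat
#' (`d = 0`) to the edge (`d = 7`): the fecundity penalty is `v = d * kappa`.
#'
#' @param d Habitat distance from the core, in \[0, 7\] (vectorised).
#' @param kappa Ecocline steepness (>= 0).
#' @return Numeric vector `d * kappa`.
#' @export
ecocline_penalty <- function(d, kappa) {
  if (any(d < 0 | d > 7)) stop("habitat distance d must lie in [0, 7]",
                               call. = FALSE)
  d * kappa
}

#' Cost of resistance
#'
#' `Phi = 1 - zeta * omega_f * h`, bound between 0 and 1, where `omega_f` is
#' the female's resistance phenotype and `h` the number of neighbouring males
#' (mating attempts experienced).
#'
#' @param omega_f Resistance phenotype, in \[0, 20\] (vectorised).
#' @param h Number of neighbouring males, in \[0, 8\].
#' @param zeta Cost slope (>= 0).
#' @return Numeric vector in \[0, 1\].
#' @export
resistance_cost <- function(omega_f, h, zeta) {
  pmin(1, pmax(0, 1 - zeta * omega_f * h))
}

#' Male mating-success probability
#'
#' The likelihood that a mating attempt succeeds decreases linearly with the
#' male's coerciveness and with the number of matings he has already
#' achieved: `J = 1 - xi * mu_m * q`, bound between 0 and 1. This is the
#' trade-off that makes coercion costly.
#'
#' @param mu_m Coercion phenotype, in \[0, 20\] (vectorised).
#' @param q Matings already achieved this generation (>= 0).
#' @param xi Trade-off slope (>= 0).
#' @return Numeric vector in \[0, 1\].
#' @export
mating_success_prob <- function(mu_m, q, xi) {
  pmin(1, pmax(0, 1 - xi * mu_m * q))
}

#' Fecundity of a mated female before the resistance cost
#'
#' Fecundity is maximal (`a`) at a single mating and declines at rate `m` per
#' additional mating; the ecocline penalty `v = d * kappa` is applied either
#' subtractively (`max(0, a - m*(x-1) - v)`, the default) or as a clamped
#' multiplier (`max(0, a - m*(x-1)) * max(0, 1 - v)`), depending on
#' `params$ecocline_mode`. The result is never negative.
#'
#' @param x Number of matings, in \[1, 8\] (vectorised).
#' @param d Habitat distance from the core.
#' @param params A [sim_config()] (or any list with `a`, `m`, `kappa`,
#'   `ecocline_mode`).
#' @return Numeric vector >= 0.
#' @export
base_fecundity <- function(x, d, params) {
  if (any(x < 1 | x > 8)) stop("x must lie in [1, 8]", call. = FALSE)
  v <- ecocline_penalty(d, params$kappa)
  core <- params$a - params$m * (x - 1)
  if (identical(params$ecocline_mode, "multiplicative")) {
    pmax(0, core) * pmax(0, 1 - v)
  } else {
    pmax(0, core - v)
  }
}

virgin_parthenogenetic_fecundity <- function(d, params) {
  v <- ecocline_penalty(d, params$kappa)
  if (identical(params$ecocline_mode, "multiplicative")) {
    pmax(0, params$epsilon * params$a) * pmax(0, 1 - v)
  } else {
    pmax(0, params$epsilon * params$a - v)
  }
}

#' Female fitness
#'
#' Lifetime offspring number `W` as a piecewise function of the number of
#' matings `x`. Wild-type (`pp`) virgins have zero fitness; virgin mutants
#' reproduce parthenogenetically with fecundity `epsilon * a` (penalised by
#' the ecocline). Mated females of either genotype are identical: fecundity
#' [base_fecundity()] declining in `x`. All pieces are multiplied by the cost
#' of resistance `Phi` ([resistance_cost()]). With `epsilon = 1`, a virgin
#' mutant has exactly the fitness of a once-mated female, so mating once is
#' never costly for any female.
#'
#' @param x Number of matings achieved, in \[0, 8\] (vectorised).
#' @param is_mutant Logical: carries at least one `P` allele.
#' @param omega_f Resistance phenotype.
#' @param h Number of neighbouring males.
#' @param d Habitat distance from the core.
#' @param params A [sim_config()] (or list with `a`, `m`, `epsilon`, `kappa`,
#'   `zeta`, `ecocline_mode`).
#' @return Numeric vector `W >= 0`.
#' @export
female_fitness <- function(x, is_mutant, omega_f, h, d, params) {
  if (any(x < 0 | x > 8)) stop("x must lie in [0, 8]", call. = FALSE)
  phi <- resistance_cost(omega_f, h, params$zeta)
  w <- numeric(length(x))
  virgin <- x == 0
  pvirgin <- virgin & is_mutant
  if (any(pvirgin)) {
    d_p <- if (length(d) > 1) d[pvirgin] else d
    w[pvirgin] <- virgin_parthenogenetic_fecundity(d_p, params)
  }
  if (any(!virgin)) {
    d_m <- if (length(d) > 1) d[!virgin] else d
    w[!virgin] <- base_fecundity(x[!virgin], d_m, params)
  }
  w * phi
}

#' Realised offspring number
#'
#' Fitness `W` is converted to a litter size by rounding to the nearest
#' integer, halves up (the rounding convention of most agent-based
#' modelling platforms).
#'
#' @param W Numeric vector of fitness values (>= 0).
#' @return Integer vector.
#' @export
offspring_count <- function(W) {
  as.integer(floor(W + 0.5))
}
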