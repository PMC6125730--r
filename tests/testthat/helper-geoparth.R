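## Small configurations for fast engine tests.
tiny_config <- function(...) {
  defaults <- list(n = 6, generations = 20, burn_in = 5, seed = 1)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(sim_config, defaults)
}

## A genome with every allele set to `value` and reproductive genotype
## given as P dosage (0 = pp, 1 = pP, 2 = PP).
flat_genome <- function(value = 0L, P_dosage = 0L) {
  g <- matrix(as.integer(value), 1, 42)
  g[, 41:42] <- c(as.integer(P_dosage >= 1), as.integer(P_dosage >= 2))
  g
}

## A hand-placed habitat population: genomes as rows, explicit sexes and
## patch cells, for constructing exact mating neighbourhoods.
hand_pop <- function(G, female, cell) {
  list(G = G, female = female, cell = as.integer(cell))
}

## Brute-force Vargha-Delaney A by pair enumeration (independent oracle).
brute_force_A <- function(xs, ys) {
  wins <- ties <- 0
  for (x in xs) for (y in ys) {
    if (x > y) wins <- wins + 1
    else if (x == y) ties <- ties + 1
  }
  (wins + 0.5 * ties) / (length(xs) * length(ys))
}

## Independent partial-correlation oracle: correlate the residuals of
## rank-regressions of predictor j and the response on the other predictors.
residual_partial_rho <- function(X, y, j) {
  Rk <- apply(cbind(X, y), 2, rank)
  others <- Rk[, setdiff(seq_len(ncol(X)), j), drop = FALSE]
  rx <- stats::resid(stats::lm(Rk[, j] ~ others))
  ry <- stats::resid(stats::lm(Rk[, ncol(Rk)] ~ others))
  stats::cor(rx, ry)
}
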