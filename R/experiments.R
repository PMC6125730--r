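#' Replicated simulation runs
#'
#' Runs `R` independent replicates of one configuration, with seeds
#' `seed_base, seed_base + 1, ..., seed_base + R - 1` (so replicate `k` can
#' be reproduced in isolation), and collects final-generation outcomes.
#'
#' @param config A [sim_config()].
#' @param R Number of replicates.
#' @param seed_base First replicate seed.
#' @return Object of class `geoparth_reps`: list with
#'   \describe{
#'     \item{habitats}{per-run, per-habitat final metrics (density =
#'       `count / N`).}
#'     \item{metapop}{per-run metapopulation-wide final metrics (see
#'       [metapop_state()]).}
#'     \item{medians}{per-habitat across-run medians.}
#'   }
#' @export
run_replicates <- function(config, R = 50, seed_base = 1) {
  stopifnot(R >= 1)
  hab <- vector("list", R)
  meta <- vector("list", R)
  for (k in seq_len(R)) {
    cfg <- config
    cfg$seed <- as.integer(seed_base + k - 1)
    sim <- run_simulation(cfg)
    f <- final_state(sim)
    f$density <- f$count / sim$final$N
    f$run <- k
    f$seed <- cfg$seed
    hab[[k]] <- f
    m <- metapop_state(sim)
    m$run <- k
    m$seed <- cfg$seed
    meta[[k]] <- m
  }
  hab <- do.call(rbind, hab)
  meta <- do.call(rbind, meta)
  metrics <- c("count", "density", "sex_ratio", "coercion_freq",
               "resistance_freq", "P_freq")
  med <- do.call(rbind, lapply(0:7, function(d) {
    sub <- hab[hab$habitat == d, , drop = FALSE]
    out <- data.frame(habitat = d)
    for (mm in metrics) out[[mm]] <- stats::median(sub[[mm]], na.rm = TRUE)
    out
  }))
  structure(list(habitats = hab, metapop = meta, medians = med,
                 config = config, R = R, seed_base = seed_base),
            class = "geoparth_reps")
}

#' @export
print.geoparth_reps <- function(x, ...) {
  cat(sprintf("<geoparth_reps> %d replicates (seeds %d..%d)\n", x$R,
              x$seed_base, x$seed_base + x$R - 1))
  cat("Per-habitat medians:\n")
  print(x$medians, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Parameter-grid experiment
#'
#' Runs replicated simulations over the full factorial grid of ecocline
#' steepness `kappa`, conflict intensity `m` and relative parthenogenetic
#' fecundity `epsilon`, and reports across-replicate medians per habitat.
#' Replicate seeds are disjoint across grid cells. A cell is flagged
#' `male_extinct` when more than half its runs end with no males anywhere in
#' the metapopulation.
#'
#' @param base_config A [sim_config()] providing all other parameters.
#' @param kappa,m,epsilon Numeric vectors of grid levels.
#' @param replicates Runs per cell.
#' @param seed_base First seed of the first cell.
#' @return Long data frame: one row per cell x habitat with median
#'   responses, plus the cell-level `male_extinct` flag.
#' @export
grid_experiment <- function(base_config, kappa, m, epsilon,
                            replicates = 50, seed_base = 1) {
  cells <- expand.grid(kappa = kappa, m = m, epsilon = epsilon,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cfg <- base_config
    cfg$kappa <- cells$kappa[ci]
    cfg$m <- cells$m[ci]
    cfg$epsilon <- cells$epsilon[ci]
    reps <- run_replicates(cfg, R = replicates,
                           seed_base = seed_base + (ci - 1L) * replicates)
    med <- reps$medians
    med$kappa <- cells$kappa[ci]
    med$m <- cells$m[ci]
    med$epsilon <- cells$epsilon[ci]
    med$male_extinct <- mean(reps$metapop$male_extinct) > 0.5
    out[[ci]] <- med
  }
  do.call(rbind, out)
}

default_perturbations <- function(config, a_change = 0.25) {
  list(
    no_coevolution = list(coevolution = FALSE),
    no_resistance_cost = list(zeta = 0),
    no_coercion_cost = list(xi = 0),
    higher_a = list(a = config$a * (1 + a_change)),
    lower_a = list(a = config$a * (1 - a_change))
  )
}

#' Robustness screen via A-tests
#'
#' Re-runs the baseline configuration with single assumptions independently
#' perturbed — sexual coevolution removed, cost of resistance removed, cost
#' of coercion removed, maximum productivity `a` raised or lowered — and
#' scores each perturbation with the Vargha-Delaney A-test of perturbed
#' versus baseline final outcomes. Responses are the core and edge sex
#' ratios and the metapopulation-wide pooled coercion and resistance allele
#' frequencies. `A >= 0.8` or `A <= 0.2` flags a qualitatively large (i.e.
#' non-robust) change.
#'
#' @param baseline A [sim_config()].
#' @param R Replicates per arm.
#' @param seed_base First baseline seed; each perturbation arm uses its own
#'   disjoint seed block.
#' @param perturbations Named list of single-parameter edits (named lists of
#'   config overrides); defaults to the five standard perturbations.
#' @param a_change Relative change applied to `a` in the productivity
#'   perturbations.
#' @return Data frame: one row per perturbation x response with `A` and the
#'   `large` flag.
#' @export
robustness_experiment <- function(baseline, R = 50, seed_base = 1,
                                  perturbations = NULL, a_change = 0.25) {
  if (is.null(perturbations)) {
    perturbations <- default_perturbations(baseline, a_change)
  }
  responses <- function(reps) {
    hab <- reps$habitats
    list(
      core_sex_ratio = hab$sex_ratio[hab$habitat == 0],
      edge_sex_ratio = hab$sex_ratio[hab$habitat == 7],
      coercion_freq = reps$metapop$coercion_freq,
      resistance_freq = reps$metapop$resistance_freq
    )
  }
  base_reps <- run_replicates(baseline, R = R, seed_base = seed_base)
  base_resp <- responses(base_reps)
  out <- list()
  for (pi in seq_along(perturbations)) {
    cfg <- baseline
    cfg[names(perturbations[[pi]])] <- perturbations[[pi]]
    cfg <- validate_config(cfg)
    reps <- run_replicates(cfg, R = R, seed_base = seed_base + pi * R)
    resp <- responses(reps)
    for (rn in names(resp)) {
      xs <- resp[[rn]][!is.na(resp[[rn]])]
      ys <- base_resp[[rn]][!is.na(base_resp[[rn]])]
      if (!length(xs) || !length(ys)) {
        A <- NA_real_; large <- NA
      } else {
        at <- vargha_delaney_A(xs, ys)
        A <- at$A; large <- at$large
      }
      out[[length(out) + 1L]] <- data.frame(
        perturbation = names(perturbations)[pi], response = rn,
        A = A, large = large)
    }
  }
  do.call(rbind, out)
}

#' Latin-hypercube sensitivity analysis
#'
#' Samples `sets` parameter sets for (`kappa`, `m`, `epsilon`, `gamma`) by
#' Latin-hypercube stratification, runs `replicates` simulations per set,
#' takes the median of each response over the replicates, and computes
#' Spearman partial rank correlations of every parameter against every
#' response. Responses: metapopulation-wide sex ratio, core and edge sex
#' ratios, and pooled coercion and resistance allele frequencies.
#'
#' @param base_config A [sim_config()] providing all other parameters.
#' @param ranges Named list of `c(lo, hi)` ranges for the sampled parameters
#'   (any subset of the [sim_config()] numeric parameters).
#' @param sets Number of parameter sets.
#' @param replicates Runs per set.
#' @param seed_base First seed; each set uses a disjoint seed block.
#' @return List of class `geoparth_lhs`: `sets` (sampled parameters),
#'   `responses` (median responses per set) and `correlations` (named list
#'   of [spearman_partial()] tables, one per response).
#' @export
sensitivity_experiment <- function(base_config,
                                   ranges = list(kappa = c(0, 0.7),
                                                 m = c(0, 2),
                                                 epsilon = c(0.7, 1),
                                                 gamma = c(0, 0.5)),
                                   sets = 100, replicates = 50,
                                   seed_base = 1) {
  params <- latin_hypercube_sample(ranges, sets = sets)
  resp <- vector("list", sets)
  for (si in seq_len(sets)) {
    cfg <- base_config
    cfg[names(params)] <- as.list(params[si, ])
    cfg <- validate_config(cfg)
    reps <- run_replicates(cfg, R = replicates,
                           seed_base = seed_base + (si - 1L) * replicates)
    hab <- reps$habitats
    med <- function(v) stats::median(v, na.rm = TRUE)
    resp[[si]] <- data.frame(
      sex_ratio = med(reps$metapop$sex_ratio),
      core_sex_ratio = med(hab$sex_ratio[hab$habitat == 0]),
      edge_sex_ratio = med(hab$sex_ratio[hab$habitat == 7]),
      coercion_freq = med(reps$metapop$coercion_freq),
      resistance_freq = med(reps$metapop$resistance_freq)
    )
  }
  resp <- do.call(rbind, resp)
  cors <- lapply(names(resp), function(rn) {
    y <- resp[[rn]]
    ok <- !is.na(y)
    if (sum(ok) < 5 || length(unique(y[ok])) == 1) return(NULL)
    spearman_partial(params[ok, , drop = FALSE], y[ok])
  })
  names(cors) <- names(resp)
  structure(list(sets = params, responses = resp, correlations = cors,
                 replicates = replicates, seed_base = seed_base),
            class = "geoparth_lhs")
}

#' @export
print.geoparth_lhs <- function(x, ...) {
  cat(sprintf("<geoparth_lhs> %d parameter sets x %d replicates\n",
              nrow(x$sets), x$replicates))
  for (rn in names(x$correlations)) {
    if (is.null(x$correlations[[rn]])) next
    cat("\nresponse:", rn, "\n")
    print.data.frame(x$correlations[[rn]], row.names = FALSE, digits = 4)
  }
  invisible(x)
}
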