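## Generation loop: mating -> reproduction -> dispersal -> recruitment.
## Discrete, non-overlapping generations; adults die after reproduction.

#' Mating phase within one habitat
#'
#' Males are processed in uniform random order; each male attempts every
#' neighbouring female (shuffled) exactly once. An attempt proceeds only if
#' the male's coercion is at least the female's resistance
#' (`mu_m >= omega_f`; skipped entirely when coevolution is disabled, in
#' which case resistance alleles are neutral), and succeeds with probability
#' `J = 1 - xi * mu_m * q` evaluated at the male's running mating count `q`,
#' so successes within a generation make later attempts harder. On success
#' the male enters the female's sperm pool.
#'
#' @param pop Habitat population (see [build_metapopulation()]).
#' @param config A [sim_config()].
#' @param nbr Precomputed Moore neighbour list (internal; built from
#'   `config$n` when omitted).
#' @return List with per-individual vectors `x` (matings achieved, females),
#'   `q` (matings achieved, males), `h` (neighbouring males, females) and
#'   `partners` (list of sperm-pool male indices per female).
#' @export
mating_phase <- function(pop, config, nbr = NULL) {
  k <- nrow(pop$G)
  x <- integer(k); q <- integer(k); h <- integer(k)
  partners <- vector("list", k)
  if (k == 0L) return(list(x = x, q = q, h = h, partners = partners))
  n <- config$n
  if (is.null(nbr)) nbr <- moore_neighbour_list(n)
  occ <- integer(n * n)
  occ[pop$cell] <- seq_len(k)
  female <- pop$female
  mu <- coercion_phenotype(pop$G)
  omega <- resistance_phenotype(pop$G)
  males <- which(!female)
  males <- males[sample.int(length(males))]
  xi <- config$xi
  coev <- config$coevolution
  ## pre-drawn uniforms for success tests (<= 8 attempts per male)
  u <- stats::runif(8L * length(males) + 1L)
  ptr <- 1L
  cells <- pop$cell
  for (mi in males) {
    nb <- occ[nbr[[cells[mi]]]]
    nb <- nb[nb > 0L]
    if (!length(nb)) next
    fnb <- nb[female[nb]]
    if (!length(fnb)) next
    h[fnb] <- h[fnb] + 1L
    if (length(fnb) > 1L) fnb <- fnb[sample.int(length(fnb))]
    mu_i <- mu[mi]
    q_i <- q[mi]
    for (fi in fnb) {
      if (coev && mu_i < omega[fi]) next
      J <- 1 - xi * mu_i * q_i
      ok <- J > 0 && u[ptr] < J
      ptr <- ptr + 1L
      if (ok) {
        q_i <- q_i + 1L
        x[fi] <- x[fi] + 1L
        partners[[fi]] <- c(partners[[fi]], mi)
      }
    }
    q[mi] <- q_i
  }
  list(x = x, q = q, h = h, partners = partners)
}

#' Reproduction phase within one habitat
#'
#' Each female produces `round(W)` offspring, with `W` from
#' [female_fitness()]. Mated females draw a single partner uniformly from
#' their sperm pool to sire all their offspring (one stored ejaculate
#' fertilises every egg); offspring sex is then 50/50. Unmated mutant
#' females produce automictic daughters; unmated wild-type females produce
#' nothing. Adults die after this phase.
#'
#' @param pop Habitat population.
#' @param mate Result of [mating_phase()] on the same population.
#' @param d Habitat distance from the core.
#' @param config A [sim_config()].
#' @param diagnose If `TRUE`, attach a per-female diagnostics data frame
#'   (resistance allele count, reproductive-mode genotype, mating status,
#'   realised fitness).
#' @return List with offspring genome matrix `G`, logical `female`, the
#'   per-female mean fitness `mean_W`, and optionally `diag`.
#' @export
reproduction_phase <- function(pop, mate, d, config, diagnose = FALSE) {
  fem <- which(pop$female)
  if (!length(fem)) {
    out <- list(G = pop$G[0, , drop = FALSE], female = logical(0),
                mean_W = NA_real_)
    if (diagnose) out$diag <- NULL
    return(out)
  }
  Gf <- pop$G[fem, , drop = FALSE]
  x <- mate$x[fem]
  h <- mate$h[fem]
  omega <- resistance_phenotype(Gf)
  mutant <- rowSums(Gf[, .REPRO_COLS, drop = FALSE]) >= 1
  W <- female_fitness(x, mutant, omega, h, d, config)
  k_off <- offspring_count(W)

  ## sexual broods: one father drawn per mother, sires the whole brood
  sex_m <- which(x > 0L & k_off > 0L)
  G_sex <- pop$G[0, , drop = FALSE]
  if (length(sex_m)) {
    fathers <- vapply(fem[sex_m], function(fi) {
      pp <- mate$partners[[fi]]
      pp[sample.int(length(pp), 1L)]
    }, integer(1))
    rep_idx <- rep(seq_along(sex_m), k_off[sex_m])
    M <- Gf[sex_m, , drop = FALSE][rep_idx, , drop = FALSE]
    Fa <- pop$G[fathers, , drop = FALSE][rep_idx, , drop = FALSE]
    G_sex <- mendelian_offspring(M, Fa)
  }
  fem_sex <- stats::runif(nrow(G_sex)) < 0.5

  ## automictic broods: virgin mutants, daughters only
  par_m <- which(x == 0L & mutant & k_off > 0L)
  G_par <- pop$G[0, , drop = FALSE]
  if (length(par_m)) {
    rep_idx <- rep(seq_along(par_m), k_off[par_m])
    G_par <- automictic_offspring(Gf[par_m, , drop = FALSE][rep_idx, ,
                                                            drop = FALSE])
  }

  out <- list(G = rbind(G_sex, G_par),
              female = c(fem_sex, rep(TRUE, nrow(G_par))),
              mean_W = mean(W))
  if (diagnose) {
    out$diag <- data.frame(
      omega_f = omega,
      genotype = repro_genotype(Gf),
      mated = x > 0L,
      x = x,
      h = h,
      W = W
    )
  }
  out
}

#' Dispersal phase
#'
#' Every offspring independently disperses with probability `gamma` to a
#' uniformly chosen neighbouring habitat along the chain. By default a
#' disperser landing in an uninhabitable (glaciated) habitat dies; with
#' `dispersal_lethal = FALSE` dispersers choose among habitable neighbours
#' only, staying home when none exists.
#'
#' @param pools List of 8 offspring pools (each with `G` and `female`).
#' @param habitable Logical vector of length 8.
#' @param config A [sim_config()].
#' @return List of 8 pools after dispersal.
#' @export
dispersal_phase <- function(pools, habitable, config) {
  gamma <- config$gamma
  if (gamma == 0) return(pools)
  ks <- vapply(pools, function(p) nrow(p$G), integer(1))
  home <- rep.int(1:8, ks)
  k_all <- length(home)
  dest <- home
  disperse <- stats::runif(k_all) < gamma
  if (any(disperse)) {
    ## interior habitats: coin-flip left/right; chain ends have one neighbour
    step <- ifelse(stats::runif(k_all) < 0.5, -1L, 1L)
    dest[disperse] <- home[disperse] + step[disperse]
    dest[disperse & home == 1L] <- 2L
    dest[disperse & home == 8L] <- 7L
    if (config$dispersal_lethal) {
      dest[!habitable[dest]] <- NA_integer_
    } else {
      ## choose among habitable neighbours only; stay home if none
      bad <- which(!habitable[dest])
      for (i in bad) {
        nbrs <- neighbour_habitats(home[i] - 1L) + 1L
        nbrs <- nbrs[habitable[nbrs]]
        dest[i] <- if (length(nbrs)) nbrs[sample.int(length(nbrs), 1L)] else
          home[i]
      }
    }
  }
  G_all <- do.call(rbind, lapply(pools, `[[`, "G"))
  fem_all <- unlist(lapply(pools, `[[`, "female"), use.names = FALSE)
  lapply(1:8, function(i) {
    keep <- which(!is.na(dest) & dest == i)
    list(G = G_all[keep, , drop = FALSE], female = fem_all[keep])
  })
}

#' Survival and recruitment phase
#'
#' Per habitat, if the offspring pool exceeds the local carrying capacity
#' `N = n^2` a uniform random excess is culled; survivors settle on distinct
#' random patches and mature into adults. Offspring in an uninhabitable
#' habitat do not recruit.
#'
#' @param metapop A `geoparth_metapop`.
#' @param pools Offspring pools after dispersal.
#' @return The metapopulation with the new adult generation in place.
#' @export
recruitment_phase <- function(metapop, pools) {
  N <- metapop$N
  for (i in 1:8) {
    if (!metapop$habitable[i]) {
      metapop$pops[[i]] <- empty_habitat_pop()
      next
    }
    p <- pools[[i]]
    k <- nrow(p$G)
    if (k > N) {
      keep <- sample.int(k, N)
      p$G <- p$G[keep, , drop = FALSE]
      p$female <- p$female[keep]
      k <- N
    }
    metapop$pops[[i]] <- new_habitat_pop(
      G = p$G, female = p$female,
      cell = if (k) sample.int(N, k) else integer(0)
    )
  }
  metapop
}

summarize_metapop <- function(metapop, generation, mean_W = rep(NA_real_, 8)) {
  k <- males <- integer(8)
  coer <- res <- pfr <- sr <- rep(NA_real_, 8)
  for (i in 1:8) {
    p <- metapop$pops[[i]]
    k[i] <- nrow(p$G)
    males[i] <- sum(!p$female)
    if (k[i]) {
      coer[i] <- sum(p$G[, .COERCION_COLS]) / (20 * k[i])
      res[i] <- sum(p$G[, .RESIST_COLS]) / (20 * k[i])
      pfr[i] <- sum(p$G[, .REPRO_COLS]) / (2 * k[i])
      sr[i] <- sum(p$female) / k[i]
    }
  }
  data.frame(generation = generation, habitat = 0:7, count = k,
             males = males, sex_ratio = sr, coercion_freq = coer,
             resistance_freq = res, P_freq = pfr, mean_W = mean_W)
}

#' Run a single simulation
#'
#' Initialises the metapopulation under the configured refuge scenario, runs
#' the burn-in of obligately sexual coevolution, then — at the start of
#' generation `burn_in` — simultaneously opens all glaciated habitats
#' (deglaciation) and introduces the dominant parthenogenesis allele `P`
#' into a random fraction of core adults, and continues the generation loop
#' (mating, reproduction, dispersal, recruitment, in that fixed order) to
#' the configured horizon.
#'
#' @param config A [sim_config()].
#' @return An object of class `geoparth_sim` with components
#'   \describe{
#'     \item{summary}{data frame of per-generation, per-habitat metrics:
#'       adult `count`, `males`, `sex_ratio` (proportion female),
#'       pooled `coercion_freq` and `resistance_freq` (allele sums over all
#'       adults divided by `20 * count`), `P_freq`, and `mean_W` (mean
#'       realised female fitness in the generation that produced these
#'       adults).}
#'     \item{diagnostics}{per-female fitness snapshots at the
#'       `diagnose_at` generations (or `NULL`).}
#'     \item{final}{the final `geoparth_metapop`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- run_simulation(sim_config(n = 6, generations = 12, burn_in = 5,
#'                                  seed = 1))
#' summary(sim)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "geoparth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  metapop <- build_metapopulation(config)
  nbr <- moore_neighbour_list(config$n)
  summaries <- list(summarize_metapop(metapop, 0L))
  diagnostics <- list()
  if (config$generations == 0L) {
    return(new_geoparth_sim(summaries, diagnostics, metapop, config))
  }
  for (gen in seq_len(config$generations)) {
    if (gen == config$burn_in) {
      metapop <- open_glaciated_habitats(metapop)
      if (!config$pulse_recurrent) {
        pulsed <- introduce_P_pulse(metapop$pops[[1]]$G,
                                    fraction = config$pulse_fraction,
                                    zygosity = config$pulse_zygosity)
        metapop$pops[[1]]$G <- pulsed$G
      }
    }
    if (config$pulse_recurrent && gen >= config$burn_in) {
      G <- metapop$pops[[1]]$G
      pp <- which(rowSums(G[, .REPRO_COLS, drop = FALSE]) == 0)
      mut <- pp[stats::runif(length(pp)) < config$pulse_fraction]
      if (length(mut)) {
        G[mut, .REPRO_COLS[1]] <- 1L
        metapop$pops[[1]]$G <- G
      }
    }
    diagnose <- gen %in% config$diagnose_at
    pools <- vector("list", 8)
    mean_W <- rep(NA_real_, 8)
    for (i in 1:8) {
      pop <- metapop$pops[[i]]
      mate <- mating_phase(pop, config, nbr)
      off <- reproduction_phase(pop, mate, d = i - 1L, config,
                                diagnose = diagnose)
      mean_W[i] <- off$mean_W
      if (diagnose && !is.null(off$diag) && nrow(off$diag)) {
        dg <- off$diag
        dg$generation <- gen
        dg$habitat <- i - 1L
        diagnostics[[length(diagnostics) + 1L]] <- dg
      }
      pools[[i]] <- list(G = off$G, female = off$female)
    }
    pools <- dispersal_phase(pools, metapop$habitable, config)
    metapop <- recruitment_phase(metapop, pools)
    if (gen %% config$record_every == 0L || gen == config$generations) {
      summaries[[length(summaries) + 1L]] <-
        summarize_metapop(metapop, gen, mean_W)
    }
  }
  new_geoparth_sim(summaries, diagnostics, metapop, config)
}

new_geoparth_sim <- function(summaries, diagnostics, metapop, config) {
  structure(list(
    summary = do.call(rbind, summaries),
    diagnostics = if (length(diagnostics)) do.call(rbind, diagnostics),
    final = metapop,
    config = config
  ), class = "geoparth_sim")
}

#' Final-generation summary of a simulation
#'
#' @param sim A `geoparth_sim`.
#' @return Data frame: the per-habitat metrics of the last recorded
#'   generation.
#' @export
final_state <- function(sim) {
  s <- sim$summary
  s[s$generation == max(s$generation), , drop = FALSE]
}

#' Metapopulation-wide aggregates at the final generation
#'
#' Pools all adults across habitats: total count, male count, sex ratio,
#' pooled coercion/resistance allele frequencies, `P`-allele frequency and
#' wild-type `p`-allele frequency.
#'
#' @param sim A `geoparth_sim`.
#' @return One-row data frame.
#' @export
metapop_state <- function(sim) {
  f <- final_state(sim)
  total <- sum(f$count)
  males <- sum(f$males)
  wmean <- function(v) {
    if (total == 0) return(NA_real_)
    sum(v * f$count, na.rm = TRUE) / total
  }
  data.frame(
    generation = f$generation[1],
    count = total,
    males = males,
    sex_ratio = if (total) 1 - males / total else NA_real_,
    coercion_freq = wmean(f$coercion_freq),
    resistance_freq = wmean(f$resistance_freq),
    P_freq = wmean(f$P_freq),
    p_freq = if (total) 1 - wmean(f$P_freq) else NA_real_,
    male_extinct = total > 0 && males == 0
  )
}

#' @export
print.geoparth_sim <- function(x, ...) {
  cat("<geoparth_sim>\n")
  cat(sprintf("  %d generations recorded (burn-in %d), 8 habitats of N=%d\n",
              max(x$summary$generation), x$config$burn_in, x$final$N))
  m <- metapop_state(x)
  cat(sprintf("  final: %d adults (%d males), sex ratio %.3f, P freq %.3f\n",
              m$count, m$males, m$sex_ratio, m$P_freq))
  invisible(x)
}

#' @export
summary.geoparth_sim <- function(object, ...) {
  out <- list(final = final_state(object),
              metapop = metapop_state(object),
              config = object$config)
  class(out) <- "summary.geoparth_sim"
  out
}

#' @export
print.summary.geoparth_sim <- function(x, ...) {
  cat("Final generation", x$final$generation[1], "per habitat:\n")
  print(x$final[, c("habitat", "count", "males", "sex_ratio",
                    "coercion_freq", "resistance_freq", "P_freq")],
        row.names = FALSE, digits = 3)
  cat("\nMetapopulation:\n")
  print(x$metapop[, c("count", "males", "sex_ratio", "P_freq")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot simulation trajectories
#'
#' One line per habitat (core darkest) for the chosen metric over
#' generations.
#'
#' @param x A `geoparth_sim`.
#' @param metric Column of the summary to plot.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.geoparth_sim <- function(x, metric = c("sex_ratio", "count", "P_freq",
                                            "coercion_freq",
                                            "resistance_freq"), ...) {
  metric <- match.arg(metric)
  s <- x$summary
  gens <- sort(unique(s$generation))
  mat <- sapply(0:7, function(d) s[[metric]][s$habitat == d])
  cols <- grDevices::hcl.colors(8, "Viridis")
  graphics::matplot(gens, mat, type = "l", lty = 1, col = cols,
                    xlab = "generation", ylab = metric, ...)
  graphics::legend("topleft", legend = paste0("d=", 0:7), col = cols,
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
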