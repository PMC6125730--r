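#' Build a simulation configuration
#'
#' Assembles and validates every free parameter of the model. Defaults give
#' the baseline conditions used throughout: maximum per-female productivity
#' `a = 6` offspring, intense sexual conflict `m = 1.5`, relative
#' parthenogenetic fecundity `epsilon = 0.9`, a flat environment
#' (`kappa = 0`), weak costs of resistance (`zeta = 0.005`) and coercion
#' (`xi = 0.01`), and moderate dispersal (`gamma = 0.1`).
#'
#' @param a Fecundity maximum at a single mating (offspring). Must be > 0.
#' @param m Rate of fecundity decline per mating beyond the first
#'   (offspring/mating); larger `m` means more intense sexual conflict.
#' @param epsilon Fecundity of virgin parthenogenetic reproduction relative to
#'   `a`, usually in \[0, 1\].
#' @param kappa Steepness of the productivity ecocline: the fecundity penalty
#'   is `v = d * kappa` for a habitat `d` steps from the core.
#' @param zeta Slope of the cost of resistance `Phi = 1 - zeta * omega_f * h`.
#' @param xi Slope of the male coercion trade-off `J = 1 - xi * mu_m * q`.
#' @param gamma Per-offspring dispersal probability, in \[0, 1\].
#' @param n Habitat grid side; each habitat is an `n x n` patch grid with
#'   carrying capacity `N = n^2`.
#' @param generations Number of generations to simulate.
#' @param burn_in Burn-in length; deglaciation and the mutation pulse happen
#'   at the start of generation `burn_in`. Must be < `generations` unless
#'   `generations` is 0.
#' @param refuge Refuge scenario: `"none"` (all 8 habitats start occupied),
#'   `"large"` (habitats 0-3) or `"small"` (core habitat only).
#' @param coevolution If `FALSE`, the coercion-resistance threshold is ignored
#'   and every neighbouring female is courted (resistance alleles become
#'   neutral).
#' @param ecocline_mode `"subtractive"` (default): fecundity is
#'   `max(0, a - m*(x-1) - d*kappa)`; `"multiplicative"`: the penalty scales
#'   fecundity by `max(0, 1 - d*kappa)`.
#' @param pulse_fraction Fraction of core adults converted to mutants at the
#'   end of the burn-in.
#' @param pulse_zygosity `"half"` (half the mutants `pP`, half `PP`) or
#'   `"het"` (all mutants heterozygous `pP`).
#' @param pulse_recurrent If `TRUE`, instead of a single pulse each wild-type
#'   core adult mutates to `pP` with probability `pulse_fraction` in every
#'   generation from the end of the burn-in onwards.
#' @param dispersal_lethal If `TRUE` (default) dispersers that pick an
#'   uninhabitable (glaciated) neighbour habitat die; if `FALSE` they choose
#'   uniformly among habitable neighbours and stay home when none exists.
#' @param record_every Record a generation summary every `record_every`
#'   generations (the initial state and the final generation are always
#'   recorded).
#' @param diagnose_at Integer vector of generations at which to snapshot
#'   per-female fitness diagnostics (see [epistasis_diagnostics()]).
#' @param seed Integer RNG seed, or `NULL` to leave the RNG stream alone.
#'
#' @return An object of class `geoparth_config`: a validated named list.
#' @seealso [preset_config()], [load_config()], [run_simulation()]
#' @examples
#' cfg <- sim_config(n = 5, generations = 10, burn_in = 2, seed = 1)
#' cfg
#' @export
sim_config <- function(a = 6, m = 1.5, epsilon = 0.9, kappa = 0,
                       zeta = 0.005, xi = 0.01, gamma = 0.1,
                       n = 20, generations = 500, burn_in = 50,
                       refuge = c("none", "large", "small"),
                       coevolution = TRUE,
                       ecocline_mode = c("subtractive", "multiplicative"),
                       pulse_fraction = 0.25,
                       pulse_zygosity = c("half", "het"),
                       pulse_recurrent = FALSE,
                       dispersal_lethal = TRUE,
                       record_every = 1,
                       diagnose_at = integer(0),
                       seed = NULL) {
  cfg <- list(
    a = a, m = m, epsilon = epsilon, kappa = kappa,
    zeta = zeta, xi = xi, gamma = gamma,
    n = as.integer(n), generations = as.integer(generations),
    burn_in = as.integer(burn_in),
    refuge = match.arg(refuge),
    coevolution = isTRUE(coevolution),
    ecocline_mode = match.arg(ecocline_mode),
    pulse_fraction = pulse_fraction,
    pulse_zygosity = match.arg(pulse_zygosity),
    pulse_recurrent = isTRUE(pulse_recurrent),
    dispersal_lethal = isTRUE(dispersal_lethal),
    record_every = as.integer(record_every),
    diagnose_at = as.integer(diagnose_at),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$a) && cfg$a > 0, "a", "must be a single value > 0")
  chk(num1(cfg$m) && cfg$m >= 0, "m", "must be >= 0")
  chk(num1(cfg$epsilon) && cfg$epsilon >= 0, "epsilon", "must be >= 0")
  chk(num1(cfg$kappa) && cfg$kappa >= 0, "kappa", "must be >= 0")
  chk(num1(cfg$zeta) && cfg$zeta >= 0, "zeta", "must be >= 0")
  chk(num1(cfg$xi) && cfg$xi >= 0, "xi", "must be >= 0")
  chk(num1(cfg$gamma) && cfg$gamma >= 0 && cfg$gamma <= 1, "gamma",
      "must lie in [0, 1]")
  chk(num1(cfg$n) && cfg$n >= 1, "n", "must be a positive integer")
  chk(num1(cfg$generations) && cfg$generations >= 0, "generations",
      "must be >= 0")
  chk(num1(cfg$burn_in) && cfg$burn_in >= 1, "burn_in", "must be >= 1")
  chk(cfg$generations == 0 || cfg$burn_in <= cfg$generations, "burn_in",
      "must not exceed `generations`")
  chk(num1(cfg$pulse_fraction) && cfg$pulse_fraction >= 0 &&
        cfg$pulse_fraction <= 1, "pulse_fraction", "must lie in [0, 1]")
  chk(num1(cfg$record_every) && cfg$record_every >= 1, "record_every",
      "must be >= 1")
  chk(all(cfg$diagnose_at >= 1), "diagnose_at",
      "generations must be positive")
  structure(cfg, class = "geoparth_config")
}

#' Named configuration presets
#'
#' `"fig5"` is the epistasis-diagnostics scenario: a small refuge (core
#' habitat only), a steep ecocline (`kappa = 0.7`), intense conflict
#' (`m = 1.5`) and `epsilon = 0.9`, with fitness snapshots taken at
#' generations 75 and 250.
#'
#' @param preset Preset name (currently only `"fig5"`).
#' @param ... Overrides passed on to [sim_config()].
#' @return A `geoparth_config`.
#' @examples
#' preset_config("fig5", n = 10, generations = 100)
#' @export
preset_config <- function(preset = "fig5", ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    fig5 = list(refuge = "small", kappa = 0.7, m = 1.5, epsilon = 0.9,
                diagnose_at = c(75L, 250L))
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_config, base)
}

#' Load a configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are rejected.
#' Values supplied in `...` override the file.
#'
#' @param path Path to a YAML file (may be empty or contain a subset of keys).
#' @param ... Overrides, as for [sim_config()].
#' @return A `geoparth_config`.
#' @export
load_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ## keep YAML-1.1 boolean-like scalars (notably the key `n`) as strings,
  ## then convert the fields that really are logical
  keep <- function(x) x
  vals <- yaml::yaml.load(paste(readLines(path, warn = FALSE),
                                collapse = "\n"),
                          handlers = list("bool#yes" = keep,
                                          "bool#no" = keep))
  if (is.null(vals)) vals <- list()
  for (fld in c("coevolution", "pulse_recurrent", "dispersal_lethal")) {
    if (is.character(vals[[fld]])) {
      vals[[fld]] <- tolower(vals[[fld]]) %in% c("true", "yes", "y", "on")
    }
  }
  if (!is.list(vals)) stop("config file must contain a YAML mapping",
                           call. = FALSE)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  over <- list(...)
  vals[names(over)] <- over
  do.call(sim_config, vals)
}

#' @export
print.geoparth_config <- function(x, ...) {
  cat("<geoparth_config>\n")
  cat(sprintf("  fitness: a=%g m=%g epsilon=%g kappa=%g (%s) zeta=%g xi=%g\n",
              x$a, x$m, x$epsilon, x$kappa, x$ecocline_mode, x$zeta, x$xi))
  cat(sprintf("  landscape: 8 habitats of %d x %d patches (N=%d), refuge=%s\n",
              x$n, x$n, x$n^2, x$refuge))
  cat(sprintf("  schedule: %d generations, burn-in %d, dispersal gamma=%g\n",
              x$generations, x$burn_in, x$gamma))
  cat(sprintf("  mutation pulse: fraction=%g, zygosity=%s%s\n",
              x$pulse_fraction, x$pulse_zygosity,
              if (x$pulse_recurrent) " (recurrent)" else ""))
  cat(sprintf("  coevolution=%s, seed=%s\n",
              x$coevolution, if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}
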