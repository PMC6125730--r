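#' Moore neighbourhood of a patch
#'
#' Patches within a habitat form an `n x n` grid indexed column-major
#' (`cell = (col - 1) * n + row`). The Moore neighbourhood is the up-to-8
#' cells sharing an edge or vertex with the focal cell; grid borders do not
#' wrap, so edge and corner patches have fewer neighbours.
#'
#' @param cell Patch index in `1:n^2`.
#' @param n Grid side.
#' @return Integer vector of neighbouring cell indices (3-8 cells).
#' @export
moore_neighbour_cells <- function(cell, n) {
  row <- ((cell - 1L) %% n) + 1L
  col <- ((cell - 1L) %/% n) + 1L
  out <- integer(0)
  for (dc in -1:1) {
    for (dr in -1:1) {
      if (dr == 0L && dc == 0L) next
      r <- row + dr; cc <- col + dc
      if (r >= 1L && r <= n && cc >= 1L && cc <= n) {
        out <- c(out, (cc - 1L) * n + r)
      }
    }
  }
  out
}

## Precomputed neighbour list for all n^2 cells (hot path).
moore_neighbour_list <- function(n) {
  lapply(seq_len(n * n), moore_neighbour_cells, n = n)
}

#' Neighbouring habitats along the core-to-edge chain
#'
#' The eight habitats form a path (distances `d = 0:7` from the core) with
#' explicit boundaries: habitat `d` neighbours `d - 1` and `d + 1` where they
#' exist, with no wraparound.
#'
#' @param d Habitat distance from the core, in `0:7`.
#' @return Integer vector of neighbouring habitat distances.
#' @export
neighbour_habitats <- function(d) {
  if (d < 0 || d > 7) stop("d must lie in [0, 7]", call. = FALSE)
  setdiff(intersect(c(d - 1L, d + 1L), 0:7), integer(0))
}

new_habitat_pop <- function(G, female, cell) {
  list(G = G, female = female, cell = cell)
}

empty_habitat_pop <- function() {
  new_habitat_pop(matrix(0L, 0, .N_GENOME_COLS), logical(0), integer(0))
}

#' Build and initialize the metapopulation
#'
#' Creates the chain of eight habitats, marks habitability according to the
#' refuge scenario, and fills every habitable habitat with `N = n^2` founder
#' adults (random genomes, random sex, one per patch). Scenarios: `"none"`
#' leaves all habitats habitable, `"large"` restricts the founders to the
#' four core-most habitats, `"small"` to the core habitat alone; the
#' remaining habitats are uninhabitable (glaciated) until
#' [open_glaciated_habitats()] is called.
#'
#' @param config A [sim_config()].
#' @return An object of class `geoparth_metapop`: a list with `n`, `N`,
#'   `habitable` (logical of length 8) and `pops` (list of 8 habitat
#'   populations, each holding a genome matrix `G`, a logical `female`
#'   vector, and patch indices `cell`).
#' @export
build_metapopulation <- function(config) {
  n <- config$n
  N <- n * n
  habitable <- switch(config$refuge,
    none = rep(TRUE, 8),
    large = c(rep(TRUE, 4), rep(FALSE, 4)),
    small = c(TRUE, rep(FALSE, 7))
  )
  pops <- vector("list", 8)
  for (i in 1:8) {
    if (habitable[i]) {
      pops[[i]] <- new_habitat_pop(
        G = random_genomes(N),
        female = stats::runif(N) < 0.5,
        cell = sample.int(N, N)
      )
    } else {
      pops[[i]] <- empty_habitat_pop()
    }
  }
  structure(list(n = n, N = N, habitable = habitable, pops = pops),
            class = "geoparth_metapop")
}

#' Open glaciated habitats
#'
#' Switches every habitat to habitable (deglaciation); occupancy is left
#' unchanged. Idempotent; a no-op under the `"none"` refuge scenario.
#'
#' @param metapop A `geoparth_metapop`.
#' @return The modified metapopulation.
#' @export
open_glaciated_habitats <- function(metapop) {
  metapop$habitable <- rep(TRUE, 8)
  metapop
}

#' Occupants of the Moore neighbourhood of a patch
#'
#' @param pop A habitat population (element of `metapop$pops`).
#' @param cell Focal patch index.
#' @param n Grid side.
#' @return Integer indices (rows of `pop$G`) of the occupants of the up-to-8
#'   neighbouring patches in the same habitat.
#' @export
moore_neighbours <- function(pop, cell, n) {
  occ <- integer(n * n)
  occ[pop$cell] <- seq_along(pop$cell)
  idx <- occ[moore_neighbour_cells(cell, n)]
  idx[idx > 0L]
}
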