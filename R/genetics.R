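#' Draw random founder genomes
#'
#' Each of the 20 antagonistic loci (10 coercion, 10 resistance) receives two
#' independent alleles from the discrete uniform distribution U\{0, 1\}; the
#' reproductive-mode locus is fixed at the wild-type `pp` genotype.
#'
#' Genomes are stored as an integer matrix with one row per individual and 42
#' columns: two explicit allele slots per locus (columns 1-20 coercion, 21-40
#' resistance, 41-42 reproductive mode with 0 = `p`, 1 = `P`). Explicit slots,
#' rather than dosage counts, are required because automictic inheritance
#' draws from the mother's two alleles with replacement.
#'
#' @param k Number of genomes to draw.
#' @return Integer matrix `k x 42`.
#' @examples
#' set.seed(1)
#' g <- random_genomes(3)
#' coercion_phenotype(g)
#' @export
random_genomes <- function(k) {
  G <- matrix(0L, nrow = k, ncol = .N_GENOME_COLS)
  G[, c(.COERCION_COLS, .RESIST_COLS)] <-
    sample(0:1, k * 40, replace = TRUE)
  G
}

#' Sex-limited polygenic phenotypes
#'
#' Coercion (`mu_m`, expressed in males) and resistance (`omega_f`, expressed
#' in females) are additive co-dominant sums of the 20 allele values at the
#' respective 10 loci, so each phenotype is an integer in \[0, 20\].
#'
#' @param G Genome matrix (rows = individuals) as from [random_genomes()].
#' @return Integer vector of phenotype values.
#' @export
coercion_phenotype <- function(G) {
  as.integer(rowSums(G[, .COERCION_COLS, drop = FALSE]))
}

#' @rdname coercion_phenotype
#' @export
resistance_phenotype <- function(G) {
  as.integer(rowSums(G[, .RESIST_COLS, drop = FALSE]))
}

#' Reproductive-mode genotype
#'
#' @param G Genome matrix.
#' @return Factor with levels `pp`, `pP`, `PP` (dosage of the dominant
#'   mutant allele `P`: 0, 1 or 2).
#' @export
repro_genotype <- function(G) {
  dosage <- rowSums(G[, .REPRO_COLS, drop = FALSE])
  factor(c("pp", "pP", "PP")[dosage + 1L], levels = c("pp", "pP", "PP"))
}

#' Capacity for parthenogenetic reproduction
#'
#' `P` is dominant with a female-limited effect: only virgin (unmated)
#' females carrying at least one `P` allele can produce daughters asexually.
#' Females that received any sperm forgo parthenogenesis.
#'
#' @param female Logical vector, `TRUE` for females.
#' @param G Genome matrix.
#' @param matings Integer vector of matings achieved (`x`).
#' @return Logical vector.
#' @export
can_reproduce_parthenogenetically <- function(female, G, matings) {
  female & rowSums(G[, .REPRO_COLS, drop = FALSE]) >= 1 & matings == 0
}

#' Sexual (Mendelian) inheritance
#'
#' For every one of the 21 loci the offspring receives one uniformly chosen
#' allele from the mother and one from the father; loci assort independently
#' (no linkage).
#'
#' @param M,F Genome matrices of mothers and fathers, row-aligned (row `i` of
#'   `M` and `F` are the parents of offspring `i`).
#' @return Integer genome matrix with `nrow(M)` rows.
#' @export
mendelian_offspring <- function(M, F) {
  k <- nrow(M)
  if (k == 0L) return(M[0, , drop = FALSE])
  slot1 <- seq(1L, 41L, by = 2L)
  slot2 <- slot1 + 1L
  G <- matrix(0L, nrow = k, ncol = .N_GENOME_COLS)
  pick_m <- matrix(stats::runif(k * 21L) < 0.5, k, 21L)
  pick_f <- matrix(stats::runif(k * 21L) < 0.5, k, 21L)
  gm <- M[, slot1, drop = FALSE]
  gm[pick_m] <- M[, slot2, drop = FALSE][pick_m]
  gf <- F[, slot1, drop = FALSE]
  gf[pick_f] <- F[, slot2, drop = FALSE][pick_f]
  G[, slot1] <- gm
  G[, slot2] <- gf
  G
}

#' Automictic (parthenogenetic) inheritance
#'
#' Offspring receive, at every locus, two draws *with replacement* from the
#' mother's two alleles at that locus. A heterozygous maternal locus can thus
#' become homozygous in the daughter (a form of recombination characteristic
#' of automixis), while a homozygous maternal locus always stays homozygous.
#'
#' @param M Genome matrix of mothers, one row per offspring (repeat rows for
#'   multiple daughters of the same mother). Every mother must carry at least
#'   one `P` allele.
#' @return Integer genome matrix with `nrow(M)` rows.
#' @export
automictic_offspring <- function(M) {
  k <- nrow(M)
  if (k == 0L) return(M[0, , drop = FALSE])
  if (any(rowSums(M[, .REPRO_COLS, drop = FALSE]) == 0)) {
    stop("automictic reproduction by a `pp` mother", call. = FALSE)
  }
  slot1 <- seq(1L, 41L, by = 2L)
  slot2 <- slot1 + 1L
  G <- matrix(0L, nrow = k, ncol = .N_GENOME_COLS)
  Ma <- M[, slot1, drop = FALSE]; Mb <- M[, slot2, drop = FALSE]
  pick1 <- matrix(stats::runif(k * 21L) < 0.5, k, 21L)
  pick2 <- matrix(stats::runif(k * 21L) < 0.5, k, 21L)
  g1 <- Ma; g1[pick1] <- Mb[pick1]
  g2 <- Ma; g2[pick2] <- Mb[pick2]
  G[, slot1] <- g1
  G[, slot2] <- g2
  G
}

#' Introduce the mutant allele for parthenogenesis
#'
#' A single mutation event converts a uniformly chosen fraction of the given
#' individuals to mutants. With `zygosity = "half"`, half become heterozygous
#' `pP` and half homozygous `PP` (for an odd mutant count `k` the split is
#' `ceiling(k/2)` `pP` and `floor(k/2)` `PP`); with `zygosity = "het"` all
#' mutants become `pP`.
#'
#' @param G Genome matrix of the target (core) adults.
#' @param fraction Fraction of individuals to mutate; the mutant count is
#'   `fraction * nrow(G)` rounded to the nearest integer.
#' @param zygosity `"half"` or `"het"`.
#' @return List with `G` (modified matrix) and `n_mutated`.
#' @export
introduce_P_pulse <- function(G, fraction = 0.25,
                              zygosity = c("half", "het")) {
  zygosity <- match.arg(zygosity)
  k_pop <- nrow(G)
  if (k_pop == 0L) {
    warning("empty population: no mutants introduced")
    return(list(G = G, n_mutated = 0L))
  }
  k <- as.integer(floor(fraction * k_pop + 0.5))
  if (k == 0L) return(list(G = G, n_mutated = 0L))
  idx <- sample.int(k_pop, k)
  if (zygosity == "het") {
    G[idx, .REPRO_COLS[1]] <- 1L
  } else {
    n_het <- as.integer(ceiling(k / 2))
    het <- idx[seq_len(n_het)]
    hom <- idx[-seq_len(n_het)]
    G[het, .REPRO_COLS[1]] <- 1L
    G[hom, .REPRO_COLS] <- 1L
  }
  list(G = G, n_mutated = k)
}
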