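#' Vargha-Delaney A effect size
#'
#' The probability that a random observation from `xs` exceeds a random
#' observation from `ys`, with ties counted half:
#' `A = (#(x > y) + 0.5 * #(x = y)) / (n * m)` over all cross pairs.
#' Computed via the rank-sum identity (equivalent to the Mann-Whitney
#' statistic), so it is invariant under strictly monotone transforms of both
#' samples. Effects with `A >= 0.8` or `A <= 0.2` are conventionally
#' qualitatively large.
#'
#' @param xs,ys Numeric samples (non-empty; NAs removed).
#' @return List of class `geoparth_atest`: `A`, sample sizes `n` and `m`, and
#'   logical `large`.
#' @examples
#' vargha_delaney_A(c(2, 3), c(0, 1)) # complete separation: A = 1
#' @export
vargha_delaney_A <- function(xs, ys) {
  xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
  n <- length(xs); m <- length(ys)
  if (n == 0L || m == 0L) stop("both samples must be non-empty",
                               call. = FALSE)
  r <- rank(c(xs, ys))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  A <- U / (n * m)
  structure(list(A = A, n = n, m = m, large = A >= 0.8 || A <= 0.2),
            class = "geoparth_atest")
}

#' @export
print.geoparth_atest <- function(x, ...) {
  cat(sprintf("Vargha-Delaney A = %.4f (n = %d, m = %d)%s\n", x$A, x$n, x$m,
              if (x$large) " [qualitatively large]" else ""))
  invisible(x)
}

#' Latin-hypercube parameter sets
#'
#' Stratified sampling: for each parameter the range is cut into `sets`
#' equal-width bins, the bins are assigned to the parameter sets by a random
#' permutation (each bin used exactly once, i.e. without replacement), and a
#' value is drawn uniformly within each assigned bin. Rows are the sampled
#' parameter sets.
#'
#' @param ranges Named list of length-2 numeric vectors `c(lo, hi)`, one per
#'   parameter (e.g. `list(kappa = c(0, 0.7), m = c(0, 2))`).
#' @param sets Number of parameter sets (= number of bins per parameter).
#' @return Data frame with `sets` rows and one column per parameter.
#' @examples
#' set.seed(1)
#' latin_hypercube_sample(list(kappa = c(0, 0.7), m = c(0, 2)), sets = 10)
#' @export
latin_hypercube_sample <- function(ranges, sets = 100) {
  stopifnot(is.list(ranges), length(ranges) >= 1, sets >= 1)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !is.finite(r[1]) || !is.finite(r[2]) ||
        r[1] >= r[2]) {
      stop("degenerate range for `", nm, "`: need c(lo, hi) with lo < hi",
           call. = FALSE)
    }
  }
  u <- lhs::randomLHS(sets, length(ranges))
  out <- as.data.frame(mapply(function(col, r) r[1] + col * (r[2] - r[1]),
                              as.data.frame(u), ranges))
  names(out) <- names(ranges)
  out
}

#' Spearman partial rank correlations
#'
#' For each predictor, the partial correlation between its ranks and the
#' ranks of the response, controlling for the ranks of all other predictors:
#' both the predictor's and the response's ranks are regressed on the
#' controlled ranks and the residuals are correlated (equivalent to the
#' precision-matrix formula whenever the rank correlation matrix is
#' invertible, but also defined when a predictor and the response are
#' perfectly rank-correlated). Ties receive average ranks. p-values use the
#' t approximation with `df = n - 2 - g` where `g` is the number of
#' controlled predictors.
#'
#' @param predictors Numeric matrix or data frame (columns = parameters,
#'   e.g. kappa, m, epsilon, gamma).
#' @param response Numeric vector of the (median) response variable.
#' @return Object of class `geoparth_sensitivity`: data frame with one row
#'   per predictor (`rho`, `p_value`, `df`).
#' @export
spearman_partial <- function(predictors, response) {
  X <- as.matrix(predictors)
  y <- as.numeric(response)
  n <- length(y)
  if (nrow(X) != n) stop("predictor rows must match response length",
                         call. = FALSE)
  if (n < 5) stop("need at least 5 observations", call. = FALSE)
  dat <- cbind(X, response = y)
  if (any(apply(dat, 2, function(v) length(unique(v)) == 1))) {
    stop("constant column: ranks undefined", call. = FALSE)
  }
  Rk <- apply(dat, 2, rank) # average ranks for ties
  p <- ncol(X)
  yi <- p + 1L
  rho <- vapply(seq_len(p), function(j) {
    ctrl <- Rk[, setdiff(seq_len(p), j), drop = FALSE]
    if (ncol(ctrl)) {
      Q <- cbind(1, ctrl)
      rx <- stats::lm.fit(Q, Rk[, j])$residuals
      ry <- stats::lm.fit(Q, Rk[, yi])$residuals
    } else {
      rx <- Rk[, j] - mean(Rk[, j])
      ry <- Rk[, yi] - mean(Rk[, yi])
    }
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
    stats::cor(rx, ry)
  }, numeric(1))
  g <- p - 1L
  df <- n - 2L - g
  tval <- rho * sqrt(df / pmax(1e-300, 1 - rho^2))
  pv <- 2 * stats::pt(-abs(tval), df)
  out <- data.frame(parameter = colnames(X), rho = rho, p_value = pv,
                    df = df, row.names = NULL)
  class(out) <- c("geoparth_sensitivity", "data.frame")
  out
}

#' @export
print.geoparth_sensitivity <- function(x, ...) {
  cat("Spearman partial rank correlations:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Epistasis and linkage diagnostics from a fitness snapshot
#'
#' Summarises a per-female fitness snapshot (from a simulation run with
#' `diagnose_at` set): mean realised fitness `W` in every cell of
#' (resistance allele count) x (reproductive-mode genotype) x (mating
#' status), and the covariance between `P`-allele dosage and resistance
#' allele count across females (the linkage-disequilibrium summary that
#' drives core female bias).
#'
#' @param snapshot Data frame as stored in `sim$diagnostics` (columns
#'   `omega_f`, `genotype`, `mated`, `W`; optionally `generation`,
#'   `habitat`).
#' @return List with `cells` (data frame of cell means and counts; cells
#'   with no females are absent) and `ld` (covariance between `P` dosage and
#'   `omega_f`, `NA` when genotype is monomorphic).
#' @export
epistasis_diagnostics <- function(snapshot) {
  stopifnot(all(c("omega_f", "genotype", "mated", "W") %in% names(snapshot)))
  cells <- stats::aggregate(W ~ omega_f + genotype + mated, data = snapshot,
                            FUN = mean, drop = TRUE)
  counts <- stats::aggregate(W ~ omega_f + genotype + mated, data = snapshot,
                             FUN = length, drop = TRUE)
  names(cells)[names(cells) == "W"] <- "mean_W"
  cells$n <- counts$W
  dosage <- c(pp = 0, pP = 1, PP = 2)[as.character(snapshot$genotype)]
  ld <- if (length(unique(dosage)) > 1 && nrow(snapshot) > 1) {
    stats::cov(dosage, snapshot$omega_f)
  } else NA_real_
  list(cells = cells, ld = ld)
}
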