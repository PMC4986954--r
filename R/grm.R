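#' Standardize a genotype column
#'
#' `z_j = (x_j - 2 q_j) / sqrt(2 q_j (1 - q_j))`, where `q_j` is the
#' allele-1 frequency. Centred and variance-standardized under
#' Hardy-Weinberg proportions.
#'
#' @param x genotype vector (0/1/2 allele counts).
#' @param q allele-1 frequency, strictly inside (0, 1).
#' @return standardized numeric vector.
#' @export
standardize <- function(x, q) {
  if (q <= 0 || q >= 1) stop("monomorphic locus: q must be in (0, 1)")
  (x - 2 * q) / sqrt(2 * q * (1 - q))
}

#' Realized genomic relationship matrix G = ZZ'/p
#'
#' `Z` holds standardized genotype columns with allele frequencies
#' estimated from all supplied individuals (reference and validation
#' together); `p` is the number of loci retained. Monomorphic loci are
#' dropped with a warning.
#'
#' @param X individuals x loci genotype matrix (0/1/2).
#' @param loci optional column subset to use.
#' @return An object of class `grm`: list with `G`, `q` (frequencies of
#'   the retained loci), `loci` (retained column indices of `X`).
#' @export
compute_grm <- function(X, loci = NULL) {
  X <- as.matrix(X)
  if (!is.null(loci)) X <- X[, loci, drop = FALSE] else loci <- seq_len(ncol(X))
  q <- colMeans(X) / 2
  poly <- q > 0 & q < 1
  if (!any(poly)) stop("all loci monomorphic")
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic locus/loci dropped")
    X <- X[, poly, drop = FALSE]
    q <- q[poly]
    loci <- loci[poly]
  }
  if (ncol(X) < 2) stop("need at least 2 polymorphic loci")
  Z <- sweep(sweep(X, 2, 2 * q), 2, sqrt(2 * q * (1 - q)), "/")
  structure(list(G = tcrossprod(Z) / ncol(Z), q = q, loci = loci),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$G), "individuals over", length(x$q), "loci; mean diag =",
      round(mean(diag(x$G)), 3), "\n")
  invisible(x)
}

#' Through-origin regression of marker on QTL relationships
#'
#' For a validation individual, regresses its vector of marker-derived
#' relationships to all reference individuals on its QTL-derived
#' relationships, with no intercept:
#' `b_i = (g_Q' g_M) / (g_Q' g_Q)`.
#'
#' @param g_M marker-derived relationship vector.
#' @param g_Q QTL-derived relationship vector (not all zero).
#' @return scalar `b_i`.
#' @export
b_regression <- function(g_M, g_Q) {
  stopifnot(length(g_M) == length(g_Q))
  den <- sum(g_Q^2)
  if (den == 0) stop("QTL relationship vector is all zero")
  sum(g_Q * g_M) / den
}

#' Average b over the validation population
#'
#' Applies [b_regression] row-wise to the VP x RP blocks of the marker-
#' and QTL-level relationship matrices and averages.
#'
#' @param G_M,G_Q relationship matrices over RP and VP individuals
#'   (matching layouts), or `grm` objects.
#' @param vp,rp row/column indices of validation and reference
#'   individuals.
#' @return list with `b` (per-VP-individual values) and `b_avg`.
#' @export
b_regression_vp <- function(G_M, G_Q, vp, rp) {
  if (inherits(G_M, "grm")) G_M <- G_M$G
  if (inherits(G_Q, "grm")) G_Q <- G_Q$G
  b <- vapply(seq_along(vp), function(i)
    b_regression(G_M[vp[i], rp], G_Q[vp[i], rp]), 0)
  list(b = b, b_avg = mean(b))
}

#' Relationship-regression upper bound for prediction R-squared
#'
#' The bound `[1 - (1 - b)^2] h2`, where `b` is the average regression of
#' marker-derived on QTL-derived relationships over the validation
#' population.
#'
#' @param b_avg average regression coefficient.
#' @param h2 trait heritability in `[0, 1]`.
#' @return scalar bound.
#' @export
dlc_bound <- function(b_avg, h2) {
  stopifnot(h2 >= 0, h2 <= 1)
  (1 - (1 - b_avg)^2) * h2
}
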