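#' Estimability upper bound for reliability of genomic prediction
#'
#' Decomposes a validation genotype vector as `x_V = x_V1 + x_V2`, where
#' `x_V1` is the orthogonal projection of `x_V` onto the row space of the
#' reference genotype matrix `X_R` and `x_V2` is orthogonal to it. The
#' upper bound for the reliability of prediction of that individual is
#'
#' `UP_i = (x_V1' x_V1) / (x_V' x_V)`,
#'
#' the fraction of the genotype vector's squared norm that is estimable
#' from the reference genotypes. `UP_i = 0` means reliability stays zero
#' no matter how large the reference grows; `UP_i = 1` means reliability
#' can approach 1.
#'
#' The projection is computed from a rank-revealing orthogonal
#' decomposition (column-pivoted QR of `X_R'`); the numerical rank uses a
#' relative tolerance `rank_tol` on the decomposition's diagonal, by
#' default `max(dim(X_R)) * .Machine$double.eps`.
#'
#' @param x_V validation genotype vector (length = number of loci), or a
#'   matrix with one validation individual per row. Must use the same
#'   coding/centring as the rows of `X_R`.
#' @param X_R reference individuals x loci genotype matrix (nonzero).
#' @param rank_tol relative rank tolerance.
#' @return numeric vector of `UP_i` in `[0, 1]`, one per validation
#'   individual.
#' @export
#' @examples
#' X_R <- rbind(c(1, 0, 0), c(0, 1, 0))
#' up_bound(c(1, 1, 1), X_R)  # 2/3
up_bound <- function(x_V, X_R, rank_tol = NULL) {
  X_R <- as.matrix(X_R)
  if (is.null(dim(x_V))) x_V <- matrix(x_V, nrow = 1)
  x_V <- as.matrix(x_V)
  stopifnot(ncol(x_V) == ncol(X_R))
  if (all(X_R == 0)) stop("X_R is zero")
  nrm2 <- rowSums(x_V^2)
  if (any(nrm2 == 0)) stop("validation genotype vector is all zero")
  qrd <- qr(t(X_R), LAPACK = TRUE)
  d <- abs(diag(qr.R(qrd)))
  if (is.null(rank_tol)) rank_tol <- max(dim(X_R)) * .Machine$double.eps
  r <- sum(d > rank_tol * d[1])
  if (r == 0) stop("X_R has numerical rank 0")
  # coordinates of each x_V in the orthonormal row-space basis
  qt <- qr.qty(qrd, t(x_V))[seq_len(r), , drop = FALSE]
  up <- colSums(qt^2) / nrm2
  pmin(pmax(up, 0), 1)
}

#' Upper bound for prediction R-squared of an individual
#'
#' `h2 * UP_i`: reliability is bounded by `UP_i` and prediction R-squared
#' (phenotype vs prediction) by heritability times that bound.
#'
#' @param h2 heritability in `[0, 1]`.
#' @param UP_i estimability bound(s) from [up_bound].
#' @return numeric vector.
#' @export
r2_upper <- function(h2, UP_i) {
  stopifnot(h2 >= 0, h2 <= 1)
  h2 * UP_i
}

#' Classify validation individuals by maximum QTL-level relationship
#'
#' For each validation individual, takes the maximum of its QTL-derived
#' genomic relationships to the reference individuals, `max(g_Vi)`, and
#' assigns the low-relationship group `L` when it is below 0.15, the
#' high-relationship group `H` when it is at or above 0.25, and
#' `"neither"` otherwise.
#'
#' @param G_cross VP x RP block of the QTL-level relationship matrix.
#' @param low,high group thresholds (defaults 0.15 and 0.25).
#' @return data.frame with `max_g` and `group` (factor `L`, `neither`,
#'   `H`) per validation individual.
#' @export
relationship_groups <- function(G_cross, low = 0.15, high = 0.25) {
  G_cross <- as.matrix(G_cross)
  if (nrow(G_cross) == 0 || ncol(G_cross) == 0)
    stop("empty relationship block")
  m <- apply(G_cross, 1, max)
  group <- factor(ifelse(m < low, "L", ifelse(m >= high, "H", "neither")),
                  levels = c("L", "neither", "H"))
  data.frame(max_g = m, group = group)
}

#' Per-individual estimability report
#'
#' Convenience wrapper computing, for every validation individual, the
#' estimability bound `UP_i`, its R-squared bound `h2 * UP_i`, the
#' maximum QTL-level relationship to the reference population and the
#' L/H group label. Genotypes are centred by twice the allele frequency
#' computed over the combined reference + validation cohort (the same
#' centring underlying `G = ZZ'/p`); set `center = FALSE` to use the raw
#' coding.
#'
#' @param X_R,X_V reference / validation genotype matrices over the
#'   marker loci used for the bound.
#' @param h2 trait heritability.
#' @param Q_R,Q_V genotype matrices over the QTL used for grouping
#'   (default: same as `X_R`, `X_V`).
#' @param center centre genotype columns before projecting (default
#'   TRUE).
#' @param rank_tol passed to [up_bound].
#' @return data.frame with columns `UP`, `r2_upper`, `max_g`, `group`.
#' @export
estimability_report <- function(X_R, X_V, h2, Q_R = X_R, Q_V = X_V,
                                center = TRUE, rank_tol = NULL) {
  X_R <- as.matrix(X_R); X_V <- as.matrix(X_V)
  force(Q_R); force(Q_V)  # capture raw genotypes before centring
  if (center) {
    cm <- colMeans(rbind(X_R, X_V))
    X_R <- sweep(X_R, 2, cm)
    X_V <- sweep(X_V, 2, cm)
  }
  up <- up_bound(X_V, X_R, rank_tol)
  gq <- compute_grm(rbind(Q_R, Q_V))
  rp <- seq_len(nrow(Q_R))
  vp <- nrow(Q_R) + seq_len(nrow(Q_V))
  grp <- relationship_groups(gq$G[vp, rp, drop = FALSE])
  data.frame(UP = up, r2_upper = r2_upper(h2, up),
             max_g = grp$max_g, group = grp$group)
}
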