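#' Effective number of chromosome segments
#'
#' `Me = 2 Ne L k / ln(Ne L)`, with `Ne` the effective population size,
#' `L` the (average) chromosome length in Morgans and `k` the number of
#' chromosomes; the log is natural. For the simulated genome
#' (`Ne = 10000`, `L = 0.1`, `k = 5`) this gives 1448; for a human-like
#' genome (`L = 1.57`, `k = 23`) about 7e4.
#'
#' @param Ne effective population size.
#' @param L chromosome length in Morgans.
#' @param k number of chromosomes.
#' @return scalar `Me`.
#' @export
#' @examples
#' round(effective_segments(10000, 0.1, 5))  # 1448
effective_segments <- function(Ne, L, k) {
  stopifnot(Ne > 0, L > 0, k > 0)
  if (Ne * L <= 1) stop("Ne * L must exceed 1")
  2 * Ne * L * k / log(Ne * L)
}

#' Approximate prediction R-squared from reference size and Me
#'
#' `R2 ~ h2_M * [n_R h2_M / (n_R h2_M + Me)]`, where `h2_M` is the
#' genomic heritability. Strictly increasing in `n_R` with asymptote
#' `h2_M`.
#'
#' @param h2_M genomic heritability in (0, 1].
#' @param n_R reference population size.
#' @param Me effective number of chromosome segments.
#' @return scalar approximate prediction R-squared.
#' @export
r2_eq1 <- function(h2_M, n_R, Me) {
  stopifnot(h2_M > 0, h2_M <= 1, n_R > 0, Me >= 0)
  h2_M * (n_R * h2_M / (n_R * h2_M + Me))
}

#' Modified Daetwyler approximation for prediction R-squared
#'
#' Reliability is approximated by `n_R h2 / (n_R h2 + min(n_QTL, Me))`
#' for a variable-selection method (BayesB), which needs to estimate only
#' the `n_QTL` effects when `n_QTL < Me`; for GBLUP the full `Me` enters
#' the denominator. The returned prediction R-squared is the reliability
#' scaled by `h2` (this scaling reproduces the study's quoted predicted
#' values for both readings).
#'
#' @param n_R reference population size.
#' @param h2 heritability.
#' @param n_QTL number of QTL.
#' @param Me effective number of chromosome segments.
#' @param method `"bayesB"` (uses `min(n_QTL, Me)`) or `"gblup"` (uses
#'   `Me`).
#' @return scalar approximate prediction R-squared.
#' @export
r2_daetwyler_mod <- function(n_R, h2, n_QTL, Me,
                             method = c("bayesB", "gblup")) {
  method <- match.arg(method)
  stopifnot(n_R > 0, h2 > 0, n_QTL > 0, Me > 0)
  denom_extra <- if (method == "bayesB") min(n_QTL, Me) else Me
  h2 * n_R * h2 / (n_R * h2 + denom_extra)
}

#' Reference size equivalent under a longer genome
#'
#' `Me` scales with total map length (holding the log term fixed), so to
#' reach the same approximate R-squared with a genome of total length
#' `genome_to` as with `genome_from`, the reference population must grow
#' by the ratio of lengths: a 30 M genome versus the simulated 0.5 M
#' needs a 60-fold larger reference (480,000 individuals in place of
#' 8,000).
#'
#' @param n_R reference size under the `genome_from` genome.
#' @param genome_from,genome_to total map lengths in Morgans.
#' @return equivalent reference size.
#' @export
#' @examples
#' equivalent_reference_size(8000, 0.5, 30)  # 480000
equivalent_reference_size <- function(n_R, genome_from, genome_to) {
  stopifnot(n_R > 0, genome_from > 0, genome_to > 0)
  n_R * genome_to / genome_from
}
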