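#' Configuration for the whole-genome regression samplers
#'
#' `pi` is the prior probability that a marker effect is exactly zero;
#' the study settings are `pi = 0.98` for BayesB/BayesC and `pi = 0`
#' (every marker in every model) for GBLUP. Chains default to 11,000
#' iterations with the first 1,000 discarded as burn-in, no thinning.
#'
#' Prior hyperparameters follow the usual genomic-prediction convention:
#' degrees of freedom `nu_beta = nu_e = 4`; the effect-variance scale is
#' set so that the prior mean of the total marker-explained variance is
#' `h2_prior * var(y)`, partitioned over the expected number of included
#' loci, i.e. `E(sigma_beta^2) = h2_prior * var(y) /
#' ((1 - pi) * sum_j 2 q_j (1 - q_j))`, and the residual scale so that
#' `E(sigma_e^2) = (1 - h2_prior) * var(y)`, with `h2_prior = 0.5`.
#'
#' @param method `"gblup"`, `"bayesC"` or `"bayesB"`. `"gblup"` is
#'   BayesC with `pi = 0`.
#' @param pi prior exclusion probability in `[0, 1)`; defaults to 0.98
#'   for bayesB/bayesC and 0 for gblup.
#' @param chain_length total MCMC iterations (default 11000).
#' @param burn_in iterations discarded (default 1000).
#' @param nu_beta,nu_e prior degrees of freedom (default 4).
#' @param h2_prior prior guess at heritability used to set the scales
#'   (default 0.5).
#' @param fix_var if `TRUE`, run with fixed variance components
#'   `sigma_beta2` / `sigma_e2` instead of sampling them (used for
#'   closed-form cross-checks).
#' @param sigma_beta2,sigma_e2 fixed variance components when
#'   `fix_var = TRUE`.
#' @return An object of class `wgr_config`.
#' @export
wgr_config <- function(method = c("gblup", "bayesC", "bayesB"), pi = NULL,
                       chain_length = 11000, burn_in = 1000,
                       nu_beta = 4, nu_e = 4, h2_prior = 0.5,
                       fix_var = FALSE, sigma_beta2 = NULL,
                       sigma_e2 = NULL) {
  method <- match.arg(method)
  if (is.null(pi)) pi <- if (method == "gblup") 0 else 0.98
  stopifnot(pi >= 0, pi < 1, burn_in < chain_length, burn_in >= 0)
  if (method == "gblup" && pi != 0)
    stop("gblup is BayesC with pi = 0")
  if (fix_var && (is.null(sigma_beta2) || is.null(sigma_e2)))
    stop("fix_var = TRUE needs sigma_beta2 and sigma_e2")
  structure(list(method = method, pi = pi,
                 chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in),
                 nu_beta = nu_beta, nu_e = nu_e, h2_prior = h2_prior,
                 fix_var = fix_var, sigma_beta2 = sigma_beta2,
                 sigma_e2 = sigma_e2),
            class = "wgr_config")
}

#' Fit a whole-genome regression by single-site Gibbs sampling
#'
#' Runs the sampler for the configured method. Marker columns are
#' mean-centred internally (the intercept absorbs the means); reported
#' effects apply unchanged to uncentred genotypes, and the reported
#' intercept is on the original genotype scale.
#'
#' @param y numeric phenotype vector (length >= 2, non-constant).
#' @param X individuals x markers genotype matrix (0/1/2 allele counts).
#' @param config a [wgr_config].
#' @return An object of class `wgr_fit`: posterior-mean intercept `mu`
#'   and effects `beta`, model frequencies `mf`, posterior mean genomic
#'   heritability `h2m`, and the variance chains (`sigma_g2_chain`,
#'   `sigma_e2_chain`, `h2m_chain`, full length; burn-in recorded in
#'   `config`).
#' @export
fit_wgr <- function(y, X, config = wgr_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), length(y) >= 2)
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("non-finite entries in y or X")
  if (var(y) == 0) stop("constant phenotype")
  cm <- colMeans(X)
  Xc <- sweep(X, 2, cm)
  vy <- var(y)
  q <- cm / 2
  sum2pq <- sum(2 * q * (1 - q))
  if (sum2pq == 0) sum2pq <- 1  # all-monomorphic panel: prior scale moot
  mean_vb <- config$h2_prior * vy / ((1 - config$pi) * sum2pq)
  S_b <- mean_vb * (config$nu_beta - 2) / config$nu_beta
  S_e <- (1 - config$h2_prior) * vy * (config$nu_e - 2) / config$nu_e
  res <- cpp_wgr_gibbs(y, Xc, config$pi, config$chain_length,
                       config$burn_in, config$nu_beta, S_b,
                       config$nu_e, S_e,
                       bayesB = (config$method == "bayesB"),
                       fix_var = config$fix_var,
                       sigma_b2_fixed = config$sigma_beta2 %||% 0,
                       sigma_e2_fixed = config$sigma_e2 %||% 0)
  keep <- seq(config$burn_in + 1L, config$chain_length)
  structure(list(mu = res$mu - sum(cm * res$beta), beta = res$beta,
                 mf = res$mf,
                 h2m = mean(res$h2m[keep]),
                 sigma_g2_chain = res$sigma_g2,
                 sigma_e2_chain = res$sigma_e2,
                 sigma_b2_chain = res$sigma_b2,
                 h2m_chain = res$h2m,
                 center = cm, config = config),
            class = "wgr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wgr_fit <- function(x, ...) {
  cat("wgr_fit [", x$config$method, ", pi = ", x$config$pi, "]: ",
      length(x$beta), " loci; posterior mean h2_M = ",
      round(x$h2m, 3), "\n", sep = "")
  invisible(x)
}

#' Posterior mean genomic heritability
#'
#' The per-iteration genetic variance is the empirical variance of
#' `X beta` over the training individuals; genomic heritability is the
#' posterior mean of `sigma_g2 / (sigma_g2 + sigma_e2)` over post-burn-in
#' samples.
#'
#' @param fit a `wgr_fit`.
#' @return scalar in `[0, 1]`.
#' @export
genomic_h2 <- function(fit) {
  stopifnot(inherits(fit, "wgr_fit"))
  keep <- seq(fit$config$burn_in + 1L, fit$config$chain_length)
  mean(fit$h2m_chain[keep])
}

#' Predict genetic values from a whole-genome regression fit
#'
#' The linear score `u_hat_i = sum_j x_ij beta_hat_j` over uncentred
#' genotypes; the intercept is omitted (squared correlations are
#' invariant to it).
#'
#' @param object a `wgr_fit`.
#' @param newdata individuals x markers genotype matrix with the same
#'   columns as the training matrix.
#' @param ... unused.
#' @return numeric vector of predicted genetic values.
#' @export
predict.wgr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta))
    stop("newdata has ", ncol(newdata), " columns; fit has ",
         length(object$beta))
  drop(newdata %*% object$beta)
}

#' Closed-form ridge regression (RR-BLUP) on markers
#'
#' Solves the ridge normal equations with an intercept:
#' `beta = (Xc'Xc + lambda I)^{-1} Xc' (y - ybar)` on mean-centred
#' markers, using the kernel form when there are more markers than
#' records. With `lambda = sigma_e2 / sigma_beta2` this is the BLUP of
#' marker effects, and its predictions equal animal-model GBLUP with
#' `G = ZZ'/p` at the matched variance ratio. Serves as the deterministic
#' oracle for the `pi = 0` sampler.
#'
#' @param y phenotype vector.
#' @param X individuals x markers genotype matrix.
#' @param lambda ridge parameter (> 0, or 0 only if `X'X` is
#'   non-singular).
#' @return list with `intercept` (`= ybar` on centred markers) and
#'   `beta`.
#' @export
rrblup_solve <- function(y, X, lambda) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), lambda >= 0)
  n <- nrow(X); p <- ncol(X)
  cm <- colMeans(X)
  Xc <- sweep(X, 2, cm)
  yc <- y - mean(y)
  if (lambda == 0 && (p >= n || qr(Xc)$rank < p))
    stop("singular system with lambda = 0")
  beta <- if (p <= n) {
    A <- crossprod(Xc)
    diag(A) <- diag(A) + lambda
    drop(solve(A, crossprod(Xc, yc)))
  } else {
    K <- tcrossprod(Xc)
    diag(K) <- diag(K) + lambda
    drop(crossprod(Xc, solve(K, yc)))
  }
  list(intercept = mean(y) - sum(cm * beta), beta = beta)
}
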