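#' Prediction accuracy measures
#'
#' Prediction R-squared is the squared Pearson correlation between
#' phenotype and prediction; reliability is the squared correlation
#' between true genetic value and prediction.
#'
#' @param y_V validation phenotypes.
#' @param u_V validation true genetic values.
#' @param u_hat predictions.
#' @return list with `R2` and `reliability`.
#' @export
accuracy <- function(y_V, u_V, u_hat) {
  stopifnot(length(y_V) == length(u_hat), length(u_V) == length(u_hat),
            length(u_hat) >= 3)
  if (sd(u_hat) == 0) stop("undefined accuracy: predictions are constant")
  list(R2 = cor(y_V, u_hat)^2, reliability = cor(u_V, u_hat)^2)
}

#' Experiment configuration
#'
#' The full study grid runs three MAF scenarios over reference sizes 75,
#' 150, 500, 1,000, 2,000, 4,000 and 8,000 with 2,000 validation
#' individuals, heritability 0.8, three methods, panels with and without
#' the QTL, and 10 replicates. Reduced profiles (smaller grid, shorter
#' chains) are set by passing the corresponding arguments.
#'
#' @param n_r_grid reference population sizes.
#' @param n_v validation population size.
#' @param h2 trait heritability.
#' @param methods subset of `c("gblup", "bayesB", "bayesC")`.
#' @param replicates number of replicates.
#' @param include_qtl logical vector of panel modes: `FALSE` = markers
#'   only, `TRUE` = markers + QTL.
#' @param chain_length,burn_in MCMC settings passed to [wgr_config].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_r_grid = c(75, 150, 500, 1000, 2000, 4000, 8000),
                              n_v = 2000, h2 = 0.8,
                              methods = c("gblup", "bayesB", "bayesC"),
                              replicates = 10,
                              include_qtl = c(FALSE, TRUE),
                              chain_length = 11000, burn_in = 1000) {
  stopifnot(replicates >= 1, all(n_r_grid >= 2), n_v >= 3)
  structure(list(n_r_grid = as.integer(n_r_grid), n_v = as.integer(n_v),
                 h2 = h2, methods = methods, replicates = as.integer(replicates),
                 include_qtl = include_qtl,
                 chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in)),
            class = "experiment_config")
}

#' Run a full prediction experiment over one scenario
#'
#' For each replicate a trait is simulated once (QTL effects re-drawn,
#' heritability rescaled on the combined reference-generation +
#' validation cohort) and a validation sample is drawn from the
#' validation-generation genotypes; for each reference size a reference
#' sample is drawn from the reference-generation genotypes; every method
#' and panel mode is then fitted to the same data (paired comparisons,
#' as when analyses share replicates). Per-cell failures are recorded
#' and the run continues.
#'
#' @param rp_geno reference-generation individuals x loci genotype
#'   matrix (the sampling pool for reference sets), or a
#'   `genotype_matrix`.
#' @param vp_geno validation-generation genotype matrix over the same
#'   loci columns.
#' @param selection a `loci_selection` whose indices refer to the
#'   columns of `rp_geno` / `vp_geno`.
#' @param config an [experiment_config].
#' @return data.frame with one row per scenario x replicate x n_R x
#'   method x panel mode: `R2`, `reliability`, `h2m`, `var_mf`, `seed`,
#'   `error`.
#' @export
run_experiment <- function(rp_geno, vp_geno, selection, config) {
  if (inherits(rp_geno, "genotype_matrix")) rp_geno <- rp_geno$geno
  if (inherits(vp_geno, "genotype_matrix")) vp_geno <- vp_geno$geno
  stopifnot(inherits(selection, "loci_selection"),
            inherits(config, "experiment_config"),
            ncol(rp_geno) == ncol(vp_geno))
  if (max(config$n_r_grid) > nrow(rp_geno))
    stop("n_R grid exceeds the reference-generation pool")
  rep_seeds <- sample.int(.Machine$integer.max, config$replicates)
  rows <- list()
  for (r in seq_len(config$replicates)) {
    set.seed(rep_seeds[r])
    vp_rows <- sample.int(nrow(vp_geno), config$n_v)
    qtl <- selection$qtl_idx
    Q_all <- rbind(rp_geno[, qtl, drop = FALSE],
                   vp_geno[vp_rows, qtl, drop = FALSE])
    trait <- simulate_trait(Q_all, config$h2)
    y_rp_pool <- trait$y[seq_len(nrow(rp_geno))]
    vp_off <- nrow(rp_geno)
    y_v <- trait$y[vp_off + seq_along(vp_rows)]
    u_v <- trait$u[vp_off + seq_along(vp_rows)]
    for (n_r in config$n_r_grid) {
      rp_rows <- sample.int(nrow(rp_geno), n_r)
      for (inc in config$include_qtl) {
        panel <- if (inc) sort(c(selection$marker_idx, qtl)) else selection$marker_idx
        X_R <- rp_geno[rp_rows, panel, drop = FALSE]
        X_V <- vp_geno[vp_rows, panel, drop = FALSE]
        for (method in config$methods) {
          rec <- data.frame(scenario = selection$scenario, replicate = r,
                            n_R = n_r, n_V = config$n_v, method = method,
                            qtl_in_panel = inc, R2 = NA_real_,
                            reliability = NA_real_, h2m = NA_real_,
                            var_mf = NA_real_, seed = rep_seeds[r],
                            error = NA_character_)
          res <- tryCatch({
            cfg <- wgr_config(method, chain_length = config$chain_length,
                              burn_in = config$burn_in)
            fit <- fit_wgr(y_rp_pool[rp_rows], X_R, cfg)
            acc <- accuracy(y_v, u_v, predict(fit, X_V))
            list(fit = fit, acc = acc)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            rec$error <- conditionMessage(res)
          } else {
            rec$R2 <- res$acc$R2
            rec$reliability <- res$acc$reliability
            rec$h2m <- res$fit$h2m
            rec$var_mf <- var(res$fit$mf)
          }
          rows[[length(rows) + 1L]] <- rec
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate experiment records into a table of means and SEs
#'
#' Means and standard errors (sample SD over replicates divided by the
#' square root of the replicate count) per scenario x method x n_R x
#' panel mode, mirroring the usual presentation of such experiments.
#'
#' @param records output of [run_experiment] (possibly row-bound over
#'   scenarios).
#' @return aggregated data.frame.
#' @export
summarize_experiment <- function(records) {
  ok <- records[is.na(records$error), ]
  key <- interaction(ok$scenario, ok$method, ok$n_R, ok$qtl_in_panel,
                     drop = TRUE)
  agg <- function(v, f) tapply(v, key, f)
  se <- function(v) sd(v) / sqrt(length(v))
  first <- !duplicated(key)
  out <- data.frame(scenario = ok$scenario[first], method = ok$method[first],
                    n_R = ok$n_R[first], qtl_in_panel = ok$qtl_in_panel[first])
  out <- out[order(out$scenario, out$method, out$n_R, out$qtl_in_panel), ]
  k <- interaction(out$scenario, out$method, out$n_R, out$qtl_in_panel,
                   drop = TRUE)
  for (v in c("R2", "reliability", "h2m", "var_mf")) {
    out[[paste0(v, "_mean")]] <- as.numeric(agg(ok[[v]], mean)[as.character(k)])
    out[[paste0(v, "_se")]] <- as.numeric(agg(ok[[v]], se)[as.character(k)])
  }
  rownames(out) <- NULL
  out
}
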