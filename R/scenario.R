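#' MAF filter
#'
#' Returns the indices (original order preserved) of sites whose minor
#' allele frequency is at least `min_maf`. The default threshold 0.005
#' matches the study-wide filter applied before marker/QTL selection.
#'
#' @param x a `genotype_matrix` or a numeric vector of MAFs.
#' @param min_maf threshold; sites with `MAF >= min_maf` are kept.
#' @return integer vector of surviving indices.
#' @export
filter_maf <- function(x, min_maf = 0.005) {
  maf <- if (inherits(x, "genotype_matrix")) x$maf else as.numeric(x)
  keep <- which(maf >= min_maf)
  if (length(keep) == 0L) stop("no sites survive the MAF filter")
  keep
}

#' Select marker and QTL loci for a MAF scenario
#'
#' Scenarios differ in how marker and QTL loci are chosen from the
#' available (already MAF-filtered) loci:
#' \describe{
#'   \item{SHL}{markers: highest MAF; QTL: lowest MAF.}
#'   \item{SHR}{markers: highest MAF; QTL: random.}
#'   \item{SRR}{markers and QTL both random.}
#' }
#' QTL are chosen first, markers from the remainder, so the two sets are
#' disjoint. "Highest"/"lowest" are order statistics of the MAF with ties
#' broken at random.
#'
#' @param mafs numeric vector of MAFs of the candidate loci.
#' @param scenario one of `"SHL"`, `"SHR"`, `"SRR"`.
#' @param n_markers number of markers (default 4200).
#' @param n_qtl number of QTL (default 70).
#' @return An object of class `loci_selection`: list with `marker_idx`,
#'   `qtl_idx` (indices into `mafs`), `maf`, `scenario`.
#' @export
select_loci <- function(mafs, scenario = c("SHL", "SHR", "SRR"),
                        n_markers = 4200, n_qtl = 70) {
  scenario <- match.arg(scenario)
  n <- length(mafs)
  if (n < n_markers + n_qtl)
    stop("need at least ", n_markers + n_qtl, " loci, have ", n)
  tie <- runif(n)
  qtl_idx <- switch(scenario,
    SHL = order(mafs, tie)[seq_len(n_qtl)],
    SHR = sample.int(n, n_qtl),
    SRR = sample.int(n, n_qtl))
  rest <- setdiff(seq_len(n), qtl_idx)
  marker_idx <- switch(scenario,
    SHL = ,
    SHR = rest[order(mafs[rest], tie[rest], decreasing = TRUE)][seq_len(n_markers)],
    SRR = sample(rest, n_markers))
  structure(list(marker_idx = sort(marker_idx), qtl_idx = sort(qtl_idx),
                 maf = mafs, scenario = scenario),
            class = "loci_selection")
}

#' @export
print.loci_selection <- function(x, ...) {
  cat("loci_selection [", x$scenario, "]: ", length(x$marker_idx),
      " markers, ", length(x$qtl_idx), " QTL\n", sep = "")
  invisible(x)
}

#' MAF-bin summary of a locus selection
#'
#' Fractions of markers and of QTL in the bins `<3%`, `3-5%`, `5-10%`,
#' `10-15%` and `>=15%` (left-closed above the first bin). Each row sums
#' to 1.
#'
#' @param selection a `loci_selection`.
#' @return matrix with rows `marker`, `qtl` and one column per bin.
#' @export
maf_table <- function(selection) {
  breaks <- c(-Inf, 0.03, 0.05, 0.10, 0.15, Inf)
  labels <- c("<3%", "3-5%", "5-10%", "10-15%", ">15%")
  frac <- function(idx) {
    b <- cut(selection$maf[idx], breaks, right = FALSE, labels = labels)
    as.numeric(table(b)) / length(idx)
  }
  out <- rbind(marker = frac(selection$marker_idx),
               qtl = frac(selection$qtl_idx))
  colnames(out) <- labels
  out
}

#' Write a locus selection as TSV
#'
#' @param selection a `loci_selection`.
#' @param map the [genome_map] the locus indices refer to (site indices in
#'   `selection` must be global map indices).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_selection_tsv <- function(selection, map, path) {
  st <- site_table(map)
  if (length(selection$maf) != nrow(st))
    stop("selection indices are not global indices of this map")
  role <- rep("", nrow(st))
  role[selection$marker_idx] <- "marker"
  role[selection$qtl_idx] <- "qtl"
  st$maf <- selection$maf
  st$role <- role
  write.table(st[role != "", ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Select marker and QTL loci matching a MAF-bin profile
#'
#' Samples marker and QTL sets whose MAF-bin composition matches given
#' fractions over the bins `<3%`, `3-5%`, `5-10%`, `10-15%`, `>=15%`
#' (largest-remainder apportionment; shortfalls in a depleted bin are
#' filled from the highest-MAF remainder). The defaults reproduce the
#' composition of the markers-common / QTL-rare (SHL) design: markers
#' mostly common with a rare tail, QTL rare-skewed but spread up to 15%.
#' Unlike the order-statistic rule in [select_loci], which at small
#' panel sizes collapses the QTL set onto the MAF filter boundary, a
#' bin profile keeps the design realistic at any scale.
#'
#' @param mafs numeric vector of MAFs of the candidate loci.
#' @param n_markers,n_qtl set sizes.
#' @param marker_fracs,qtl_fracs length-5 bin fractions (each summing
#'   to 1).
#' @param scenario_tag tag stored on the selection (default `"SHL"`).
#' @return A `loci_selection` (marker and QTL sets disjoint).
#' @export
select_loci_profile <- function(mafs, n_markers, n_qtl,
                                marker_fracs = c(0.061, 0.046, 0.117,
                                                 0.114, 0.663),
                                qtl_fracs = c(0.314, 0.243, 0.229,
                                              0.200, 0.014),
                                scenario_tag = "SHL") {
  stopifnot(length(marker_fracs) == 5, length(qtl_fracs) == 5,
            abs(sum(marker_fracs) - 1) < 0.01,  # printed tables round
            abs(sum(qtl_fracs) - 1) < 0.01)
  marker_fracs <- marker_fracs / sum(marker_fracs)
  qtl_fracs <- qtl_fracs / sum(qtl_fracs)
  n <- length(mafs)
  if (n < n_markers + n_qtl)
    stop("need at least ", n_markers + n_qtl, " loci, have ", n)
  apportion <- function(frac, m) {
    counts <- floor(frac * m)
    rem <- order(frac * m - counts, decreasing = TRUE)
    extra <- rem[seq_len(m - sum(counts))]
    counts[extra] <- counts[extra] + 1L
    counts
  }
  bin <- as.integer(cut(mafs, c(0, 0.03, 0.05, 0.10, 0.15, 0.51),
                        right = FALSE))
  draw <- function(counts, exclude) {
    picked <- integer(0)
    for (b in seq_along(counts)) {
      cand <- setdiff(which(bin == b), c(exclude, picked))
      picked <- c(picked, sample(cand, min(counts[b], length(cand))))
    }
    short <- sum(counts) - length(picked)
    if (short > 0) {
      rest <- setdiff(seq_len(length(mafs)), c(exclude, picked))
      picked <- c(picked,
                  rest[order(mafs[rest], decreasing = TRUE)][seq_len(short)])
    }
    picked
  }
  qtl <- draw(apportion(qtl_fracs, n_qtl), integer(0))
  markers <- draw(apportion(marker_fracs, n_markers), qtl)
  structure(list(marker_idx = sort(markers), qtl_idx = sort(qtl),
                 maf = mafs, scenario = scenario_tag),
            class = "loci_selection")
}
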