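#' Genome map: chromosomes, genetic lengths and site positions
#'
#' A `genome_map` holds the genetic architecture over which haplotypes are
#' simulated: an ordered set of chromosomes with genetic lengths in Morgans
#' and, per chromosome, strictly increasing site positions (Morgans,
#' `0 <= pos <= length`).
#'
#' @param lengths numeric vector of chromosome genetic lengths (Morgans),
#'   all positive.
#' @param positions list with one numeric vector per chromosome of site
#'   positions, strictly increasing and within `[0, length]`.
#' @param ids optional chromosome identifiers (default `1:k`).
#'
#' @return An object of class `genome_map` with elements `lengths`, `pos`,
#'   `ids`, `n_sites` and `offset` (0-based global index of each
#'   chromosome's first site; sites are numbered globally in map order).
#' @export
#' @examples
#' gm <- genome_map(c(0.1, 0.1), list(c(0.01, 0.05), c(0.02, 0.04, 0.09)))
#' gm$n_sites
genome_map <- function(lengths, positions, ids = seq_along(lengths)) {
  stopifnot(is.numeric(lengths), length(lengths) >= 1L,
            is.list(positions), length(positions) == length(lengths))
  if (any(lengths <= 0)) stop("all chromosome lengths must be > 0")
  for (c in seq_along(positions)) {
    p <- positions[[c]]
    if (length(p) > 0) {
      if (any(diff(p) <= 0))
        stop("site positions must be strictly increasing on chromosome ", c)
      if (min(p) < 0 || max(p) > lengths[c])
        stop("site positions outside [0, length] on chromosome ", c)
    }
    positions[[c]] <- as.numeric(p)
  }
  ns <- vapply(positions, length, 0L)
  structure(list(lengths = as.numeric(lengths), pos = positions,
                 ids = ids, n_sites = sum(ns),
                 offset = cumsum(c(0L, ns[-length(ns)]))),
            class = "genome_map")
}

#' Simulate a genome map with uniformly placed sites
#'
#' Sites are placed uniformly at random along each chromosome, with counts
#' proportional to chromosome length. The default geometry mirrors the
#' simulated genome used throughout this package: the first 0.1 Morgan of
#' each of 5 chromosomes (0.5 M in total).
#'
#' @param n_sites total number of sites across the genome.
#' @param n_chrom number of chromosomes (default 5).
#' @param chrom_length genetic length of each chromosome in Morgans
#'   (default 0.1).
#' @return A [genome_map].
#' @export
sim_genome_map <- function(n_sites, n_chrom = 5, chrom_length = 0.1) {
  stopifnot(n_sites >= n_chrom)
  base <- n_sites %/% n_chrom
  extra <- n_sites %% n_chrom
  counts <- rep(base, n_chrom) + c(rep(1L, extra), rep(0L, n_chrom - extra))
  pos <- lapply(counts, function(k) sort(runif(k, 0, chrom_length)))
  genome_map(rep(chrom_length, n_chrom), pos)
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", length(x$lengths), "chromosomes,",
      format(sum(x$lengths), digits = 3), "Morgans,",
      x$n_sites, "sites\n")
  invisible(x)
}

#' Flat site table for a genome map
#'
#' @param map a [genome_map].
#' @return data.frame with columns `site` (global 1-based index), `chrom`
#'   and `pos` (Morgans).
#' @export
site_table <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  data.frame(site = seq_len(map$n_sites),
             chrom = rep(map$ids, vapply(map$pos, length, 0L)),
             pos = unlist(map$pos, use.names = FALSE))
}
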