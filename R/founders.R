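#' Configuration for the synthetic founder generator
#'
#' The founder panel stands in for a sequenced human sample: 85 diploid
#' phased founders over 0.5 M of genome, with a rare-allele-skewed site
#' frequency spectrum and linkage disequilibrium that decays with genetic
#' distance. Founder haplotypes are Li-Stephens-style mosaics over a small
#' panel of "ancestral" haplotypes: per-site allele frequencies are drawn
#' from a neutral-like density proportional to 1/f truncated to
#' `[sfs_min_freq, 0.5]`, ancestral alleles are Bernoulli draws at those
#' frequencies, and each founder haplotype copies from one ancestral
#' haplotype at a time, switching to a uniformly chosen one at the points
#' of a Poisson process with intensity `switch_rate` per Morgan. Shared
#' copying tracts between founders generate distance-decaying LD without a
#' coalescent simulation.
#'
#' @param n_founders number of diploid founders (default 85, i.e. 170
#'   haplotypes).
#' @param n_ancestral number of ancestral source haplotypes (>= 1;
#'   default 30).
#' @param switch_rate copying-switch intensity per Morgan (>= 0;
#'   default 300, so copying tracts average ~0.33 cM and useful LD spans
#'   a few neighbouring sites at sequence-like density — the same
#'   LD-scale-to-marker-spacing ratio as a human study genotyped at
#'   dense marker spacing).
#' @param sfs_min_freq lower truncation of the 1/f frequency density
#'   (in (0, 0.5); default 0.005, matching the minimum MAF retained
#'   downstream).
#' @return An object of class `founder_config`.
#' @export
founder_config <- function(n_founders = 85, n_ancestral = 30,
                           switch_rate = 300, sfs_min_freq = 0.005) {
  stopifnot(n_founders >= 1, n_ancestral >= 1, switch_rate >= 0,
            sfs_min_freq > 0, sfs_min_freq < 0.5)
  structure(list(n_founders = as.integer(n_founders),
                 n_ancestral = as.integer(n_ancestral),
                 switch_rate = switch_rate, sfs_min_freq = sfs_min_freq),
            class = "founder_config")
}

#' Draw site frequencies from the truncated 1/f spectrum
#'
#' Density proportional to 1/f on `[fmin, 0.5]`; inverse-CDF sampling:
#' `f = fmin * (0.5/fmin)^u` for `u ~ U(0,1)`.
#'
#' @param n number of draws.
#' @param fmin lower truncation.
#' @return numeric vector of frequencies.
#' @keywords internal
rsfs <- function(n, fmin) {
  fmin * (0.5 / fmin)^runif(n)
}

#' Generate a synthetic phased founder haplotype panel
#'
#' @param config a [founder_config].
#' @param map a [genome_map] with at least one site per chromosome.
#' @return An object of class `haplotype_panel`: a list with `map`,
#'   `alleles` (integer 0/1 matrix, one row per haplotype, phased pairs of
#'   rows per founder) and `n_founders`.
#' @export
#' @examples
#' gm <- sim_genome_map(200)
#' pan <- synth_founders(founder_config(n_founders = 10), gm)
#' dim(pan$alleles)  # 20 haplotypes x 200 sites
synth_founders <- function(config, map) {
  stopifnot(inherits(config, "founder_config"), inherits(map, "genome_map"))
  ns_per_chr <- vapply(map$pos, length, 0L)
  if (any(ns_per_chr == 0L))
    stop("degenerate map: every chromosome needs at least one site")
  S <- map$n_sites
  H <- 2L * config$n_founders
  A <- config$n_ancestral
  freq <- rsfs(S, config$sfs_min_freq)
  anc <- matrix(as.integer(runif(A * S) < rep(freq, each = A)), nrow = A)
  alleles <- matrix(0L, nrow = H, ncol = S)
  for (h in seq_len(H)) {
    for (c in seq_along(map$pos)) {
      p <- map$pos[[c]]
      L <- map$lengths[c]
      cols <- map$offset[c] + seq_along(p)
      nsw <- if (config$switch_rate > 0) rpois(1, config$switch_rate * L) else 0L
      if (nsw == 0L) {
        src <- sample.int(A, 1L)
        alleles[h, cols] <- anc[src, cols]
      } else {
        bp <- c(sort(runif(nsw, 0, L)), L)
        src <- sample.int(A, nsw + 1L, replace = TRUE)
        seg <- findInterval(p, bp, left.open = FALSE) + 1L
        # sites at position exactly equal to a switch point join the
        # right-hand tract (half-open copying intervals)
        seg[seg > nsw + 1L] <- nsw + 1L
        alleles[h, cols] <- anc[cbind(src[seg], cols)]
      }
    }
  }
  structure(list(map = map, alleles = alleles,
                 n_founders = config$n_founders, site_freq = freq),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  maf <- panel_maf(x)
  cat("haplotype_panel:", x$n_founders, "diploid founders (",
      nrow(x$alleles), "haplotypes ) x", ncol(x$alleles), "sites;",
      sum(maf > 0), "segregating\n")
  invisible(x)
}

#' Minor allele frequencies of a haplotype panel
#'
#' Allele 1 is the counted allele; MAF = `min(f, 1 - f)`.
#'
#' @param panel a `haplotype_panel`.
#' @return numeric vector of per-site MAFs.
#' @export
panel_maf <- function(panel) {
  f <- colMeans(panel$alleles)
  pmin(f, 1 - f)
}

#' Read a phased diploid VCF into a haplotype panel
#'
#' Biallelic SNP records with phased GT fields (`0|1` style) are
#' transcribed in file order; multiallelic records are skipped with a
#' warning giving the count; an unphased genotype is an error naming the
#' offending position. Genetic positions are assigned from physical
#' positions at a constant rate.
#'
#' @param path path to a VCF (v4.x) file.
#' @param cM_per_Mb constant physical-to-genetic rate (default 1 cM/Mb).
#' @return A `haplotype_panel`.
#' @export
read_phased_vcf <- function(path, cM_per_Mb = 1) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- v@gt[, -1, drop = FALSE]
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic records in ", path)
  # GT is the first colon-separated field
  gtf <- matrix(sub(":.*$", "", gt), nrow = nrow(gt))
  unphased <- matrix(grepl("/", gtf, fixed = TRUE), nrow = nrow(gtf))
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1, 1]
    stop("unphased genotype at ", fix[bad, "CHROM"], ":", fix[bad, "POS"])
  }
  if (!all(grepl("^[01]\\|[01]$", gtf)))
    stop("GT fields must be phased diploid 0|1 style")
  chroms <- unique(fix[, "CHROM"])
  pos_morgan <- as.numeric(fix[, "POS"]) * 1e-6 * cM_per_Mb / 100
  positions <- lapply(chroms, function(ch) pos_morgan[fix[, "CHROM"] == ch])
  lengths <- vapply(positions, function(p) max(p) * 1.000001, 0)
  map <- genome_map(lengths, positions, ids = chroms)
  n_ind <- ncol(gtf)
  H <- matrix(0L, nrow = 2L * n_ind, ncol = nrow(fix))
  for (i in seq_len(n_ind)) {
    H[2L * i - 1L, ] <- as.integer(substr(gtf[, i], 1, 1))
    H[2L * i, ] <- as.integer(substr(gtf[, i], 3, 3))
  }
  structure(list(map = map, alleles = H, n_founders = n_ind),
            class = "haplotype_panel")
}

#' Write a haplotype panel as TSV
#'
#' Writes two files: `<stem>_haplotypes.tsv` (haplotype rows x site
#' columns) and `<stem>_sites.tsv` (chrom, genetic position, allele-1
#' frequency).
#'
#' @param panel a `haplotype_panel`.
#' @param stem output path stem.
#' @return invisibly, the two file paths.
#' @export
write_panel_tsv <- function(panel, stem) {
  hap <- paste0(stem, "_haplotypes.tsv")
  sit <- paste0(stem, "_sites.tsv")
  write.table(panel$alleles, hap, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  st <- site_table(panel$map)
  st$freq <- colMeans(panel$alleles)
  write.table(st, sit, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(hap, sit))
}
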