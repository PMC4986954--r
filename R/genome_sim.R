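#' Forward-in-time simulation configuration
#'
#' Defaults follow the study design simulated throughout this package:
#' a population of 10,000 bred by random mating for 111 non-overlapping
#' generations from the founder panel, with snapshots at generations 101
#' (reference) and 111 (validation) and a per-site, per-gamete mutation
#' rate of 1e-8 that flips the allele state.
#'
#' @param pop_size individuals per generation (default 10000).
#' @param n_generations number of generations to simulate (default 111).
#' @param snapshot_generations generations to retain (default c(101, 111)).
#' @param mutation_rate per-site per-gamete allele-flip probability
#'   (default 1e-8).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(pop_size = 10000, n_generations = 111,
                       snapshot_generations = c(101, 111),
                       mutation_rate = 1e-8) {
  stopifnot(pop_size >= 1, n_generations >= 1, mutation_rate >= 0)
  snapshot_generations <- as.integer(snapshot_generations)
  if (length(snapshot_generations) == 0L)
    stop("at least one snapshot generation is required")
  if (any(snapshot_generations < 1L | snapshot_generations > n_generations))
    stop("snapshot generations must lie in 1..n_generations")
  structure(list(pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 snapshot_generations = snapshot_generations,
                 mutation_rate = mutation_rate),
            class = "sim_config")
}

new_population <- function(individuals, map, generation) {
  structure(list(generation = as.integer(generation),
                 individuals = individuals, map = map,
                 size = length(individuals)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("population: generation", x$generation, "with", x$size,
      "individuals\n")
  invisible(x)
}

#' Subset individuals of a population
#' @param x a `population`.
#' @param i individual indices.
#' @param ... unused.
#' @export
`[.population` <- function(x, i, ...) {
  new_population(x$individuals[i], x$map, x$generation)
}

#' Represent the founder panel as a diploid population
#'
#' Founder `i` carries haplotype rows `2i-1` and `2i` of the panel as
#' single full-length segments, so all downstream segment origins index
#' into the panel.
#'
#' @param panel a `haplotype_panel`.
#' @return A `population` at generation 0.
#' @export
founder_population <- function(panel) {
  k <- length(panel$map$lengths)
  inds <- lapply(seq_len(panel$n_founders), function(i) {
    h <- function(row) lapply(seq_len(k), function(c)
      list(ends = panel$map$lengths[c], origin = row, mut = integer(0)))
    list(h(2L * i - 1L), h(2L * i))
  })
  new_population(inds, panel$map, 0L)
}

map_for_cpp <- function(map) {
  list(lengths = map$lengths, pos = map$pos)
}

#' One meiosis: sample a gamete from a diploid parent
#'
#' Per chromosome, the crossover count is Poisson in the genetic length
#' (Morgans), crossover positions are uniform and the recombinant
#' alternates the two parental homologs starting from a fair-coin choice.
#' Segments are half-open `[start, end)`. Mutations flip the inherited
#' allele state at panel sites with probability `mutation_rate` each.
#'
#' @param parent a diploid individual (element of `population$individuals`).
#' @param map a [genome_map].
#' @param mutation_rate per-site flip probability.
#' @return A haploid genome (list of per-chromosome segment records) with
#'   attribute `crossovers` giving the realized crossover count.
#' @export
make_gamete <- function(parent, map, mutation_rate = 0) {
  stopifnot(inherits(map, "genome_map"))
  cpp_make_gamete(parent, map_for_cpp(map), mutation_rate)
}

#' Advance one non-overlapping generation by random mating
#'
#' Each offspring is the union of two gametes from two parents drawn
#' uniformly with replacement (monoecious; selfing permitted).
#'
#' @param pop a `population`.
#' @param n_offspring number of offspring to produce (> 0).
#' @param mutation_rate per-site flip probability per gamete.
#' @return A `population` with the generation index incremented.
#' @export
next_generation <- function(pop, n_offspring, mutation_rate = 0) {
  stopifnot(inherits(pop, "population"))
  if (length(pop$individuals) == 0L) stop("population is empty")
  if (n_offspring <= 0) stop("n_offspring must be > 0")
  inds <- cpp_next_generation(pop$individuals, as.integer(n_offspring),
                              map_for_cpp(pop$map), mutation_rate)
  new_population(inds, pop$map, pop$generation + 1L)
}

#' Evolve a population from founder haplotypes
#'
#' Generation 1 is formed from `2 * pop_size` founder gametes (each
#' obtained by picking a founder uniformly and recombining its two phased
#' haplotypes in one meiosis); subsequent generations follow by random
#' mating. Only the requested snapshot generations are retained.
#'
#' @param founders a `haplotype_panel`.
#' @param config a [sim_config].
#' @return Named list of `population` snapshots (names `gen<g>`).
#' @export
#' @examples
#' pan <- synth_founders(founder_config(n_founders = 5), sim_genome_map(50))
#' snaps <- evolve(pan, sim_config(pop_size = 10, n_generations = 3,
#'                                 snapshot_generations = 3))
#' snaps$gen3
evolve <- function(founders, config) {
  stopifnot(inherits(founders, "haplotype_panel"),
            inherits(config, "sim_config"))
  if (founders$n_founders == 0L) stop("founder panel is empty")
  snaps <- sort(unique(config$snapshot_generations))
  raw <- cpp_evolve(founders$n_founders, map_for_cpp(founders$map),
                    config$pop_size, config$n_generations,
                    config$mutation_rate, snaps)
  out <- lapply(seq_along(snaps), function(k)
    new_population(raw[[k]], founders$map, snaps[k]))
  names(out) <- paste0("gen", snaps)
  out
}

#' Drop founder sequence to a population
#'
#' Materialises allele counts (0/1/2, counting allele 1) by looking up,
#' for each site, the founder-haplotype allele of the segment covering the
#' site's position on each homolog, flipped by any accumulated mutation at
#' that site.
#'
#' @param pop a `population`.
#' @param founders the `haplotype_panel` the segment origins index into.
#' @param sites optional sorted vector of global site indices (default all
#'   sites).
#' @return An object of class `genotype_matrix`: list with `geno`
#'   (individuals x sites integer matrix), `sites` (global indices),
#'   `maf`, and `generation`.
#' @export
drop_sequence <- function(pop, founders, sites = NULL) {
  stopifnot(inherits(pop, "population"),
            inherits(founders, "haplotype_panel"))
  if (is.null(sites)) sites <- seq_len(founders$map$n_sites)
  sites <- as.integer(sites)
  stopifnot(!is.unsorted(sites), min(sites) >= 1L,
            max(sites) <= founders$map$n_sites)
  G <- cpp_drop(pop$individuals, founders$alleles,
                map_for_cpp(founders$map), sites)
  f <- colMeans(G) / 2
  structure(list(geno = G, sites = sites, maf = pmin(f, 1 - f),
                 generation = pop$generation),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: generation", x$generation, "-", nrow(x$geno),
      "individuals x", ncol(x$geno), "sites\n")
  invisible(x)
}

#' Distinct founder-haplotype origins present in a population
#'
#' With no mutation the set of surviving origin labels can only shrink
#' across generations (lineage loss under drift).
#'
#' @param pop a `population`.
#' @return sorted integer vector of origin labels.
#' @export
origin_labels <- function(pop) {
  sort(unique(unlist(lapply(pop$individuals, function(ind)
    lapply(ind, function(h) lapply(h, function(cs) cs$origin))))))
}

#' Export a genotype matrix as an unphased VCF
#'
#' Writes biallelic records (placeholder REF/A ALT/G alleles) with
#' unphased diploid GT fields derived from the 0/1/2 allele counts.
#' Physical positions are back-converted from genetic positions at a
#' constant rate (the inverse of the convention used by
#' [read_phased_vcf]). The file is bgzip-compressed by the underlying
#' writer (`.vcf.gz`).
#'
#' @param g a `genotype_matrix`.
#' @param map the [genome_map] its site indices refer to.
#' @param path output path (a `.gz` suffix is added if absent).
#' @param cM_per_Mb constant genetic-to-physical rate (default 1).
#' @return invisibly, the path written.
#' @export
write_genotypes_vcf <- function(g, map, path, cM_per_Mb = 1) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(map, "genome_map"))
  st <- site_table(map)[g$sites, ]
  pos_bp <- as.integer(round(st$pos * 100 / cM_per_Mb * 1e6))
  n <- nrow(g$geno)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_code[t(g$geno) + 1L], nrow = length(g$sites))
  colnames(gt) <- paste0("ind", seq_len(n))
  fix <- cbind(CHROM = as.character(st$chrom), POS = as.character(pos_bp),
               ID = paste0("site", g$sites), REF = "A", ALT = "G",
               QUAL = ".", FILTER = "PASS", INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cls <- methods::getClass("vcfR", where = asNamespace("vcfR"))
  v <- methods::new(cls, meta = meta, fix = fix,
                    gt = cbind(FORMAT = "GT", gt))
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
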