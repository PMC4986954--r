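make_two_founder_panel <- function(n_sites = 20, L = 0.1) {
  gm <- genome_map(L, list(seq(0.001, L - 0.001, length.out = n_sites)))
  # founder 1 (rows 1-2) homozygous 0, founder 2 (rows 3-4) homozygous 1
  alleles <- rbind(rep(0L, n_sites), rep(0L, n_sites),
                   rep(1L, n_sites), rep(1L, n_sites))
  structure(list(map = gm, alleles = alleles, n_founders = 2L),
            class = "haplotype_panel")
}

test_that("zero-length genetic maps transmit an intact homolog", {
  pan <- make_two_founder_panel()
  gm0 <- genome_map(1e-12, list(0))
  parent <- founder_population(pan)$individuals[[1]]
  set.seed(1)
  origins <- replicate(200, {
    g <- make_gamete(parent, gm0, 0)
    g[[1]]$origin
  })
  expect_true(all(lengths(origins) == 1))
  # each parental homolog with prob ~1/2
  expect_gt(mean(unlist(origins) == 1), 0.35)
  expect_lt(mean(unlist(origins) == 1), 0.65)
})

test_that("mutation-free gametes from a homozygote match the parent", {
  pan <- make_two_founder_panel()
  # founder 1 carries haplotype rows 1 and 2, both all-zero: homozygous
  pop0 <- founder_population(pan)
  pop0$individuals <- pop0$individuals[1]
  set.seed(2)
  pop1 <- next_generation(pop0, 5, mutation_rate = 0)
  g <- drop_sequence(pop1, pan)
  expect_true(all(g$geno == 0L))
})

test_that("crossover counts are Poisson in the total map length", {
  set.seed(30)
  pan <- make_two_founder_panel(n_sites = 50)
  gm <- sim_genome_map(50)  # 5 x 0.1 M
  pan$map <- gm
  parent <- founder_population(pan)$individuals[[1]]
  set.seed(3)
  n <- 10000
  cx <- vapply(seq_len(n), function(i)
    attr(make_gamete(parent, gm, 0), "crossovers"), 0L)
  expect_equal(mean(cx), 0.5, tolerance = 3 * sqrt(0.5 / n) / 0.5)
  expect_equal(var(cx), 0.5, tolerance = 0.1)
})

test_that("one-generation drift is unbiased", {
  set.seed(4)
  gm <- sim_genome_map(40, n_chrom = 1)
  pan <- synth_founders(founder_config(n_founders = 250), gm)
  pop <- founder_population(pan)
  f_parent <- colMeans(pan$alleles)
  site <- which(f_parent > 0.2 & f_parent < 0.8)[1]
  reps <- 50
  f_off <- replicate(reps, {
    off <- next_generation(pop, 500, mutation_rate = 0)
    mean(drop_sequence(off, pan, sites = site)$geno) / 2
  })
  se <- sqrt(f_parent[site] * (1 - f_parent[site]) / (2 * 500) / reps)
  expect_lt(abs(mean(f_off) - f_parent[site]), 3 * se)
})

test_that("generation counters and snapshots are bookkept", {
  pan <- make_two_founder_panel()
  set.seed(5)
  pop <- founder_population(pan)
  for (i in 1:3) pop <- next_generation(pop, 4)
  expect_equal(pop$generation, 3L)
  snaps <- evolve(pan, sim_config(pop_size = 4, n_generations = 5,
                                  snapshot_generations = c(2, 5)))
  expect_named(snaps, c("gen2", "gen5"))
  expect_equal(snaps$gen5$generation, 5L)
  expect_equal(snaps$gen2$size, 4L)
  expect_error(sim_config(pop_size = 4, n_generations = 5,
                          snapshot_generations = integer(0)),
               "at least one snapshot")
})

test_that("segment origins always index founder haplotypes and lineages only die", {
  set.seed(6)
  gm <- sim_genome_map(30)
  pan <- synth_founders(founder_config(n_founders = 6), gm)
  snaps <- evolve(pan, sim_config(pop_size = 8, n_generations = 10,
                                  snapshot_generations = 1:10,
                                  mutation_rate = 0))
  labs <- lapply(snaps, origin_labels)
  for (l in labs) {
    expect_true(all(l >= 1 & l <= 12))
  }
  n_lab <- lengths(labs)
  expect_true(all(diff(n_lab) <= 0))
})

test_that("segments tile each chromosome with no gaps after meiosis", {
  set.seed(7)
  gm <- sim_genome_map(25, n_chrom = 5, chrom_length = 0.4)
  pan <- synth_founders(founder_config(n_founders = 4), gm)
  pop <- founder_population(pan)
  for (i in 1:5) pop <- next_generation(pop, 6, mutation_rate = 1e-3)
  for (ind in pop$individuals) {
    for (h in ind) {
      for (c in seq_along(h)) {
        ends <- h[[c]]$ends
        expect_true(all(diff(ends) > 0))
        expect_equal(ends[length(ends)], 0.4)
        expect_equal(length(ends), length(h[[c]]$origin))
      }
    }
  }
})

test_that("identity drop doubles the founder haplotype", {
  pan <- make_two_founder_panel()
  hap2 <- lapply(1, function(i) {
    h <- lapply(seq_along(pan$map$lengths), function(c)
      list(ends = pan$map$lengths[c], origin = 2L, mut = integer(0)))
    list(h, h)
  })
  pop <- structure(list(generation = 1L, individuals = hap2, map = pan$map,
                        size = 1L), class = "population")
  g <- drop_sequence(pop, pan)
  expect_equal(drop(g$geno), 2L * pan$alleles[2, ])
})

test_that("a single private mutation flips one genotype by one", {
  pan <- make_two_founder_panel()
  base <- lapply(seq_along(pan$map$lengths), function(c)
    list(ends = pan$map$lengths[c], origin = 1L, mut = integer(0)))
  with_mut <- base
  with_mut[[1]]$mut <- 7L
  pop <- structure(list(generation = 1L,
                        individuals = list(list(base, base),
                                           list(with_mut, base)),
                        map = pan$map, size = 2L), class = "population")
  g <- drop_sequence(pop, pan)
  diffs <- g$geno[2, ] - g$geno[1, ]
  expect_equal(sum(diffs != 0), 1L)
  expect_equal(diffs[7], 1L)  # founder allele 0 flips to 1
})

test_that("segment drop matches a naive per-site transmission oracle", {
  set.seed(8)
  gm <- genome_map(0.5, list(sort(runif(20, 0, 0.5))))
  pan <- synth_founders(founder_config(n_founders = 4, n_ancestral = 8), gm)
  pop <- founder_population(pan)
  pos <- site_table(gm)$pos
  for (rep in 1:25) {
    parent <- pop$individuals[[sample(4, 1)]]
    gam <- make_gamete(parent, gm, mutation_rate = 0.02)
    # naive oracle: resolve each site from the recorded events
    naive <- vapply(seq_len(20), function(s) {
      cs <- gam[[1]]
      seg <- findInterval(pos[s], cs$ends, left.open = TRUE) + 1L
      seg <- min(seg, length(cs$origin))
      a <- pan$alleles[cs$origin[seg], s]
      if (s %in% cs$mut) a <- 1L - a
      a
    }, 0L)
    # package route: drop a diploid carrying this gamete twice
    ind <- list(gam, gam)
    pop1 <- structure(list(generation = 1L, individuals = list(ind),
                           map = gm, size = 1L), class = "population")
    expect_equal(drop(drop_sequence(pop1, pan)$geno), 2L * naive)
  }
})

test_that("evolution is reproducible under a fixed seed", {
  pan <- make_two_founder_panel()
  set.seed(9)
  pan2 <- synth_founders(founder_config(n_founders = 5), sim_genome_map(60))
  run <- function() {
    set.seed(10)
    snaps <- evolve(pan2, sim_config(pop_size = 20, n_generations = 8,
                                     snapshot_generations = 8,
                                     mutation_rate = 1e-4))
    drop_sequence(snaps$gen8, pan2)$geno
  }
  expect_identical(run(), run())
})

test_that("degenerate requests error cleanly", {
  pan <- make_two_founder_panel()
  pop <- founder_population(pan)
  expect_error(next_generation(pop, 0), "n_offspring")
  empty <- pop
  empty$individuals <- list()
  expect_error(next_generation(empty, 3), "empty")
})

test_that("genotype matrices round-trip through unphased VCF export", {
  set.seed(11)
  gm <- sim_genome_map(12, n_chrom = 2)
  pan <- synth_founders(founder_config(n_founders = 4), gm)
  pop <- founder_population(pan)
  g <- drop_sequence(pop, pan)
  path <- tempfile(fileext = ".vcf.gz")
  write_genotypes_vcf(g, gm, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt[, -1, drop = FALSE]
  counts <- matrix(vapply(strsplit(sub(":.*", "", gt), "/"),
                          function(x) sum(as.integer(x)), 0L),
                   nrow = nrow(gt))
  expect_equal(unname(t(counts)), unname(g$geno))
})
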