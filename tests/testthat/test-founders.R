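test_that("a single ancestral haplotype collapses the panel", {
  set.seed(1)
  gm <- sim_genome_map(100)
  pan <- synth_founders(founder_config(n_ancestral = 1), gm)
  expect_equal(nrow(pan$alleles), 170L)
  # every haplotype copies the one source end-to-end: all rows identical
  expect_true(all(apply(pan$alleles, 2, function(x) length(unique(x)) == 1)))
  expect_true(all(panel_maf(pan) == 0))
})

test_that("switch_rate = 0 makes each haplotype one ancestral copy", {
  set.seed(2)
  gm <- sim_genome_map(300, n_chrom = 1)
  cfg <- founder_config(n_founders = 20, n_ancestral = 5, switch_rate = 0)
  pan <- synth_founders(cfg, gm)
  # each founder haplotype must equal some single source haplotype; with 5
  # sources and 40 haplotypes, at most 5 distinct rows can occur
  expect_lte(nrow(unique(pan$alleles)), 5L)
})

test_that("degenerate maps are rejected", {
  gm <- genome_map(c(0.1, 0.1), list(c(0.05), numeric(0)))
  expect_error(synth_founders(founder_config(), gm), "at least one site")
})

test_that("site frequency spectrum follows the truncated 1/f density", {
  # oracle: numeric integration of the density 1/(f log(0.5/fmin))
  dens <- function(f) 1 / (f * log(0.5 / 0.005))
  frac_below_05 <- integrate(dens, 0.005, 0.05)$value
  expect_equal(frac_below_05, 0.5, tolerance = 1e-8)
  set.seed(7)
  f <- gpbound:::rsfs(4e4, 0.005)
  expect_equal(mean(f < 0.05), frac_below_05, tolerance = 0.02)
})

test_that("founder MAF spectrum is rare-skewed across bins", {
  set.seed(11)
  gm <- sim_genome_map(20000)
  pan <- synth_founders(founder_config(), gm)
  maf <- panel_maf(pan)
  maf <- maf[maf >= 0.005]
  expect_gt(length(maf), 10000)
  counts <- table(cut(maf, c(0.005, 0.1, 0.2, 0.3, 0.4, 0.5)))
  expect_true(all(diff(as.numeric(counts)) <= 0))
})

test_that("pairwise LD decays with genetic distance", {
  set.seed(13)
  gm <- sim_genome_map(1500, n_chrom = 1)
  pan <- synth_founders(founder_config(), gm)
  maf <- panel_maf(pan)
  use <- which(maf >= 0.1)
  pos <- site_table(gm)$pos[use]
  H <- pan$alleles[, use]
  set.seed(14)
  pick <- replicate(4000, sort(sample(length(use), 2)))
  d <- pos[pick[2, ]] - pos[pick[1, ]]
  r2 <- vapply(seq_len(ncol(pick)), function(k)
    suppressWarnings(cor(H[, pick[1, k]], H[, pick[2, k]])^2), 0)
  # 0.01 M bins: non-increasing bin means up to sampling noise (once the
  # curve reaches the unlinked background, adjacent bins are equal in
  # expectation and differ only by estimation error)
  bins <- cut(d, seq(0, 0.05, by = 0.01))
  mean_r2 <- tapply(r2, bins, mean, na.rm = TRUE)
  se_r2 <- tapply(r2, bins, function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
  ok <- !is.na(mean_r2)
  mean_r2 <- mean_r2[ok]; se_r2 <- se_r2[ok]
  expect_gte(length(mean_r2), 3)
  slack <- 3 * sqrt(se_r2[-length(se_r2)]^2 + se_r2[-1]^2)
  expect_true(all(diff(mean_r2) <= slack))
  # and genuine decay from the first bin to the background
  expect_gt(mean_r2[1], mean_r2[length(mean_r2)])
})

test_that("founder synthesis is reproducible under a fixed seed", {
  gm <- {
    set.seed(21)
    sim_genome_map(500)
  }
  set.seed(22)
  a <- synth_founders(founder_config(), gm)
  set.seed(22)
  b <- synth_founders(founder_config(), gm)
  expect_identical(a$alleles, b$alleles)
})

test_that("phased VCF round-trips into a haplotype panel", {
  path <- write_vcf_fixture(c(
    vcf_record("1", 100, "A", "G", c("0|1", "1|1")),
    vcf_record("1", 2000, "C", "T", c("0|0", "1|0")),
    vcf_record("1", 30000, "G", "A", c("1|0", "0|1"))))
  pan <- read_phased_vcf(path)
  expect_equal(dim(pan$alleles), c(4L, 3L))
  expect_equal(pan$alleles[, 1], c(0L, 1L, 1L, 1L))
  expect_equal(pan$alleles[, 2], c(0L, 0L, 1L, 0L))
  expect_equal(pan$n_founders, 2L)
  # constant-rate physical->genetic conversion: 1 cM/Mb
  expect_equal(site_table(pan$map)$pos, c(100, 2000, 30000) * 1e-8)
})

test_that("unphased and multiallelic VCF records are handled", {
  path <- write_vcf_fixture(c(
    vcf_record("1", 100, "A", "G", c("0|1", "1|1")),
    vcf_record("1", 200, "C", "T", c("0/1", "1|1"))))
  expect_error(read_phased_vcf(path), "1:200")
  recs <- c(vcf_record("1", 100, "A", "G", c("0|1", "1|1")),
            vcf_record("1", 150, "A", "G,T", c("0|1", "1|1")),
            vcf_record("1", 200, "C", "T", c("0|0", "1|1")),
            vcf_record("1", 300, "G", "A", c("1|1", "0|0")),
            vcf_record("1", 400, "T", "C", c("0|1", "0|0")))
  path2 <- write_vcf_fixture(recs)
  expect_warning(pan <- read_phased_vcf(path2), "1 multiallelic")
  expect_equal(ncol(pan$alleles), 4L)
})
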