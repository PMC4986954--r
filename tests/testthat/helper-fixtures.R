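# Shared fixtures. Heavy ones are built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# A small evolved cohort used across module tests: 2,000 sites, 85
# founders, 1,000 individuals, 20 generations.
small_cohort <- function() {
  fixture("small_cohort", function() {
    set.seed(4711)
    gm <- sim_genome_map(2000)
    pan <- synth_founders(founder_config(), gm)
    snaps <- evolve(pan, sim_config(pop_size = 1000, n_generations = 20,
                                    snapshot_generations = c(10, 20),
                                    mutation_rate = 1e-8))
    g10 <- drop_sequence(snaps$gen10, pan)
    g20 <- drop_sequence(snaps$gen20, pan)
    list(map = gm, panel = pan, snaps = snaps, g10 = g10, g20 = g20)
  })
}

# SHL-analogue selection: markers and QTL are sampled to match the
# published SHL MAF-bin composition (markers mostly common but with a
# rare tail: 0.061/0.046/0.117/0.114/0.663; QTL rare-skewed with a
# spread up to 15%: 0.314/0.243/0.229/0.200/0.014, over the bins <3%,
# 3-5%, 5-10%, 10-15%, >=15%). A bottom-n/top-n order statistic cannot
# represent either row at desk scale (QTL would degenerate to the
# filter boundary). Largest-remainder apportionment per bin; shortfalls
# filled from the highest-MAF remainder.
select_shl_analogue <- function(mafs, n_markers, n_qtl) {
  select_loci_profile(mafs, n_markers, n_qtl)
}

# Reduced-scale trend experiment mirroring the full study grid: 3,000
# sites, population 2,500 for 111 generations, SHL-analogue selection
# (500 markers, 10 QTL), reference sizes 75/500/2,000, 500 validation
# individuals, 3 replicates, chains 3,000 with 500 burn-in.
trend_experiment <- function() {
  fixture("trend_experiment", function() {
    set.seed(20160816)
    gm <- sim_genome_map(3000)
    pan <- synth_founders(founder_config(), gm)
    snaps <- evolve(pan, sim_config(pop_size = 2500))
    rp <- drop_sequence(snaps$gen101, pan)
    vp <- drop_sequence(snaps$gen111, pan)
    keep <- filter_maf(rp, 0.005)
    sel <- select_shl_analogue(rp$maf[keep], n_markers = 500, n_qtl = 10)
    cfg <- experiment_config(n_r_grid = c(75, 500, 2000), n_v = 500,
                             h2 = 0.8, replicates = 3,
                             chain_length = 3000, burn_in = 500)
    rec <- run_experiment(rp$geno[, keep], vp$geno[, keep], sel, cfg)
    list(records = rec, summary = summarize_experiment(rec), sel = sel)
  })
}

# Estimability cohort at the study's design point: population 10,000 for
# 111 generations, 12,000 sites, 5,000 loci drawn from the MAF >= 0.005
# panel, n_R = 5,000.
estimability_cohort <- function() {
  fixture("estimability_cohort", function() {
    set.seed(5000)
    gm <- sim_genome_map(12000)
    pan <- synth_founders(founder_config(), gm)
    snaps <- evolve(pan, sim_config(pop_size = 10000))
    g101 <- drop_sequence(snaps$gen101, pan)
    panel_sites <- filter_maf(g101, 0.005)
    loci <- sort(sample(panel_sites, 5000))
    rp_pool <- g101$geno[, loci]
    vp_pool <- drop_sequence(snaps$gen111, pan, sites = loci)$geno
    rm(snaps, g101)
    gc()
    list(rp_pool = rp_pool, vp_pool = vp_pool)
  })
}

# GBLUP as closed-form ridge at the simulated variance ratio, kernel form.
gblup_ridge_predict <- function(y_R, X_R, X_V, h2) {
  q <- colMeans(rbind(X_R, X_V)) / 2
  sum2pq <- sum(2 * q * (1 - q))
  sigma_u2 <- h2 / (1 - h2)
  lambda <- sum2pq / sigma_u2  # sigma_e2 = 1 by construction
  sol <- rrblup_solve(y_R, X_R, lambda)
  drop(X_V %*% sol$beta)
}

# Write a small phased VCF fixture; returns the path.
write_vcf_fixture <- function(records, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
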