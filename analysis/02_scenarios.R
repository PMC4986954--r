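#!/usr/bin/env Rscript
# Step 2 — marker/QTL selection scenarios.
#
# Applies the MAF >= 0.005 filter to the generation-101 genotypes from
# step 01 and builds the three selection scenarios: SHL (markers common,
# QTL rare), SHR (markers high MAF, QTL random) and SRR (both random),
# at the desk scale of 500 markers and 10 QTL. SHL is built from its
# published MAF-bin composition (select_loci_profile): a bottom-n order
# statistic would collapse all 10 QTL onto the 0.005 filter boundary at
# this panel size, which no realistic chip design does. Writes the
# MAF-bin composition of each selection and the selections themselves.

library(gpbound)
genomes <- readRDS("results/genomes.rds")
set.seed(202)

keep <- filter_maf(genomes$g101, 0.005)
message(length(keep), " candidate loci after the MAF filter")

rows <- list()
for (sc in c("SHL", "SHR", "SRR")) {
  sel <- if (sc == "SHL") {
    select_loci_profile(genomes$g101$maf[keep], n_markers = 500, n_qtl = 10)
  } else {
    select_loci(genomes$g101$maf[keep], sc, n_markers = 500, n_qtl = 10)
  }
  tab <- maf_table(sel)
  rows[[sc]] <- data.frame(scenario = sc, type = rownames(tab), tab,
                           check.names = FALSE)
  saveRDS(list(keep = keep, sel = sel),
          sprintf("results/selection_%s.rds", sc))
  message(sc, ": mean marker MAF = ",
          round(mean(sel$maf[sel$marker_idx]), 3), ", mean QTL MAF = ",
          round(mean(sel$maf[sel$qtl_idx]), 3))
}
out <- do.call(rbind, rows)
write.table(out, "results/scenario_maf_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Wrote results/scenario_maf_bins.tsv")
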