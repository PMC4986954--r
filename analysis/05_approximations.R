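#!/usr/bin/env Rscript
# Step 5 — closed-form accuracy approximations.
#
# Evaluates the effective number of chromosome segments for the
# simulated (5 x 0.1 M) and human-like (23 x 1.57 M) genomes, the
# approximate prediction R-squared curve in reference size, the modified
# Daetwyler predictions for variable selection vs GBLUP at n_R = 75, and
# the genome-length scaling of the required reference size.

library(gpbound)
dir.create("results", showWarnings = FALSE)

Me_sim <- effective_segments(10000, 0.1, 5)
Me_hum <- effective_segments(10000, 1.57, 23)
message(sprintf("Me: simulated genome %.0f, human-like genome %.0f",
                Me_sim, Me_hum))

grid <- c(75, 150, 500, 1000, 2000, 4000, 8000, 50000, 480000)
curve <- expand.grid(n_R = grid, h2_M = c(0.698, 0.724, 0.757))
curve$R2 <- mapply(function(n, h) r2_eq1(h, n, Me_sim), curve$n_R,
                   curve$h2_M)
write.table(curve, "results/eq1_curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

daet <- data.frame(
  method = c("bayesB", "gblup"),
  R2_pred = c(r2_daetwyler_mod(75, 0.8, 70, 1448, "bayesB"),
              r2_daetwyler_mod(75, 0.8, 70, 1448, "gblup")))
write.table(daet, "results/daetwyler_75.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("Modified Daetwyler at n_R = 75: BayesB %.3f vs GBLUP %.3f",
                daet$R2_pred[1], daet$R2_pred[2]))

scale <- data.frame(genome_from_M = 0.5, genome_to_M = 30,
                    fold = equivalent_reference_size(1, 0.5, 30),
                    n_R_equivalent = equivalent_reference_size(8000, 0.5, 30))
write.table(scale, "results/genome_scaling.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf(
  "A 30 M genome needs a %.0f-fold larger reference: %d -> %.0f individuals",
  scale$fold, 8000L, scale$n_R_equivalent))
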