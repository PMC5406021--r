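#!/usr/bin/env Rscript
# Step 2: microsatellite diversity and spatial structure.
#
# Reads the genotype table from step 1, imputes the remaining missing
# calls from population allele frequencies, and computes: per-population
# diversity (N, Na, Ne, Ho, He, uHe, F), pairwise Fst / G''ST / Jost's D
# matrices with permutation p-values, and a Mantel test of genetic
# (PhiPT) against great-circle geographic distance. Coordinates are the
# approximate centroids of the six sampled regions (configuration, not
# data).

suppressPackageStartupMessages(library(invabc))
set.seed(2025)

geno <- read_genotype_table("results/genotypes.csv", default_panel())
geno <- impute_missing(geno, "sampled", seed = 2025)

div <- diversity_summary(geno)
write.csv(div$means, "results/diversity_by_population.csv",
          row.names = FALSE)
cat("mean uHe by population:\n")
print(round(setNames(div$means$uHe_mean, div$means$pop), 3))

# pairwise differentiation (199 permutations here; the study convention
# of 9,999 is a parameter)
n_perm <- 199
for (stat in c("fst", "gppst", "jostd")) {
  m <- pairwise_matrix(geno, stat, n_perm = n_perm, seed = 2025)
  write.csv(m$stat, sprintf("results/pairwise_%s.csv", stat))
  write.csv(m$p, sprintf("results/pairwise_%s_p.csv", stat))
}
fst <- as.matrix(read.csv("results/pairwise_fst.csv", row.names = 1))
cat(sprintf("pairwise Fst range: %.3f-%.3f\n",
            min(fst[upper.tri(fst)]), max(fst[upper.tri(fst)])))

# Mantel: PhiPT distance against km between region centroids
coords <- data.frame(
  pop = c("SEA", "IDN", "PAP", "PNG_2015", "PNG_1995", "SOL", "TS_2015",
          "TS_2007"),
  lat = c(13.7, -6.2, -4.5, -9.4, -9.4, -9.4, -10.1, -10.1),
  lon = c(100.5, 106.8, 136.9, 147.2, 147.2, 160.0, 142.2, 142.2))
phipt <- pairwise_matrix(geno, "phipt")$stat
coords <- coords[match(rownames(phipt), coords$pop), ]
geo <- geo_dist_km(coords)
mt <- mantel_test(phipt, geo, n_perm = 999, seed = 2025)
cat(sprintf("Mantel: r = %.3f (R2 = %.3f), genetic = %.2g*km + %.3f, P = %.4f\n",
            mt$r, mt$R2, mt$slope, mt$intercept, mt$p))
write.csv(data.frame(r = mt$r, R2 = mt$R2, slope = mt$slope,
                     intercept = mt$intercept, p = mt$p),
          "results/mantel.csv", row.names = FALSE)
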