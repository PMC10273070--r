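#!/usr/bin/env Rscript
# Step 4 — genomewide prediction under the five training/test schemes.
#
# Evaluates RR-BLUP predictive ability (Pearson r between predicted and
# observed trait BLUPs in the test set) under: random training fractions
# (10/25/50/75%), leave-one-family-out, within-family delete-one for the two
# largest families, the family-size subset curve for the largest family, and
# SNPs-per-chromosome subsampling. Iteration counts are reduced from the
# reference design (500/100) to keep the driver interactive; the tidy
# per-iteration table supports any aggregation.

suppressPackageStartupMessages(library(gwsel))

seed <- 20260904L
markers <- read_marker_matrix("results/markers_qc.csv")
blups <- utils::read.csv("results/trait_blups.csv", stringsAsFactors = FALSE)
pedigree <- read_pedigree("results/pedigree.csv")
map <- as_genetic_map(utils::read.csv("results/genetic_map.csv"))

traits <- c("overcolor", "weight", "M1", "M2", "Cn", "SSC", "TA")

cat("== random training fractions ==\n")
cv_rf <- random_fraction_cv(blups, markers,
                            fractions = c(0.10, 0.25, 0.50, 0.75),
                            n_iter = 25, seed = seed, pedigree = pedigree,
                            traits = traits)
print(summarize_cv(cv_rf), digits = 2, row.names = FALSE)

cat("\n== leave-one-family-out ==\n")
cv_lofo <- leave_one_family_out_cv(blups, markers, pedigree, traits = traits)
print(summarize_cv(cv_lofo, by = c("scheme", "trait")), digits = 2,
      row.names = FALSE)

cat("\n== within-family delete-one (two largest families) ==\n")
cv_wf <- rbind(
  within_family_loo(blups, markers, pedigree, "fam09", traits = c("M1", "SSC")),
  within_family_loo(blups, markers, pedigree, "fam11", traits = c("M1", "SSC")))
print(cv_wf[, c("trait", "test_family", "n_test", "r")], digits = 2,
      row.names = FALSE)

cat("\n== family-size subset curve (largest family) ==\n")
cv_fs <- family_subset_curve(blups, markers, pedigree, "fam09",
                             sizes = c(20, 40, 60, 80, 100, 120),
                             n_iter = 10, seed = seed + 1, traits = "M1")
print(summarize_cv(cv_fs), digits = 2, row.names = FALSE)

cat("\n== SNPs per chromosome ==\n")
cv_snp <- snps_per_chrom_cv(blups, markers, map, pedigree,
                            counts = c(5, 10, 15, 20, 25, 30), n_iter = 5,
                            seed = seed + 2, families = c("fam09", "fam11"),
                            traits = c("M1", "SSC"))
print(summarize_cv(cv_snp, by = c("scheme", "trait", "snps_per_chrom")),
      digits = 2, row.names = FALSE)

all_cv <- list(cv_rf, cv_lofo, cv_wf, cv_fs, cv_snp)
cols <- Reduce(union, lapply(all_cv, names))
padded <- lapply(all_cv, function(d) {
  for (c in setdiff(cols, names(d))) d[[c]] <- NA
  d[, cols]
})
utils::write.csv(do.call(rbind, padded), "results/cv_results.csv",
                 row.names = FALSE)
cat("\nwrote results/cv_results.csv (one row per evaluated model)\n")
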