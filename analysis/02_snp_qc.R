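#!/usr/bin/env Rscript
# Step 2 — SNP quality control.
#
# Applies the curation pipeline to the simulated array data: drop SNPs with
# > 20% missing calls, impute the remainder by population mode, drop
# monomorphic SNPs, then prune within-chromosome redundancy (|r| > 0.80,
# removing the lower-MAF member of each offending pair) by backwards
# elimination. Writes the filtered matrix and the removal report.

suppressPackageStartupMessages(library(gwsel))

markers <- read_marker_matrix("results/markers.csv")
map_df <- utils::read.csv("results/genetic_map.csv", stringsAsFactors = FALSE)
map <- as_genetic_map(map_df)

qc <- filter_snps(markers, map, max_missing = 0.20, r_threshold = 0.80)
print(qc$report)

write_marker_matrix(qc$markers, "results/markers_qc.csv")
utils::write.csv(qc$report$removed_redundant, "results/qc_redundant.csv",
                 row.names = FALSE)
utils::write.csv(
  data.frame(snp = c(qc$report$removed_missingness,
                     qc$report$removed_monomorphic),
             reason = rep(c("missingness", "monomorphic"),
                          c(length(qc$report$removed_missingness),
                            length(qc$report$removed_monomorphic)))),
  "results/qc_removed.csv", row.names = FALSE)
cat("wrote results/markers_qc.csv and QC reports\n")
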