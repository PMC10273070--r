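#!/usr/bin/env Rscript
# Step 1 — simulate the breeding germplasm and its phenotype records.
#
# Builds the default synthetic analogue of the study population: a 17-
# chromosome map with 57 SNPs per chromosome, 13 full-sib families (852
# unselected offspring) dominated by two hub parents, 103 further cultivars/
# parents/progenitors and advanced selections, and seven harvest fruit-
# quality traits recorded over five years with three fruit per tree-year and
# 10% of tree-year cells unobserved. Writes the marker matrix, pedigree and
# phenotype records under results/.

suppressPackageStartupMessages(library(gwsel))

seed <- 20260901L
dir.create("results", showWarnings = FALSE)

map <- make_genetic_map()            # 17 x 57, 71.8 cM chromosomes
germ <- build_germplasm_set(default_germplasm_config(), map, seed = seed)
arch <- make_trait_architecture(map, default_trait_specs(), seed = seed + 1)
ph <- simulate_phenotypes(germ$markers, arch, years = 2010:2014, n_reps = 3,
                          missingness = 0.10, seed = seed + 2)

print(germ)
cat(sprintf("phenotype records: %d rows over %d traits\n",
            nrow(ph$records), length(unique(ph$records$trait))))

write_marker_matrix(germ$markers, "results/markers.csv")
write_pedigree(germ$pedigree, "results/pedigree.csv")
write_phenotypes(ph$records, "results/phenotypes.csv")
map_out <- data.frame(map, chrom_length = chrom_lengths(map)[map$chrom])
utils::write.csv(map_out, "results/genetic_map.csv", row.names = FALSE)
utils::write.csv(
  data.frame(individual = rownames(ph$tbv), ph$tbv, check.names = FALSE),
  "results/true_breeding_values.csv", row.names = FALSE)

cat("wrote results/{markers,pedigree,phenotypes,genetic_map,true_breeding_values}.csv\n")
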