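#!/usr/bin/env Rscript
# Step 3 — across-year phenotype adjustment.
#
# Fits the two-way random-effects model (year + individual, with the
# year x individual interaction kept when it lowers REML AIC by more than 2)
# per trait, and writes the mean-adjusted individual BLUPs used as
# phenotypic values by all downstream prediction stages, plus the variance
# partition per trait.

suppressPackageStartupMessages(library(gwsel))

records <- read_phenotypes("results/phenotypes.csv")
bl <- blup_all_traits(records)

for (tr in names(bl$fits)) print(bl$fits[[tr]])
cat("\nvariance proportions:\n")
wide <- stats::reshape(bl$proportions, idvar = "trait",
                       timevar = "component", direction = "wide")
print(wide, digits = 2, row.names = FALSE)

write_blups(bl$blups, "results/trait_blups.csv")
utils::write.csv(bl$proportions, "results/variance_proportions.csv",
                 row.names = FALSE)
cat("wrote results/trait_blups.csv and results/variance_proportions.csv\n")
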