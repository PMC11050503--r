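#!/usr/bin/env Rscript
# Within-population diversity (H_O, uH_E, rarefied A_R, bootstrap uFIS) and
# the relationship-matrix PCA. Expects results/dataset/ from 01_simulate.R.
# The landrace population should show depressed diversity and the most
# distant PCA cluster; its uFIS is inflated by the implanted autozygosity.

library(sweepscan)

ds <- read_vcf("results/dataset/genotypes.vcf", "results/dataset/popmap.tsv")

tab <- diversity_summary(ds, n_boot = 1000, seed = 1)
cat("diversity summary (rarefaction g =", attr(tab, "rarefaction_g"), "gene copies):\n")
print(tab, digits = 4)
write.table(tab, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

p <- pca_grm(ds, n_components = 3)
cat(sprintf("\nPCA variance explained: %s\n",
            paste(sprintf("%.1f%%", 100 * p$var_explained), collapse = ", ")))
cent <- sapply(split(p$coords[, c("PC1", "PC2")], p$coords$population), colMeans)
cat("population centroids (PC1/PC2):\n")
print(round(cent, 3))
write.table(p$coords, "results/pca_coords.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
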