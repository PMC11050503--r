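#!/usr/bin/env Rscript
# Runs of homozygosity by the consecutive method (min 50 SNPs, min 0.5 Mb,
# up to 21 heterozygous and 21 missing calls per run, max 1 Mb gap), FROH
# against the SNP-covered genome, length-class summaries, within-population
# ROH islands (> 50% of samples) and their cross-population overlap.
# Expects results/dataset/ from 01_simulate.R.

library(sweepscan)

ds <- read_vcf("results/dataset/genotypes.vcf", "results/dataset/popmap.tsv")
pops <- unique(unname(ds$populations))

# data-driven check of the minimum-SNP rule at this dataset's scale
het <- mean(ds$geno == 1L, na.rm = TRUE)
l <- min_snp_from_formula(nrow(ds$markers), length(ds$samples), het)
cat(sprintf("false-positive formula suggests min %d SNPs (mean het %.3f); using 50\n",
            l, het))

params <- roh_params()
segs <- detect_runs(ds, params = params)
cat(sprintf("detected %d ROH segments\n", nrow(segs)))
write.table(segs, "results/roh_segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fr <- froh(segs, ds)
cat("\nFROH by population:\n")
print(fr$per_population, digits = 3)
write.table(fr$per_population, "results/froh.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cls <- length_class_summary(segs, ds)
cat("\nROH length classes (mean count per individual / mean length, Mb):\n")
print(cls, digits = 3)
write.table(cls, "results/roh_length_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

islands <- do.call(rbind, lapply(pops, function(pp) {
  roh_islands(segs, pp, ds, threshold = 0.5)
}))
cat(sprintf("\n%d ROH islands (>50%% of samples)\n",
            if (is.null(islands)) 0L else nrow(islands)))
if (!is.null(islands) && nrow(islands) > 0) {
  write.table(islands, "results/roh_islands.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  ov <- island_overlap(islands)
  cat(sprintf("%d cross-population island overlap(s)\n", nrow(ov$overlaps)))
  if (nrow(ov$overlaps) > 0) print(ov$overlaps)
  write.table(ov$overlaps, "results/roh_island_overlaps.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
}
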