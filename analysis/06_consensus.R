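#!/usr/bin/env Rscript
# Merges the three evidence streams (ZFst blocks, FLK regions, ROH islands)
# into consensus sweep regions -- a region must be supported by two methods
# or by two distinct breed pairs -- then annotates them with the gene and
# QTL intervals and tallies QTL trait classes. Expects the outputs of
# 03-05 plus the annotation files from 01_simulate.R.

library(sweepscan)

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

blocks <- read_tsv("results/zfst_blocks.tsv")
flk <- read_tsv("results/flk_regions.tsv")
islands <- read_tsv("results/roh_islands.tsv")

ev <- rbind(
  evidence_records("zfst", blocks$chrom, blocks$start, blocks$end,
                   blocks$pair, blocks$peak_z),
  evidence_records("flk", flk$chrom, flk$start, flk$end, "all",
                   -log10(flk$min_p)),
  evidence_records("roh_island", islands$chrom, islands$start, islands$end,
                   islands$population, islands$incidence)
)
cat(sprintf("%d evidence records (%s)\n", nrow(ev),
            paste(sprintf("%s: %d", names(table(ev$method)), table(ev$method)),
                  collapse = ", ")))

regions <- merge_evidence(ev)
discarded <- attr(regions, "discarded")
cat(sprintf("%d consensus regions; %d single-evidence components discarded\n",
            nrow(regions), if (is.null(discarded)) 0L else nrow(discarded)))

genes <- read_intervals("results/dataset/genes.tsv", "biomart_tsv")
regions <- annotate_genes(regions, genes)
qtls <- read_intervals("results/dataset/qtls.gff", "qtl_gff")
ann <- annotate_qtls(regions, qtls)
regions <- ann$regions

print(regions[, c("chrom", "start", "end", "length_mb", "methods",
                  "populations", "genes", "n_qtls")])
cat("\nQTL trait-class tally:\n")
print(ann$class_totals)

write.table(regions, "results/consensus_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ann$tally, "results/qtl_tally.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_regions(regions, "results/consensus_regions.bed", "bed")

truth <- read_intervals("results/dataset/truth_sweeps.bed", "bed")
hit <- vapply(seq_len(nrow(truth)), function(i) {
  any(regions$chrom == truth$chrom[i] & regions$start <= truth$end[i] &
        regions$end >= truth$start[i])
}, TRUE)
cat(sprintf("\n%d of %d implanted sweeps are covered by a consensus region\n",
            sum(hit), nrow(truth)))
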