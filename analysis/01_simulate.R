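#!/usr/bin/env Rscript
# Builds the study dataset used by every later step: three populations
# (20 + 20 + 17 males, mirroring two commercial broiler lines and one small
# closed landrace), one 50 Mb autosome at ~2 SNPs/kb, Balding-Nichols drift
# (F = 0.05 for the two large populations, 0.3 for the isolated one), three
# implanted 70 kb sweeps (one per population) and heavy autozygosity in the
# small population. Writes the VCF bundle plus truth files under
# results/dataset/.

library(sweepscan)

cfg <- sim_config(
  n_populations = 3,
  samples_per_population = c(20, 20, 17),
  pop_labels = c("lineA", "lineB", "landrace"),
  chromosomes = c(chr1 = 50e6, chr2 = 10e6),
  snp_density = 2e-3,
  drift_fst = c(0.05, 0.05, 0.3),
  sweep_specs = list(
    sweep_spec("chr1", 10000001, 10070000, "lineA"),
    sweep_spec("chr1", 25000001, 25070000, "lineB"),
    sweep_spec("chr1", 40000001, 40070000, "landrace")
  ),
  roh_specs = list(
    roh_spec("landrace", expected_tracts_per_individual = 14,
             class_weights = c(0.6, 0.3, 0.1)),
    roh_spec("lineA", expected_tracts_per_individual = 3),
    roh_spec("lineB", expected_tracts_per_individual = 3)
  ),
  # deep-coverage resequencing: low missingness, so the per-run missing-call
  # allowance does not artificially fragment long autozygous tracts
  missing_rate = 0.002,
  seed = 20240101
)

freqs <- simulate_frequencies(cfg)
for (sp in cfg$sweep_specs) freqs <- implant_sweep(freqs, sp)
sim <- simulate_genotypes(freqs, cfg)

print(sim$dataset)
cat(sprintf("implanted %d sweeps and %d autozygous tracts\n",
            nrow(sim$truth$sweeps), nrow(sim$truth$tracts)))

paths <- write_fixture_bundle(sim, cfg, "results/dataset")
cat("wrote:\n")
print(paths)
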