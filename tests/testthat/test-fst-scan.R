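test_that("per-marker FST handles fixed differences and identical samples", {
  # fixed difference, equal sample sizes -> 1
  geno <- rbind(a1 = 0L, a2 = 0L, a3 = 0L, b1 = 2L, b2 = 2L, b3 = 2L)
  ds <- make_dataset(geno, rep(c("a", "b"), each = 3))
  expect_equal(snp_fst(ds, "a", "b")$fst, 1)
  # identical allele counts -> estimate <= 0
  geno2 <- rbind(a1 = 0L, a2 = 1L, a3 = 2L, b1 = 0L, b2 = 1L, b3 = 2L)
  ds2 <- make_dataset(geno2, rep(c("a", "b"), each = 3))
  expect_lte(snp_fst(ds2, "a", "b")$fst, 0)
  expect_error(snp_fst(ds2, "a", "nope"), "unknown population")
})

test_that("Weir-Cockerham estimator agrees with an independent implementation", {
  ds <- random_dataset(24, 300, rep(c("a", "b"), each = 12), seed = 41,
                       missing_rate = 0.08)
  fst <- snp_fst(ds, "a", "b")
  ga <- ds$geno[1:12, , drop = FALSE]
  gb <- ds$geno[13:24, , drop = FALSE]
  oracle <- oracle_wc_fst(ga, gb)
  kept <- !is.na(oracle)
  expect_identical(nrow(fst), sum(kept))
  expect_equal(fst$fst, oracle[kept], tolerance = 1e-12)
})

test_that("window tiling follows the step*k+1 bin convention", {
  # single marker at 55,000 with 50 kb / 10 kb -> exactly 5 windows
  w <- window_scan(data.frame(chrom = "c", pos = 55000, fst = 0.5), min_snps = 1)
  expect_identical(w$bin_start, as.numeric(10000 * (1:5) + 1))
  expect_identical(w$bin_end, w$bin_start + 50000 - 1)
  expect_identical(w$n_snps, rep(1L, 5))
  # the printed convention: a window may span 54,420,001-54,470,000
  w2 <- window_scan(data.frame(chrom = "c", pos = 54450000, fst = 0.1),
                    min_snps = 1)
  expect_true(any(w2$bin_start == 54420001 & w2$bin_end == 54470000))
  # constant per-marker FST -> every window mean equals it
  d <- data.frame(chrom = "c", pos = seq(1000, 200000, by = 1000), fst = 0.37)
  w3 <- window_scan(d, min_snps = 1)
  expect_true(all(w3$mean_fst == 0.37))
  # windows below min_snps are dropped and counted
  w4 <- window_scan(d, min_snps = 51)
  expect_identical(nrow(w4), 0L)
  expect_gt(attr(w4, "n_dropped"), 0)
  # marker order within a window does not change the means
  d_shuf <- d[sample(nrow(d)), ]
  w5 <- window_scan(d_shuf, min_snps = 1)
  expect_equal(w5$mean_fst, w3$mean_fst)
})

test_that("Z-transformation is exact sample-sd standardisation", {
  w <- data.frame(chrom = "c", bin_start = c(1, 10001, 20001),
                  bin_end = c(50000, 60000, 70000), n_snps = 10L,
                  mean_fst = c(1, 2, 3))
  z <- z_transform(w)
  expect_equal(z$z_fst, c(-1, 0, 1))
  expect_error(z_transform(transform(w, mean_fst = 2)), "degenerate")
  # normalisation identity on arbitrary input
  set.seed(51)
  w$mean_fst <- runif(3)
  z <- z_transform(w)
  expect_lt(abs(mean(z$z_fst)), 1e-9)
  expect_lt(abs(sd(z$z_fst) - 1), 1e-9)
})

test_that("top blocks merge adjacent selected windows and require two members", {
  mk <- function(starts, z) {
    data.frame(chrom = "c", bin_start = starts, bin_end = starts + 49999,
               n_snps = 10L, mean_fst = z, z_fst = z)
  }
  # one isolated outlier window -> no block
  w <- mk(seq(1, by = 10000, length.out = 50), c(rep(0, 49), 10))
  w$z_fst <- (w$mean_fst - mean(w$mean_fst)) / sd(w$mean_fst)
  b <- top_blocks(w, top_fraction = 0.02, step = 10000)
  expect_identical(nrow(b), 0L)
  # two overlapping selected windows -> one merged block spanning the union
  w2 <- mk(c(54420001, 54430001, seq(1, by = 10000, length.out = 98)),
           c(10, 10, rep(0, 98)))
  b2 <- top_blocks(w2, top_fraction = 0.02, step = 10000)
  expect_identical(nrow(b2), 1L)
  expect_identical(b2$start, 54420001)
  expect_identical(b2$end, 54480000)
  expect_identical(b2$n_windows, 2L)
  # ties at the threshold are all included
  w3 <- mk(seq(1, by = 10000, length.out = 10), c(rep(1, 3), rep(0, 7)))
  w3$z_fst <- w3$mean_fst
  b3 <- top_blocks(w3, top_fraction = 0.1, step = 10000)
  expect_identical(sum(b3$n_windows), 3L)
  # every block position is covered by at least one selected window
  thr <- attr(b3, "threshold")
  sel <- w3[w3$z_fst >= thr, ]
  for (i in seq_len(nrow(b3))) {
    expect_true(any(sel$bin_start <= b3$start[i] & sel$bin_end >= b3$start[i]))
    expect_true(any(sel$bin_start <= b3$end[i] & sel$bin_end >= b3$end[i]))
  }
})

test_that("implanted sweep window outranks the neutral background", {
  cfg <- sim_config(chromosomes = c(chr1 = 20e6), snp_density = 5e-4,
                    samples_per_population = c(15, 15, 15), drift_fst = 0.05,
                    missing_rate = 0, seed = 61,
                    sweep_specs = list(sweep_spec("chr1", 10e6, 10.2e6, "pop3")))
  fr <- simulate_frequencies(cfg)
  for (sp in cfg$sweep_specs) fr <- implant_sweep(fr, sp)
  sim <- simulate_genotypes(fr, cfg)
  sc <- zfst_scan(sim$dataset, "pop1", "pop3")
  in_sweep <- sc$windows$bin_end >= 10e6 & sc$windows$bin_start <= 10.2e6
  bg_q <- quantile(sc$windows$mean_fst[!in_sweep], 0.999)
  expect_gt(max(sc$windows$mean_fst[in_sweep]), bg_q)
})

test_that("LD decay: perfect duplicates, equilibrium background and determinism", {
  set.seed(71)
  base <- matrix(rbinom(20 * 40, 2, 0.5), nrow = 20)
  # duplicate each marker right next to itself -> r2 = 1 at short distance
  geno <- base[, rep(seq_len(40), each = 2)]
  pos <- as.integer(rbind(seq(10000, by = 50000, length.out = 40),
                          seq(10500, by = 50000, length.out = 40)))
  ds <- make_dataset(cbind(geno, base), rep("a", 20),
                     chrom = rep(c("chr1", "chr2"), c(80, 40)),
                     pos = c(pos, seq_len(40) * 50000L))
  ld <- ld_decay(ds, "a", max_distance = 1000, n_pairs = 2000, seed = 1)
  expect_equal(ld$bins$mean_r2[1], 1)
  # linkage-equilibrium simulation: flat curve, recommended window = first bin
  cfg <- sim_config(n_populations = 1, samples_per_population = 40,
                    chromosomes = c(chr1 = 2e6, chr2 = 2e6), snp_density = 5e-4,
                    drift_fst = 0.05, missing_rate = 0, seed = 72)
  sim <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  ld2 <- ld_decay(sim$dataset, "pop1", max_distance = 100000, n_pairs = 5000,
                  seed = 2)
  expect_identical(ld2$recommended_window, min(ld2$bins$dist_upper))
  expect_lt(max(ld2$bins$mean_r2) - ld2$background, 0.05)
  ld3 <- ld_decay(sim$dataset, "pop1", max_distance = 100000, n_pairs = 5000,
                  seed = 2)
  expect_identical(ld2, ld3)
  # background needs a second chromosome
  one <- subset_dataset(sim$dataset,
                        marker_idx = which(sim$dataset$markers$chrom == "chr1"))
  expect_error(ld_decay(one, "pop1"), "2 chromosomes")
})
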