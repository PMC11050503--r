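test_that("observed heterozygosity matches a direct tally", {
  # trivial cases
  ds <- make_dataset(rbind(s1 = c(1L, 0L), s2 = c(1L, 2L)), c("a", "a"))
  ho <- observed_heterozygosity(ds, "a")
  expect_identical(ho$per_locus, c(1, 0))
  # random fixture vs brute-force loop
  ds <- random_dataset(15, 200, rep("a", 15), seed = 21, missing_rate = 0.1)
  ho <- observed_heterozygosity(ds, "a")
  direct <- vapply(seq_len(200), function(j) {
    g <- ds$geno[, j]; g <- g[!is.na(g)]
    sum(g == 1) / length(g)
  }, 1.0)
  expect_equal(ho$per_locus, direct[!is.nan(direct)])
  expect_equal(ho$mean, mean(direct, na.rm = TRUE))
})

test_that("unbiased expected heterozygosity applies the small-sample correction", {
  # n = 2 diploids, allele frequency 0.5 -> (2n/(2n-1)) * 0.5 = 2/3
  ds <- make_dataset(rbind(s1 = 0L, s2 = 2L), c("a", "a"))
  expect_equal(unbiased_expected_heterozygosity(ds, "a")$per_locus, 4 / 3 * 0.5)
  # monomorphic locus -> 0
  ds0 <- make_dataset(rbind(s1 = c(0L, 1L), s2 = c(0L, 1L)), c("a", "a"))
  expect_equal(unbiased_expected_heterozygosity(ds0, "a")$per_locus[1], 0)
  # large n at p = 0.5 tends to 0.5
  set.seed(4)
  big <- make_dataset(matrix(rbinom(2000, 2, 0.5), ncol = 2), rep("a", 1000))
  expect_lt(abs(unbiased_expected_heterozygosity(big, "a")$mean - 0.5), 0.02)
  # uHE >= biased HE on finite samples
  ds <- random_dataset(10, 100, rep("a", 10), seed = 31)
  n <- colSums(!is.na(ds$geno))
  p <- colSums(ds$geno) / (2 * n)
  he_biased <- 2 * p * (1 - p)
  expect_true(all(unbiased_expected_heterozygosity(ds, "a")$per_locus >=
                    he_biased - 1e-12))
})

test_that("rarefied allelic richness equals exhaustive subset enumeration", {
  # N = 4 gene copies, counts (3,1), g = 2 -> 1.5; counts (2,2) -> 5/3
  ds31 <- make_dataset(rbind(s1 = 2L, s2 = 1L), c("a", "a"))  # alt copies 3
  expect_equal(rarefied_allelic_richness(ds31, "a", g = 2)$per_population$A_R, 1.5)
  expect_equal(oracle_ar_enumeration(3, 4, 2), 1.5)
  ds22 <- make_dataset(rbind(s1 = 1L, s2 = 1L), c("a", "a"))
  expect_equal(rarefied_allelic_richness(ds22, "a", g = 2)$per_population$A_R, 5 / 3)
  expect_equal(oracle_ar_enumeration(2, 4, 2), 5 / 3)
  # monomorphic -> exactly 1
  dsm <- make_dataset(rbind(s1 = 0L, s2 = 0L, s3 = 0L), c("a", "a", "a"))
  expect_equal(rarefied_allelic_richness(dsm, "a", g = 2)$per_population$A_R, 1)
  # random counts vs enumeration across g values
  set.seed(9)
  for (rep in 1:10) {
    n_total <- sample(4:8, 1)
    n_alt <- sample.int(n_total - 1, 1)
    g <- sample(2:(n_total - 1), 1)
    geno <- integer(n_total %/% 2 + n_total %% 2)
    # build a diploid genotype vector carrying exactly n_alt alt copies
    full <- c(rep(1L, n_alt), rep(0L, n_total - n_alt))
    if (n_total %% 2 == 1) full <- c(full, 0L)  # pad to even copies
    gmat <- matrix(full[seq_len(2 * length(geno))], ncol = 2)
    ds <- make_dataset(matrix(rowSums(gmat), ncol = 1), rep("a", nrow(gmat)))
    N <- 2 * nrow(gmat)
    ar <- rarefied_allelic_richness(ds, "a", g = g)$per_population$A_R
    expect_equal(ar, oracle_ar_enumeration(n_alt, N, g), tolerance = 1e-12)
  }
  # A_R at g = N equals the observed allele count; monotone nondecreasing in g
  ds <- make_dataset(rbind(s1 = 2L, s2 = 1L, s3 = 0L), rep("a", 3))
  ar_path <- vapply(2:6, function(g) {
    rarefied_allelic_richness(ds, "a", g = g)$per_population$A_R
  }, 1.0)
  expect_equal(ar_path[length(ar_path)], 2)
  expect_true(all(diff(ar_path) >= -1e-12))
  expect_error(rarefied_allelic_richness(ds, "a", g = 1), "g must be")
})

test_that("uFIS point estimate, degenerate cases and order invariance", {
  # all-homozygous polymorphic data -> uFIS = 1
  ds <- make_dataset(rbind(s1 = c(0L, 2L), s2 = c(2L, 0L), s3 = c(0L, 2L)),
                     rep("a", 3))
  f <- ufis_with_ci(ds, "a", n_boot = 100, seed = 1)
  expect_equal(f$ufis, 1)
  # identical loci -> every bootstrap replicate equals the point estimate,
  # so the CI collapses onto it
  g <- rbind(s1 = 1L, s2 = 1L, s3 = 1L, s4 = 0L, s5 = 2L, s6 = 1L, s7 = 0L, s8 = 2L)
  dsc <- make_dataset(cbind(g, g, g), rep("a", 8))
  fc <- ufis_with_ci(dsc, "a", n_boot = 200, seed = 3)
  expected <- 1 - 0.5 / ((16 / 15) * 0.5)  # H_O 0.5, p 0.5, uHE (2n/(2n-1))/2
  expect_equal(fc$ufis, expected)
  expect_equal(fc$ci95, c(expected, expected))
  # invariance to marker order and sample order
  ds <- random_dataset(12, 150, rep("a", 12), seed = 13, missing_rate = 0.05)
  f1 <- ufis_with_ci(ds, "a", n_boot = 50, seed = 2)
  perm <- sample(seq_len(150))
  ds_m <- make_dataset(ds$geno[, perm], rep("a", 12))  # columns permuted
  f_m <- ufis_with_ci(ds_m, "a", n_boot = 50, seed = 2)
  f_s <- ufis_with_ci(subset_dataset(ds, samples = rev(ds$samples)), "a",
                      n_boot = 50, seed = 2)
  expect_equal(f1$ufis, f_m$ufis)
  expect_equal(f1$ufis, f_s$ufis)
  expect_error(
    ufis_with_ci(make_dataset(rbind(s1 = c(0L, 0L), s2 = c(0L, 0L)),
                              c("a", "a")), "a", n_boot = 10),
    "polymorphism"
  )
})

test_that("relationship-matrix PCA separates duplicated genotype groups", {
  set.seed(17)
  proto_a <- rbinom(80, 2, 0.5)
  proto_b <- rbinom(80, 2, 0.5)
  geno <- rbind(a1 = proto_a, a2 = proto_a, a3 = proto_a,
                b1 = proto_b, b2 = proto_b, b3 = proto_b)
  ds <- make_dataset(geno, rep(c("a", "b"), each = 3))
  p <- pca_grm(ds, n_components = 2)
  pc1 <- p$coords$PC1
  expect_lt(max(abs(pc1[1:3] - pc1[1])), 1e-8)
  expect_lt(max(abs(pc1[4:6] - pc1[4])), 1e-8)
  expect_gt(abs(pc1[1] - pc1[4]), 0.1)
  # eigenvalues nonincreasing and nonnegative to tolerance
  expect_true(all(diff(p$eigenvalues) <= 1e-8))
  expect_true(all(p$eigenvalues > -1e-8))
  # coordinates agree with an independent SVD route
  g <- ds$geno
  pf <- colMeans(g) / 2
  poly <- pf > 0 & pf < 1
  z <- scale(g[, poly], center = 2 * pf[poly],
             scale = sqrt(2 * pf[poly] * (1 - pf[poly])))
  sv <- svd(z)
  coords_svd <- sv$u[, 1:2] %*% diag(sv$d[1:2]) / sqrt(sum(poly))
  for (k in 1:2) {
    expect_equal(abs(p$coords[[paste0("PC", k)]]), abs(coords_svd[, k]),
                 tolerance = 1e-6)
  }
  expect_error(pca_grm(make_dataset(rbind(s1 = c(0L, 2L), s2 = c(0L, 2L)),
                                    c("a", "a"))), "monomorphic")
})

test_that("high-drift population is the outlying PCA cluster", {
  cfg <- sim_config(chromosomes = c(chr1 = 3e6), snp_density = 1e-3,
                    samples_per_population = c(10, 10, 10),
                    drift_fst = c(0.05, 0.05, 0.3), missing_rate = 0, seed = 23)
  sim <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  p <- pca_grm(sim$dataset, n_components = 2)
  cent <- sapply(split(p$coords[, c("PC1", "PC2")], p$coords$population), colMeans)
  d12 <- sqrt(sum((cent[, "pop1"] - cent[, "pop2"])^2))
  d13 <- sqrt(sum((cent[, "pop1"] - cent[, "pop3"])^2))
  d23 <- sqrt(sum((cent[, "pop2"] - cent[, "pop3"])^2))
  expect_gt(min(d13, d23), d12)
})

test_that("diversity summary assembles one row per population", {
  sh <- shared_sim()
  tab <- diversity_summary(sh$sim$dataset, n_boot = 100, seed = 1)
  expect_identical(tab$population, c("pop1", "pop2", "pop3"))
  expect_true(all(tab$H_O >= 0 & tab$H_O <= 1))
  expect_true(all(tab$uH_E >= 0 & tab$uH_E <= 1))
  expect_true(all(tab$A_R >= 1 & tab$A_R <= 2))
  expect_true(all(tab$uF_IS_lo <= tab$uF_IS & tab$uF_IS <= tab$uF_IS_hi))
  # the autozygous-tract population shows depressed H_O and elevated uFIS
  expect_lt(tab$H_O[3], min(tab$H_O[1:2]))
  expect_gt(tab$uF_IS[3], max(tab$uF_IS[1:2]))
})
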