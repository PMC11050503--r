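roh_dataset <- function(g_list, pos) {
  geno <- do.call(rbind, g_list)
  rownames(geno) <- paste0("s", seq_along(g_list))
  make_dataset(geno, rep("a", length(g_list)), pos = pos)
}

test_that("minimum-SNP formula inverts exactly and reproduces l = 50", {
  # alpha / (ns * ni) = (1 - het)^k exactly -> l = k
  het <- 0.3
  k <- 40
  ns <- 1000
  ni <- 0.05 / (ns * (1 - het)^k)
  expect_identical(min_snp_from_formula(ns, ni, het), 40L)
  # near-certain heterozygosity -> tiny run length requirement
  expect_lte(min_snp_from_formula(1e7, 57, 1 - 1e-10), 2L)
  # dense resequencing scale: ~12.5M markers, 57 birds, mean het 0.374 -> 50
  expect_identical(min_snp_from_formula(12563892, 57, 0.374, alpha = 0.05), 50L)
  expect_error(min_snp_from_formula(100, 10, 0), "mean_het")
})

test_that("consecutive detector finds textbook runs and respects thresholds", {
  pos <- as.integer(seq(10000, by = 10170, length.out = 60))  # spans ~0.6 Mb
  ds <- roh_dataset(list(rep(0L, 60)), pos)
  seg <- detect_runs(ds, params = roh_params())
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$n_snps, 60L)
  expect_identical(seg$start, pos[1])
  expect_identical(seg$end, pos[60])
  # 49 SNPs spanning the same length -> below min_snp, nothing emitted
  ds49 <- roh_dataset(list(rep(0L, 49)), as.integer(seq(10000, by = 12500,
                                                        length.out = 49)))
  expect_identical(nrow(detect_runs(ds49, params = roh_params())), 0L)
  # a > max_gap_bp gap splits the run
  pos_gap <- c(pos[1:30], pos[31:60] + 2e6L)
  ds_gap <- roh_dataset(list(rep(0L, 60)), pos_gap)
  expect_identical(nrow(detect_runs(ds_gap, params = roh_params(min_snp = 25,
                                                                min_length_bp = 2e5))), 2L)
})

test_that("detector equals the brute-force interval oracle on random instances", {
  set.seed(91)
  for (case in 1:60) {
    n <- sample(20:120, 1)
    pos <- sort(sample.int(3e6, n))
    g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                prob = c(0.45, 0.2, 0.25, 0.1))
    params <- roh_params(
      min_snp = sample(3:15, 1),
      min_length_bp = sample(c(1e4, 1e5, 5e5), 1),
      max_opp_run = sample(0:4, 1),
      max_miss_run = sample(0:4, 1),
      max_gap_bp = sample(c(5e4, 2e5, 1e6), 1)
    )
    ds <- roh_dataset(list(g), pos)
    got <- detect_runs(ds, params = params)
    want <- oracle_roh(g, pos, params)
    expect_identical(got[c("start", "end", "n_snps", "length_bp")],
                     want, label = paste("case", case))
    # every emitted segment re-satisfies all constraints independently
    for (r in seq_len(nrow(got))) {
      ix <- which(pos >= got$start[r] & pos <= got$end[r])
      expect_lte(sum(g[ix] == 1L, na.rm = TRUE), params$max_opp_run)
      expect_lte(sum(is.na(g[ix])), params$max_miss_run)
      expect_true(all(diff(pos[ix]) <= params$max_gap_bp))
    }
    # segments never overlap within a sample
    if (nrow(got) > 1) expect_true(all(diff(got$start) > 0 &
                                         got$start[-1] > got$end[-nrow(got)]))
  }
})

test_that("FROH uses the SNP-covered genome length and recovers trivial cases", {
  pos <- as.integer(seq(1, 1e6, length.out = 100))
  ds <- roh_dataset(list(rep(1L, 100), rep(0L, 100)), pos)
  # no segments -> 0
  none <- detect_runs(ds, samples = "s1", params = roh_params())
  f0 <- froh(none, ds)
  expect_true(all(f0$per_sample$froh == 0))
  # one segment covering 10% of the covered length
  seg <- data.frame(sample = "s1", chrom = "chr1", start = 1L, end = 1e5L,
                    n_snps = 10L, length_bp = 1e5L)
  f <- froh(seg, ds)
  expect_equal(f$per_sample$froh[f$per_sample$sample == "s1"], 1e5 / 1e6)
  expect_true(all(f$per_sample$froh >= 0 & f$per_sample$froh <= 1))
  # lowering min_length_bp can only increase FROH (monotonicity)
  set.seed(92)
  g <- sample(c(0L, 2L, 1L), 500, replace = TRUE, prob = c(0.48, 0.48, 0.04))
  dsr <- roh_dataset(list(g), as.integer(seq(1, 5e6, length.out = 500)))
  f_strict <- froh(detect_runs(dsr, params = roh_params(min_snp = 10,
                                                        min_length_bp = 8e5)), dsr)
  f_loose <- froh(detect_runs(dsr, params = roh_params(min_snp = 10,
                                                       min_length_bp = 2e5)), dsr)
  expect_gte(f_loose$per_sample$froh[1], f_strict$per_sample$froh[1])
})

test_that("length classes are left-open right-closed with an absent-class marker", {
  ds <- roh_dataset(list(rep(0L, 10)), as.integer(seq(1, 9e6, length.out = 10)))
  segs <- data.frame(
    sample = "s1", chrom = "chr1",
    start = c(1L, 1L, 1L), end = c(3e6L, 2e6L, 55e4L),
    n_snps = 50L, length_bp = c(3e6L, 2e6L, 55e4L)
  )
  tab <- length_class_summary(segs, ds)
  c24 <- tab[tab$class == "2-4 Mb", ]
  c052 <- tab[tab$class == "0.5-2 Mb", ]
  c48 <- tab[tab$class == "4-8 Mb", ]
  expect_equal(c24$mean_count_per_individual, 1)
  # exactly 2 Mb belongs to the 0.5-2 class (right-closed)
  expect_equal(c052$mean_count_per_individual, 2)
  # a class with no segment reports zero count and an absent mean length
  expect_equal(c48$mean_count_per_individual, 0)
  expect_true(is.na(c48$mean_length_mb))
})

test_that("ROH islands match the per-marker counting oracle", {
  pos <- as.integer(seq(1e5, 2e6, by = 1e5))
  ds <- roh_dataset(rep(list(rep(0L, length(pos))), 4), pos)
  mk_seg <- function(sample, start, end) {
    data.frame(sample = sample, chrom = "chr1", start = start, end = end,
               n_snps = 10L, length_bp = end - start + 1L)
  }
  # 3 of 4 samples share a span -> island with incidence 0.75
  segs <- rbind(mk_seg("s1", 3e5L, 9e5L), mk_seg("s2", 3e5L, 9e5L),
                mk_seg("s3", 3e5L, 9e5L))
  isl <- roh_islands(segs, "a", ds)
  expect_identical(nrow(isl), 1L)
  expect_equal(isl$incidence, 0.75)
  expect_identical(isl$start, 3e5L)
  expect_identical(isl$end, 9e5L)
  # exactly 50% coverage -> no island (strict threshold)
  segs2 <- rbind(mk_seg("s1", 3e5L, 9e5L), mk_seg("s2", 3e5L, 9e5L))
  expect_identical(nrow(roh_islands(segs2, "a", ds)), 0L)
  # random fixtures against the brute-force tally
  set.seed(93)
  for (case in 1:20) {
    segs_r <- do.call(rbind, lapply(paste0("s", 1:4), function(sid) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      st <- sort(sample(seq(1e5, 18e5, by = 1e5), k))
      mk_seg(sid, st, pmin(st + sample(c(2e5, 4e5), k, replace = TRUE), 2e6))
    }))
    if (is.null(segs_r)) next
    isl_r <- roh_islands(segs_r, "a", ds, threshold = 0.5)
    counts <- oracle_island_counts(segs_r, paste0("s", 1:4),
                                   rep("chr1", length(pos)), pos)
    above <- counts / 4 > 0.5
    # same marker set flagged: each island covers exactly a maximal TRUE run
    flagged <- rep(FALSE, length(pos))
    for (r in seq_len(nrow(isl_r))) {
      flagged[pos >= isl_r$start[r] & pos <= isl_r$end[r]] <- TRUE
    }
    expect_identical(flagged, above, label = paste("island case", case))
    if (nrow(isl_r) > 0) {
      expect_equal(isl_r$incidence,
                   vapply(seq_len(nrow(isl_r)), function(r) {
                     min(counts[pos >= isl_r$start[r] & pos <= isl_r$end[r]]) / 4
                   }, 1.0))
    }
  }
  # invariance to sample order
  isl_rev <- roh_islands(segs[3:1, ], "a", ds)
  expect_identical(isl, isl_rev)
})

test_that("cross-population island overlap reproduces printed interval arithmetic", {
  isl <- data.frame(
    population = c("CRW", "USH", "CRW", "PRW"),
    chrom = "GGA4",
    start = c(70462265L, 70701554L, 70740151L, 70740151L),
    end = c(70739807L, 70970711L, 71008491L, 70753263L),
    incidence = 0.6, n_snps = 10L
  )
  ov <- island_overlap(isl)
  # CRW 70,462,265-70,739,807 x USH 70,701,554-70,970,711 overlap as printed
  expect_true(any(ov$overlaps$start == 70701554 & ov$overlaps$end >= 70739807))
  # member island lengths in Mb at 3 decimals match the printed values
  m <- ov$members
  expect_equal(m$length_mb[m$start == 70462265], 0.278)
  expect_equal(m$length_mb[m$start == 70740151 & m$end == 70753263], 0.013)
  expect_equal(m$length_mb[m$start == 70740151 & m$end == 71008491], 0.268)
  # disjoint islands produce an empty report
  disj <- data.frame(population = c("a", "b"), chrom = "chr1",
                     start = c(1L, 1e6L), end = c(1e5L, 2e6L),
                     incidence = 0.6, n_snps = 5L)
  expect_identical(nrow(island_overlap(disj)$overlaps), 0L)
})
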