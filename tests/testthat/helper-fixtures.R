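# Hand-built datasets and independent oracle implementations used across the
# suite. Oracles are deliberately written with different algebra / brute-force
# enumeration than the package code they check.

# genotype_dataset from a plain genotype matrix (samples x markers)
make_dataset <- function(geno, pops, chrom = NULL, pos = NULL,
                         hap1 = NULL, hap2 = NULL) {
  m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(rownames(geno))) rownames(geno) <- paste0("s", seq_len(nrow(geno)))
  genotype_dataset(
    geno = geno,
    markers = data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                         stringsAsFactors = FALSE),
    populations = stats::setNames(pops, rownames(geno)),
    hap1 = hap1, hap2 = hap2
  )
}

random_dataset <- function(n, m, pops, seed, missing_rate = 0) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  geno <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (missing_rate > 0) geno[runif(n * m) < missing_rate] <- NA
  make_dataset(geno, pops)
}

# --- Weir & Cockerham (1984) two-population oracle -------------------------
# Different organisation than the package: per-marker scalar computation from
# genotype count tables, following the published component formulas verbatim.
oracle_wc_fst <- function(gA, gB) {
  one_marker <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    n <- c(length(a), length(b))
    if (any(n < 2)) return(NA_real_)
    p <- c(sum(a), sum(b)) / (2 * n)
    h <- c(mean(a == 1), mean(b == 1))
    r <- 2
    nbar <- mean(n)
    CV2 <- sum((n - nbar)^2) / (r * nbar^2) * r / (r - 1)
    nC <- nbar * (1 - CV2 * (r - 1) / r)  # equivalent closed form
    pbar <- sum(n * p) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) return(NA_real_)
    ssq <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    A <- nbar / nC * (ssq - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4))
    B <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * ssq -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- hbar / 2
    A / (A + B + C)
  }
  vapply(seq_len(ncol(gA)), function(j) one_marker(gA[, j], gB[, j]), 1.0)
}

# --- rarefied allelic richness by exhaustive subset enumeration ------------
oracle_ar_enumeration <- function(n_alt, n_total, g) {
  copies <- c(rep(1L, n_alt), rep(0L, n_total - n_alt))
  subs <- utils::combn(n_total, g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# --- ROH brute force: evaluates EVERY interval against the run predicate ---
# and replays the greedy acceptance rule (emit at current start with the
# largest admissible end, restart after an emission, else advance one SNP).
oracle_roh <- function(g, pos, params) {
  n <- length(g)
  admissible <- function(s, e) {
    gg <- g[s:e]
    if (sum(gg == 1L, na.rm = TRUE) > params$max_opp_run) return(FALSE)
    if (sum(is.na(gg)) > params$max_miss_run) return(FALSE)
    if (e > s && any(diff(pos[s:e]) > params$max_gap_bp)) return(FALSE)
    TRUE
  }
  out <- NULL
  s <- 1L
  while (s <= n) {
    if (!admissible(s, s)) { s <- s + 1L; next }
    e_max <- s
    for (e in s:n) {
      if (admissible(s, e)) e_max <- e else break
    }
    if ((e_max - s + 1L) >= params$min_snp &&
        (pos[e_max] - pos[s] + 1L) >= params$min_length_bp) {
      out <- rbind(out, data.frame(start = pos[s], end = pos[e_max],
                                   n_snps = e_max - s + 1L,
                                   length_bp = pos[e_max] - pos[s] + 1L))
      s <- e_max + 1L
    } else {
      s <- s + 1L
    }
  }
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      n_snps = integer(), length_bp = integer())
  }
  out
}

# --- per-marker island coverage tally, straight loop ------------------------
oracle_island_counts <- function(segments, samples, chrom, pos) {
  vapply(seq_along(pos), function(i) {
    sum(vapply(samples, function(sid) {
      ss <- segments[segments$sample == sid & segments$chrom == chrom[i], , drop = FALSE]
      any(ss$start <= pos[i] & ss$end >= pos[i])
    }, TRUE))
  }, 1L)
}

# --- quadratic all-pairs interval intersection ------------------------------
oracle_interval_join <- function(regions, intervals) {
  lapply(seq_len(nrow(regions)), function(i) {
    hits <- c()
    for (j in seq_len(nrow(intervals))) {
      if (intervals$chrom[j] == regions$chrom[i] &&
          max(intervals$start[j], regions$start[i]) <=
            min(intervals$end[j], regions$end[i])) {
        hits <- c(hits, j)
      }
    }
    hits[order(intervals$start[hits])]
  })
}

# per-sample fraction of the SNP-covered genome inside implanted tracts
# (union of possibly overlapping truth intervals)
truth_coverage <- function(tracts, samples, covered_length) {
  vapply(samples, function(sid) {
    tt <- tracts[tracts$sample == sid, , drop = FALSE]
    tot <- 0
    for (ch in unique(tt$chrom)) {
      t2 <- tt[tt$chrom == ch, , drop = FALSE]
      t2 <- t2[order(t2$start), , drop = FALSE]
      cur_s <- t2$start[1]; cur_e <- t2$end[1]
      for (r in seq_len(nrow(t2))[-1]) {
        if (t2$start[r] > cur_e) {
          tot <- tot + cur_e - cur_s + 1
          cur_s <- t2$start[r]; cur_e <- t2$end[r]
        } else {
          cur_e <- max(cur_e, t2$end[r])
        }
      }
      tot <- tot + cur_e - cur_s + 1
    }
    tot / covered_length
  }, 1.0)
}

# small simulated bundle shared by io/pipeline tests (built once per run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        chromosomes = c(chr1 = 4e6, chr2 = 4e6), snp_density = 3e-4,
        samples_per_population = c(8, 8, 6), drift_fst = 0.05,
        sweep_specs = list(sweep_spec("chr1", 15e5, 19e5, "pop3")),
        roh_specs = list(roh_spec("pop3", expected_tracts_per_individual = 2)),
        missing_rate = 0.01, seed = 11
      )
      fr <- simulate_frequencies(cfg)
      for (sp in cfg$sweep_specs) fr <- implant_sweep(fr, sp)
      cache <<- list(cfg = cfg, sim = simulate_genotypes(fr, cfg))
    }
    cache
  }
})
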