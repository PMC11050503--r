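#' ROH detection parameters
#'
#' Defaults follow the consecutive-runs convention for dense resequencing
#' data: minimum 50 SNPs and 0.5 Mb per run, at most 21 heterozygous and 21
#' missing calls inside a run (per-run totals), and no adjacent-SNP gap over
#' 1 Mb.
#'
#' @param min_snp minimum SNPs in a run.
#' @param min_length_bp minimum run length in bp.
#' @param max_opp_run maximum heterozygous calls tolerated inside a run.
#' @param max_miss_run maximum missing calls tolerated inside a run.
#' @param max_gap_bp maximum gap between adjacent member SNPs.
#' @param alpha significance level for [min_snp_from_formula()].
#' @export
roh_params <- function(min_snp = 50, min_length_bp = 500000,
                       max_opp_run = 21, max_miss_run = 21,
                       max_gap_bp = 1000000, alpha = 0.05) {
  stopifnot(min_snp >= 0, min_length_bp > 0, max_opp_run >= 0,
            max_miss_run >= 0, max_gap_bp > 0)
  structure(list(min_snp = min_snp, min_length_bp = min_length_bp,
                 max_opp_run = max_opp_run, max_miss_run = max_miss_run,
                 max_gap_bp = max_gap_bp, alpha = alpha),
            class = "roh_params")
}

#' Minimum SNP count from the false-positive formula
#'
#' `l = ceiling( ln(alpha / (n_markers * n_individuals)) / ln(1 - mean_het) )`
#' controls the chance that a run of `l` homozygous calls arises by chance
#' across all markers and individuals.
#'
#' @param n_markers total markers scanned.
#' @param n_individuals individuals scanned.
#' @param mean_het mean heterozygosity, strictly inside (0, 1).
#' @param alpha significance level.
#' @return Integer minimum SNP count.
#' @export
min_snp_from_formula <- function(n_markers, n_individuals, mean_het,
                                 alpha = 0.05) {
  if (mean_het <= 0 || mean_het >= 1) stop("mean_het must be inside (0, 1)")
  r <- log(alpha / (n_markers * n_individuals)) / log(1 - mean_het)
  # guard the ceiling against floating-point noise at exact integer ratios
  as.integer(ceiling(r - 1e-9))
}

#' Detect runs of homozygosity (consecutive method)
#'
#' Greedy left-to-right scan per sample and chromosome: from the current
#' start index the run is extended to the largest end index such that the
#' interval holds at most `max_opp_run` heterozygous and `max_miss_run`
#' missing calls and no adjacent-SNP gap exceeds `max_gap_bp`. If that
#' interval meets the `min_snp` and `min_length_bp` thresholds it is emitted
#' and the scan restarts after it; otherwise the start advances by one SNP.
#' Emitted segments are non-overlapping by construction.
#'
#' @param dataset a [genotype_dataset()].
#' @param samples sample ids to scan (default all).
#' @param params a [roh_params()].
#' @return data.frame of segments: `sample`, `chrom`, `start`, `end`
#'   (positions of the first/last member SNP), `n_snps`, `length_bp`.
#' @export
detect_runs <- function(dataset, samples = NULL, params = roh_params()) {
  if (is.null(samples)) samples <- dataset$samples
  chrom_index <- split(seq_len(nrow(dataset$markers)), dataset$markers$chrom)
  segs <- list()
  for (sid in samples) {
    gfull <- dataset$geno[sid, ]
    for (ch in names(chrom_index)) {
      idx <- chrom_index[[ch]]
      pos <- dataset$markers$pos[idx]
      if (any(diff(pos) <= 0)) stop("markers not sorted on ", ch)
      g <- gfull[idx]
      runs <- consecutive_runs(g, pos, params)
      if (nrow(runs) > 0) {
        runs$sample <- sid
        runs$chrom <- ch
        segs[[length(segs) + 1]] <- runs
      }
    }
  }
  if (length(segs) == 0) {
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), n_snps = integer(),
                      length_bp = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, segs)
  out <- out[, c("sample", "chrom", "start", "end", "n_snps", "length_bp")]
  rownames(out) <- NULL
  out
}

# core greedy scan for one sample/chromosome; g in {0,1,2,NA}, pos sorted
consecutive_runs <- function(g, pos, params) {
  n <- length(g)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  het_cum <- c(0L, cumsum(het))
  mis_cum <- c(0L, cumsum(mis))
  # gap_break[i] TRUE when the gap between SNP i and i+1 exceeds max_gap_bp
  gap_break_cum <- c(0L, cumsum(c(diff(pos) > params$max_gap_bp, FALSE)))
  ok_interval <- function(s, e) {
    (het_cum[e + 1] - het_cum[s]) <= params$max_opp_run &&
      (mis_cum[e + 1] - mis_cum[s]) <= params$max_miss_run &&
      (gap_break_cum[e] - gap_break_cum[s]) == 0  # gaps strictly inside [s, e]
  }
  res_s <- integer(); res_e <- integer()
  s <- 1L
  e <- 0L
  while (s <= n) {
    if (e < s) e <- s
    if (!ok_interval(s, e)) { s <- s + 1L; next }
    while (e < n && ok_interval(s, e + 1L)) e <- e + 1L
    if ((e - s + 1L) >= params$min_snp &&
        (pos[e] - pos[s] + 1L) >= params$min_length_bp) {
      res_s <- c(res_s, s); res_e <- c(res_e, e)
      s <- e + 1L
    } else {
      s <- s + 1L
    }
  }
  data.frame(
    start = pos[res_s], end = pos[res_e],
    n_snps = res_e - res_s + 1L,
    length_bp = pos[res_e] - pos[res_s] + 1L,
    stringsAsFactors = FALSE
  )
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH` per individual is the summed ROH length divided by the
#' SNP-covered autosomal genome length (sum over chromosomes of last minus
#' first marker position + 1).
#'
#' @param segments data.frame from [detect_runs()].
#' @param dataset the scanned [genotype_dataset()].
#' @return List with `per_sample` (sample, population, total length, count,
#'   froh) and `per_population` (mean, SE, min, max of each).
#' @export
froh <- function(segments, dataset) {
  denom <- sum(vapply(split(dataset$markers$pos, dataset$markers$chrom),
                      function(p) max(p) - min(p) + 1, 1.0))
  if (denom <= 0) stop("zero SNP-covered genome length")
  per_sample <- data.frame(
    sample = dataset$samples,
    population = unname(dataset$populations),
    roh_length = 0, roh_count = 0L,
    stringsAsFactors = FALSE
  )
  if (nrow(segments) > 0) {
    agg_len <- tapply(segments$length_bp, segments$sample, sum)
    agg_n <- tapply(segments$length_bp, segments$sample, length)
    i <- match(names(agg_len), per_sample$sample)
    per_sample$roh_length[i] <- as.numeric(agg_len)
    per_sample$roh_count[i] <- as.integer(agg_n)
  }
  per_sample$froh <- per_sample$roh_length / denom
  summarise <- function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
      min = min(v), max = max(v))
  }
  per_pop <- do.call(rbind, lapply(split(per_sample, per_sample$population),
    function(d) {
      data.frame(
        population = d$population[1], n = nrow(d),
        t(c(length_mb = summarise(d$roh_length / 1e6),
            count = summarise(as.numeric(d$roh_count)),
            froh = summarise(d$froh))),
        stringsAsFactors = FALSE
      )
    }))
  rownames(per_pop) <- NULL
  list(per_sample = per_sample, per_population = per_pop,
       covered_length = denom)
}

#' ROH summary by length class
#'
#' Tallies per-individual counts and mean lengths in the length classes
#' (left-open, right-closed; default 0.5-2, 2-4, 4-8 Mb), then averages
#' within population. Segments above the last bound go to an overflow class.
#'
#' @param segments data.frame from [detect_runs()].
#' @param dataset the scanned [genotype_dataset()].
#' @param class_bounds_mb class boundaries in Mb.
#' @return data.frame: population, class, mean count per individual, mean
#'   segment length in Mb (`NA` when the population has no segment in the
#'   class).
#' @export
length_class_summary <- function(segments, dataset,
                                 class_bounds_mb = c(0.5, 2, 4, 8)) {
  nb <- length(class_bounds_mb)
  labels <- c(paste0(class_bounds_mb[-nb], "-", class_bounds_mb[-1], " Mb"),
              paste0(">", class_bounds_mb[nb], " Mb"))
  pops <- unique(unname(dataset$populations))
  pop_n <- table(dataset$populations)
  if (nrow(segments) > 0) {
    len_mb <- segments$length_bp / 1e6
    cls <- findInterval(len_mb, class_bounds_mb, left.open = TRUE,
                        rightmost.closed = FALSE)
    cls[cls == 0] <- 1  # below the first bound cannot occur given min_length
    seg_pop <- unname(dataset$populations[segments$sample])
  }
  rows <- list()
  for (pop in pops) {
    for (ci in seq_along(labels)) {
      if (nrow(segments) > 0) {
        in_cell <- seg_pop == pop & cls == ci
        cnt <- sum(in_cell) / pop_n[[pop]]
        ml <- if (any(in_cell)) mean(len_mb[in_cell]) else NA_real_
      } else {
        cnt <- 0; ml <- NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        population = pop, class = labels[ci],
        mean_count_per_individual = cnt, mean_length_mb = ml,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  n_overflow <- if (nrow(segments) > 0) sum(cls > nb - 1) else 0L
  attr(out, "n_overflow") <- n_overflow
  out
}

#' Within-population ROH islands
#'
#' Per marker, counts the samples of the population whose segments cover it;
#' an island is a maximal run of consecutive markers where the coverage
#' fraction is strictly above `threshold`. Island coordinates are the
#' first/last member marker positions; incidence is the minimum coverage
#' fraction over member markers.
#'
#' @param segments data.frame from [detect_runs()].
#' @param population population label.
#' @param dataset the scanned [genotype_dataset()].
#' @param threshold coverage fraction that must be exceeded (default 0.5).
#' @return data.frame: `population`, `chrom`, `start`, `end`, `incidence`,
#'   `n_snps`.
#' @export
roh_islands <- function(segments, population, dataset, threshold = 0.5) {
  ids <- population_samples(dataset, population)
  if (length(ids) < 2) stop("population needs >= 2 samples")
  segs <- segments[segments$sample %in% ids, , drop = FALSE]
  chrom_index <- split(seq_len(nrow(dataset$markers)), dataset$markers$chrom)
  out <- list()
  for (ch in names(chrom_index)) {
    idx <- chrom_index[[ch]]
    pos <- dataset$markers$pos[idx]
    cov <- integer(length(pos))
    ss <- segs[segs$chrom == ch, , drop = FALSE]
    for (sid in unique(ss$sample)) {
      si <- ss[ss$sample == sid, , drop = FALSE]
      covered <- rep(FALSE, length(pos))
      for (r in seq_len(nrow(si))) {
        covered <- covered | (pos >= si$start[r] & pos <= si$end[r])
      }
      cov <- cov + covered
    }
    frac <- cov / length(ids)
    above <- frac > threshold
    if (!any(above)) next
    run_id <- cumsum(c(TRUE, diff(above) != 0))
    for (rr in unique(run_id[above])) {
      members <- which(run_id == rr & above)
      out[[length(out) + 1]] <- data.frame(
        population = population, chrom = ch,
        start = pos[members[1]], end = pos[members[length(members)]],
        incidence = min(frac[members]), n_snps = length(members),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(population = character(), chrom = character(),
                      start = integer(), end = integer(),
                      incidence = numeric(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-population ROH island overlap
#'
#' Reports every maximal genomic interval covered by islands of two or more
#' populations, together with the member islands and their lengths in Mb.
#'
#' @param islands data.frame of islands from [roh_islands()] (possibly
#'   several populations bound together).
#' @return List with `overlaps` (chrom, start, end, populations, length_mb)
#'   and `members` (the member islands with `length_mb`).
#' @export
island_overlap <- function(islands) {
  empty <- list(
    overlaps = data.frame(chrom = character(), start = integer(),
                          end = integer(), populations = character(),
                          length_mb = numeric(), stringsAsFactors = FALSE),
    members = data.frame()
  )
  if (nrow(islands) == 0) return(empty)
  out <- list()
  members <- list()
  for (ch in unique(islands$chrom)) {
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    bounds <- sort(unique(c(isl$start, isl$end + 1L)))
    if (length(bounds) < 2) next
    seg_start <- bounds[-length(bounds)]
    seg_end <- bounds[-1] - 1L
    npop <- vapply(seq_along(seg_start), function(i) {
      hit <- isl$start <= seg_start[i] & isl$end >= seg_end[i]
      length(unique(isl$population[hit]))
    }, 1L)
    covered <- npop >= 2
    if (!any(covered)) next
    run_id <- cumsum(c(TRUE, diff(covered) != 0))
    for (rr in unique(run_id[covered])) {
      pieces <- which(run_id == rr & covered)
      # merge only contiguous covered elementary segments
      contiguous <- split(pieces, cumsum(c(TRUE, seg_start[pieces][-1] !=
                                             seg_end[pieces][-length(pieces)] + 1L)))
      for (grp in contiguous) {
        s <- seg_start[grp[1]]; e <- seg_end[grp[length(grp)]]
        hit <- isl$start <= e & isl$end >= s
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = s, end = e,
          populations = paste(sort(unique(isl$population[hit])), collapse = ","),
          length_mb = region_length_mb(s, e),
          stringsAsFactors = FALSE
        )
        mm <- isl[hit, , drop = FALSE]
        mm$length_mb <- region_length_mb(mm$start, mm$end)
        members[[length(members) + 1]] <- mm
      }
    }
  }
  if (length(out) == 0) return(empty)
  list(overlaps = do.call(rbind, out),
       members = unique(do.call(rbind, members)))
}
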