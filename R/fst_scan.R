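#' Weir-Cockerham FST from per-population counts
#'
#' Vectorised two-population Weir & Cockerham (1984) estimator computed from
#' sample sizes, allele frequencies and observed heterozygote frequencies.
#' Negative estimates are retained (they keep window means unbiased).
#'
#' @param n1,n2 typed diploid counts per marker.
#' @param p1,p2 alternate-allele frequencies per marker.
#' @param h1,h2 observed heterozygote frequencies per marker.
#' @return Numeric vector of per-marker estimates (`NaN` where undefined).
#' @export
wc_fst_counts <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

#' Per-marker FST between two populations
#'
#' Markers with fewer than two typed diploids in either population, or
#' monomorphic across the pooled pair, are dropped.
#'
#' @param dataset a [genotype_dataset()].
#' @param pop_a,pop_b population labels.
#' @return data.frame `chrom`, `pos`, `fst`, with `attr(, "pair")`.
#' @export
snp_fst <- function(dataset, pop_a, pop_b) {
  ga <- dataset$geno[population_samples(dataset, pop_a), , drop = FALSE]
  gb <- dataset$geno[population_samples(dataset, pop_b), , drop = FALSE]
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- colSums(ga, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(gb, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(ga == 1L, na.rm = TRUE) / n1
  h2 <- colSums(gb == 1L, na.rm = TRUE) / n2
  pbar <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * n1 + 2 * n2)
  keep <- n1 >= 2 & n2 >= 2 & pbar > 0 & pbar < 1
  out <- data.frame(
    chrom = dataset$markers$chrom[keep],
    pos = dataset$markers$pos[keep],
    fst = wc_fst_counts(n1[keep], p1[keep], h1[keep], n2[keep], p2[keep], h2[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "pair") <- paste(pop_a, pop_b, sep = "/")
  out
}

#' Sliding-window mean FST
#'
#' Windows tile each chromosome at `bin_start = step * k + 1` (so a window
#' may run e.g. 54,420,001-54,470,000 for the 50 kb / 10 kb defaults); each
#' marker contributes to every window covering it. Windows holding fewer
#' than `min_snps` markers are dropped (count in `attr(, "n_dropped")`).
#'
#' @param fst data.frame from [snp_fst()] (`chrom`, `pos`, `fst`).
#' @param window_size,step window and step size in bp.
#' @param min_snps minimum markers per retained window.
#' @return data.frame `chrom`, `bin_start`, `bin_end`, `n_snps`, `mean_fst`.
#' @export
window_scan <- function(fst, window_size = 50000, step = 10000, min_snps = 10) {
  if (window_size %% step != 0) {
    warning("window_size is not a multiple of step; windows will not abut cleanly")
  }
  per_chrom <- lapply(split(fst, fst$chrom), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    # window k (0-based) spans [k*step + 1, k*step + window_size];
    # marker at pos is in windows k = max(0, ceil((pos - window_size)/step)) .. floor((pos-1)/step)
    k_hi <- (d$pos - 1) %/% step
    k_lo <- pmax(0, ceiling((d$pos - window_size) / step))
    reps <- k_hi - k_lo + 1
    k <- unlist(mapply(seq, k_lo, k_hi, SIMPLIFY = FALSE))
    vals <- rep(d$fst, reps)
    agg_n <- tapply(vals, k, length)
    agg_m <- tapply(vals, k, mean)
    kk <- as.integer(names(agg_n))
    data.frame(
      chrom = d$chrom[1],
      bin_start = kk * step + 1,
      bin_end = kk * step + window_size,
      n_snps = as.integer(agg_n),
      mean_fst = as.numeric(agg_m),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_chrom)
  keep <- out$n_snps >= min_snps
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(!keep)
  attr(res, "window_size") <- window_size
  attr(res, "step") <- step
  res
}

#' Genome-wide Z-transformation of window means
#'
#' `ZFst = (Fst - mean) / sd` with mean and sample standard deviation taken
#' over all retained windows of the scan.
#'
#' @param windows data.frame from [window_scan()].
#' @return The input with a `z_fst` column appended.
#' @export
z_transform <- function(windows) {
  if (nrow(windows) < 2) stop("need >= 2 windows to Z-transform")
  s <- stats::sd(windows$mean_fst)
  if (s == 0) stop("degenerate scan: all window means identical")
  windows$z_fst <- (windows$mean_fst - mean(windows$mean_fst)) / s
  windows
}

#' Top-fraction outlier blocks
#'
#' Selects the windows whose `z_fst` reaches the `(1 - top_fraction)`
#' nearest-rank quantile (ties at the threshold all included), merges
#' selected windows that overlap or abut (gap at most `step`) on the same
#' chromosome and keeps only merged groups of two or more windows.
#'
#' @param windows data.frame from [z_transform()].
#' @param top_fraction selected upper tail (default 0.001, i.e. top 0.1%).
#' @param step the scan's step size; taken from the windows' attribute when
#'   present.
#' @return data.frame of blocks: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_z`; `attr(, "threshold")` holds the selection threshold.
#' @export
top_blocks <- function(windows, top_fraction = 0.001, step = NULL) {
  if (is.null(step)) step <- attr(windows, "step")
  if (is.null(step)) stop("step not given and not recorded on the window table")
  n <- nrow(windows)
  if (n < 1 / top_fraction) {
    message("fewer than 1/top_fraction windows; threshold is coarse")
  }
  zs <- sort(windows$z_fst)
  # nearest-rank threshold selecting the ceiling(top_fraction * n) largest
  # values; ties at the threshold are all included
  rank <- n - ceiling(top_fraction * n) + 1
  thr <- zs[max(1, rank)]
  sel <- windows[windows$z_fst >= thr, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$bin_start), , drop = FALSE]
  blocks <- list()
  if (nrow(sel) > 0) {
    cur <- sel[1, ]
    cur_n <- 1L
    cur_peak <- cur$z_fst
    flush <- function(b, nw, pk) {
      if (nw >= 2) {
        blocks[[length(blocks) + 1]] <<- data.frame(
          chrom = b$chrom, start = b$bin_start, end = b$bin_end,
          n_windows = nw, peak_z = pk, stringsAsFactors = FALSE
        )
      }
    }
    for (i in seq_len(nrow(sel))[-1]) {
      w <- sel[i, ]
      joined <- w$chrom == cur$chrom && w$bin_start <= cur$bin_end + step + 1
      if (joined) {
        cur$bin_end <- max(cur$bin_end, w$bin_end)
        cur_n <- cur_n + 1L
        cur_peak <- max(cur_peak, w$z_fst)
      } else {
        flush(cur, cur_n, cur_peak)
        cur <- w; cur_n <- 1L; cur_peak <- w$z_fst
      }
    }
    flush(cur, cur_n, cur_peak)
  }
  out <- if (length(blocks) > 0) {
    do.call(rbind, blocks)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_windows = integer(), peak_z = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  if (!is.null(attr(windows, "pair"))) attr(out, "pair") <- attr(windows, "pair")
  out
}

#' Pairwise windowed ZFst scan
#'
#' Convenience wrapper running [snp_fst()], [window_scan()], [z_transform()]
#' and [top_blocks()] for one population pair.
#'
#' @inheritParams snp_fst
#' @inheritParams window_scan
#' @inheritParams top_blocks
#' @return List with `windows` (including `z_fst` and a `pair` column) and
#'   `blocks`.
#' @export
zfst_scan <- function(dataset, pop_a, pop_b, window_size = 50000, step = 10000,
                      min_snps = 10, top_fraction = 0.001) {
  fst <- snp_fst(dataset, pop_a, pop_b)
  w <- z_transform(window_scan(fst, window_size, step, min_snps))
  w$pair <- attr(fst, "pair")
  attr(w, "pair") <- attr(fst, "pair")
  b <- top_blocks(w, top_fraction, step = step)
  if (nrow(b) > 0) b$pair <- attr(fst, "pair")
  list(windows = w, blocks = b)
}

#' Linkage-disequilibrium decay curve
#'
#' r-squared is the squared Pearson correlation of genotype codes over
#' pairwise-complete samples of one population. Intra-chromosome pairs are
#' sampled up to `max_distance` apart and binned by distance (10 kb bins);
#' the background level is the mean r-squared of sampled inter-chromosome
#' pairs. The recommended window size is the upper edge of the first bin
#' whose mean drops to within 0.01 of the background.
#'
#' @param dataset a [genotype_dataset()].
#' @param population population label.
#' @param max_distance largest intra-chromosome pair distance in bp.
#' @param n_pairs pairs sampled for the curve and for the background.
#' @param seed integer seed.
#' @param bin_width distance bin width in bp.
#' @return List with `bins` (data.frame: distance bin upper edge, mean r2,
#'   n pairs), `background` and `recommended_window`.
#' @export
ld_decay <- function(dataset, population, max_distance = 500000,
                     n_pairs = 20000, seed = 1, bin_width = 10000) {
  chroms <- unique(dataset$markers$chrom)
  if (length(chroms) < 2) stop("need >= 2 chromosomes for the background level")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- dataset$geno[population_samples(dataset, population), , drop = FALSE]
  pos <- dataset$markers$pos
  chrom <- dataset$markers$chrom
  m <- length(pos)

  r2_pair <- function(i, j) {
    suppressWarnings(stats::cor(g[, i], g[, j], use = "pairwise.complete.obs"))^2
  }
  # intra-chromosome pairs: sample an anchor marker, then a partner uniformly
  # among the markers within max_distance upstream on the same chromosome
  anchors <- sample.int(m, n_pairs, replace = TRUE)
  chrom_index <- split(seq_len(m), chrom)
  j <- rep(NA_integer_, n_pairs)
  for (ch in names(chrom_index)) {
    idx <- chrom_index[[ch]]           # global indices, pos sorted within
    local_pos <- pos[idx]
    sel <- which(chrom[anchors] == ch)
    if (length(sel) == 0) next
    a_local <- match(anchors[sel], idx)
    lo_local <- findInterval(local_pos[a_local] - max_distance, local_pos) + 1L
    hi_local <- a_local - 1L
    span <- hi_local - lo_local + 1L
    okk <- span >= 1
    pick <- rep(NA_integer_, length(sel))
    pick[okk] <- lo_local[okk] +
      floor(stats::runif(sum(okk)) * span[okk])
    j[sel] <- idx[pick]
  }
  ok <- !is.na(j)
  i <- anchors[ok]; j <- j[ok]
  r2 <- vapply(seq_along(i), function(k) r2_pair(i[k], j[k]), 1.0)
  d <- pos[i] - pos[j]
  bin <- ceiling(d / bin_width)
  keep <- !is.na(r2)
  bins <- data.frame(
    dist_upper = as.integer(names(tapply(r2[keep], bin[keep], mean))) * bin_width,
    mean_r2 = as.numeric(tapply(r2[keep], bin[keep], mean)),
    n = as.integer(tapply(r2[keep], bin[keep], length))
  )
  bins <- bins[order(bins$dist_upper), ]
  # inter-chromosome background
  bi <- sample.int(m, n_pairs, replace = TRUE)
  bj <- sample.int(m, n_pairs, replace = TRUE)
  bok <- chrom[bi] != chrom[bj]
  br2 <- vapply(which(bok), function(k) r2_pair(bi[k], bj[k]), 1.0)
  background <- mean(br2, na.rm = TRUE)
  at_bg <- bins$dist_upper[bins$mean_r2 <= background + 0.01]
  list(
    bins = bins,
    background = background,
    recommended_window = if (length(at_bg) > 0) min(at_bg) else NA_integer_
  )
}
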