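#' Reynolds genetic distances between populations
#'
#' `D(i,j) = sum_l (p_il - p_jl)^2 / sum_l [1 - p_il p_jl - (1-p_il)(1-p_jl)]`
#' over the retained markers; a short-term, drift-appropriate coancestry
#' distance.
#'
#' @param x a [genotype_dataset()] or a markers x populations frequency
#'   matrix.
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
reynolds_distances <- function(x) {
  p <- if (inherits(x, "genotype_dataset")) population_frequencies(x) else x
  p <- p[stats::complete.cases(p), , drop = FALSE]
  k <- ncol(p)
  if (k < 2) stop("need >= 2 populations")
  D <- matrix(0, k, k, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      num <- sum((p[, i] - p[, j])^2)
      den <- sum(1 - p[, i] * p[, j] - (1 - p[, i]) * (1 - p[, j]))
      if (den == 0) stop("no shared polymorphism between ", colnames(p)[i],
                         " and ", colnames(p)[j])
      D[i, j] <- D[j, i] <- num / den
    }
  }
  D
}

#' Population kinship matrix from a Reynolds-distance tree
#'
#' Builds a neighbour-joining tree from the distance matrix (a two-leaf
#' "star" for two populations), midpoint-roots it (no outgroup is assumed to
#' exist among the populations), clamps negative NJ branch lengths to zero,
#' and returns the drift covariance `F`: `F_ij` is the branch length shared
#' by the root-to-i and root-to-j paths, `F_ii` the root-to-i path length.
#'
#' @param reynolds symmetric distance matrix with population names.
#' @return List with `F` (kinship matrix), `tree` (an \pkg{ape} `phylo`) and
#'   `n_clamped` (negative branch lengths set to zero).
#' @export
kinship_from_tree <- function(reynolds) {
  if (any(!is.finite(reynolds))) stop("non-finite distances")
  pops <- colnames(reynolds)
  k <- length(pops)
  if (k == 2) {
    d <- reynolds[1, 2]
    F <- diag(rep(d / 2, 2))
    dimnames(F) <- list(pops, pops)
    tree <- ape::read.tree(
      text = sprintf("(%s:%f,%s:%f);", pops[1], d / 2, pops[2], d / 2)
    )
    return(list(F = F, tree = tree, n_clamped = 0L))
  }
  tree <- ape::nj(stats::as.dist(reynolds))
  n_clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree <- phangorn::midpoint(tree)
  # root-to-node distances; F_ij = depth of the MRCA of tips i and j
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  depths <- ape::dist.nodes(tree)[root, ]
  mrca <- ape::mrca(tree)
  F <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      F[i, j] <- if (i == j) depths[i] else depths[mrca[i, j]]
    }
  }
  F <- F[pops, pops]
  list(F = F, tree = tree, n_clamped = n_clamped)
}

#' Single-marker FLK statistic
#'
#' Tests whether population allele frequencies at one marker deviate from
#' neutral drift under the population tree:
#' `p0 = (1' F^-1 p) / (1' F^-1 1)`;
#' `T = (p - p0 1)' [p0 (1 - p0) F]^-1 (p - p0 1)`,
#' compared to a chi-squared distribution with `n_populations - 1` degrees
#' of freedom.
#'
#' @param p vector of per-population frequencies at the marker.
#' @param F kinship matrix from [kinship_from_tree()].
#' @return List with `T`, `df`, `p_value` (`NA` with a reason when the
#'   estimated ancestral frequency is 0 or 1).
#' @export
flk_stat <- function(p, F) {
  Finv <- tryCatch(solve(F), error = function(e) stop("singular kinship matrix"))
  one <- rep(1, length(p))
  p0 <- as.numeric(crossprod(one, Finv %*% p) / crossprod(one, Finv %*% one))
  if (p0 <= 0 || p0 >= 1) {
    return(list(T = NA_real_, df = length(p) - 1L, p_value = NA_real_,
                skipped = "estimated ancestral frequency at the boundary"))
  }
  r <- p - p0
  T <- as.numeric(crossprod(r, Finv %*% r)) / (p0 * (1 - p0))
  df <- length(p) - 1L
  list(T = T, df = df, p_value = stats::pchisq(T, df, lower.tail = FALSE))
}

#' FLK scan over all markers
#'
#' Vectorised [flk_stat()] across a frequency table, with a pooled
#' minor-allele-frequency filter applied first. Markers whose estimated
#' ancestral frequency lands on the boundary are skipped (count reported).
#'
#' @param x a [genotype_dataset()] or a markers x populations frequency
#'   matrix (then `markers` must be given).
#' @param F kinship matrix.
#' @param maf_min pooled minor-allele-frequency filter (default 0.05).
#' @param markers optional data.frame (`chrom`, `pos`) aligned with a matrix
#'   input.
#' @return data.frame `chrom`, `pos`, `T`, `df`, `p_value`, `neg_log10_p`;
#'   `attr(, "n_skipped")` counts boundary markers.
#' @export
flk_scan <- function(x, F, maf_min = 0.05, markers = NULL) {
  if (inherits(x, "genotype_dataset")) {
    P <- population_frequencies(x)[, colnames(F), drop = FALSE]
    markers <- x$markers
  } else {
    P <- x[, colnames(F), drop = FALSE]
    if (is.null(markers)) {
      markers <- data.frame(chrom = "chr?", pos = seq_len(nrow(P)))
    }
  }
  complete <- stats::complete.cases(P)
  pooled <- rowMeans(P)
  keep <- complete & pmin(pooled, 1 - pooled) >= maf_min
  P <- P[keep, , drop = FALSE]
  markers <- markers[keep, , drop = FALSE]
  Finv <- tryCatch(solve(F), error = function(e) stop("singular kinship matrix"))
  one <- rep(1, ncol(P))
  w <- as.numeric(Finv %*% one)
  p0 <- as.numeric(P %*% w) / sum(w)
  usable <- p0 > 0 & p0 < 1
  R <- P - p0 %o% one
  T <- rowSums((R %*% Finv) * R) / (p0 * (1 - p0))
  T[!usable] <- NA_real_
  df <- ncol(P) - 1L
  out <- data.frame(
    chrom = markers$chrom, pos = markers$pos,
    T = T, df = df,
    p_value = stats::pchisq(T, df, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  out$neg_log10_p <- -log10(out$p_value)
  out <- out[usable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!usable)
  out
}

#' Haplotype-cluster FLK window statistic
#'
#' A permutation-calibrated, haplotype-level analogue of the single-marker
#' test (it is not the fastPHASE-based hapFLK model). Window haplotypes are
#' clustered by k-medoids on Hamming distance; each cluster's membership is
#' treated as a biallelic allele and its FLK T summed over clusters. The
#' p-value is `(1 + #{perm >= observed}) / (1 + n_perm)` under permutation
#' of individuals across populations.
#'
#' @param dataset a phased [genotype_dataset()].
#' @param marker_idx integer indices of the window's markers.
#' @param F kinship matrix.
#' @param K number of haplotype clusters (default 5).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed (clustering and permutations).
#' @return List with `T`, `p_value`, `K`, `n_perm` and the window span.
#' @export
hapcluster_flk_window <- function(dataset, marker_idx, F, K = 5,
                                  n_perm = 1000, seed = 1) {
  if (!dataset$phased) {
    stop("unphased data: use the single-SNP FLK scan (flk_scan) instead")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- rbind(dataset$hap1[, marker_idx, drop = FALSE],
             dataset$hap2[, marker_idx, drop = FALSE])  # 2N x W
  h[is.na(h)] <- 0L
  pops2 <- rep(unname(dataset$populations), 2)
  if (nrow(unique(h)) < 2) stop("fewer than 2 distinct haplotypes in window")
  K_eff <- min(K, nrow(unique(h)))
  dmat <- stats::dist(h, method = "manhattan")
  cl <- cluster::pam(dmat, k = K_eff, cluster.only = TRUE)

  stat_from_assignment <- function(pop_labels) {
    pops <- colnames(F)
    freq <- vapply(pops, function(pp) {
      tabulate(cl[pop_labels == pp], nbins = K_eff) / sum(pop_labels == pp)
    }, numeric(K_eff))
    tot <- 0
    for (kk in seq_len(K_eff)) {
      st <- flk_stat(freq[kk, ], F)
      if (!is.na(st$T)) tot <- tot + st$T
    }
    tot
  }
  obs <- stat_from_assignment(pops2)
  n_ind <- length(dataset$samples)
  perm_ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_ind)
    plab <- unname(dataset$populations)[perm]
    perm_ge <- perm_ge + (stat_from_assignment(rep(plab, 2)) >= obs)
  }
  list(
    T = obs,
    p_value = (1 + perm_ge) / (1 + n_perm),
    K = K_eff, n_perm = n_perm,
    chrom = dataset$markers$chrom[marker_idx[1]],
    start = dataset$markers$pos[marker_idx[1]],
    end = dataset$markers$pos[marker_idx[length(marker_idx)]]
  )
}

#' Call FLK regions from a marker scan
#'
#' Markers below `cutoff_p` are selected and runs separated by at most
#' `merge_gap` bp merged into regions; each region reports its most
#' significant marker. A second, stringent tier flags regions whose peak
#' passes the Bonferroni cutoff `alpha / n_tests`.
#'
#' @param results data.frame from [flk_scan()] (sorted by chrom, pos).
#' @param cutoff_p selection cutoff (default `1e-5`).
#' @param merge_gap merge distance in bp (default 100 kb).
#' @param alpha family-wise level for the Bonferroni tier.
#' @param n_tests number of tests for the Bonferroni tier (default
#'   `nrow(results)`).
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_snps`,
#'   `most_significant_pos`, `min_p`, `bonferroni`;
#'   `attr(, "bonferroni_neg_log10")` holds `-log10(alpha / n_tests)`.
#' @export
call_flk_regions <- function(results, cutoff_p = 1e-5, merge_gap = 100000,
                             alpha = 0.05, n_tests = nrow(results)) {
  bonf_cut <- alpha / n_tests
  sel <- results[!is.na(results$p_value) & results$p_value < cutoff_p, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_snps = integer(), most_significant_pos = integer(),
                      min_p = numeric(), bonferroni = logical(),
                      stringsAsFactors = FALSE)
  attr(empty, "bonferroni_neg_log10") <- -log10(bonf_cut)
  if (nrow(sel) == 0) return(empty)
  sel <- sel[order(sel$chrom, sel$pos), , drop = FALSE]
  new_region <- c(TRUE, sel$chrom[-1] != sel$chrom[-nrow(sel)] |
                    diff(sel$pos) > merge_gap)
  rid <- cumsum(new_region)
  rows <- lapply(split(sel, rid), function(d) {
    data.frame(
      chrom = d$chrom[1], start = min(d$pos), end = max(d$pos),
      n_snps = nrow(d),
      most_significant_pos = d$pos[which.min(d$p_value)],
      min_p = min(d$p_value),
      bonferroni = min(d$p_value) < bonf_cut,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni_neg_log10") <- -log10(bonf_cut)
  out
}
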