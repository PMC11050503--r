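#' Observed heterozygosity
#'
#' Per retained locus, the fraction of typed genotypes that are heterozygous;
#' loci with no typed genotype in the population are dropped. The standard
#' error is the standard deviation over loci divided by `sqrt(#loci)`.
#'
#' @param dataset a [genotype_dataset()].
#' @param population population label.
#' @return List with `per_locus`, `mean`, `se`, `n_loci`.
#' @export
observed_heterozygosity <- function(dataset, population) {
  g <- dataset$geno[population_samples(dataset, population), , drop = FALSE]
  typed <- colSums(!is.na(g))
  keep <- typed > 0
  ho <- colSums(g == 1L, na.rm = TRUE)[keep] / typed[keep]
  list(per_locus = unname(ho), mean = mean(ho),
       se = stats::sd(ho) / sqrt(length(ho)), n_loci = length(ho))
}

#' Unbiased expected heterozygosity
#'
#' Nei's small-sample-corrected gene diversity per locus:
#' `uHE = 2n/(2n - 1) * (1 - sum(p_a^2))` with `n` typed diploids and allele
#' frequencies estimated from allele counts. Loci with fewer than two typed
#' diploids are dropped (their count is reported).
#'
#' @inheritParams observed_heterozygosity
#' @return List with `per_locus`, `mean`, `se`, `n_loci`, `n_dropped`.
#' @export
unbiased_expected_heterozygosity <- function(dataset, population) {
  g <- dataset$geno[population_samples(dataset, population), , drop = FALSE]
  n <- colSums(!is.na(g))
  keep <- n >= 2
  p <- colSums(g, na.rm = TRUE)[keep] / (2 * n[keep])
  uhe <- (2 * n[keep]) / (2 * n[keep] - 1) * (1 - p^2 - (1 - p)^2)
  list(per_locus = unname(uhe), mean = mean(uhe),
       se = stats::sd(uhe) / sqrt(length(uhe)),
       n_loci = sum(keep), n_dropped = sum(!keep))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g` gene copies,
#' per locus: `sum_a [1 - choose(N - N_a, g) / choose(N, g)]` with `N` typed
#' gene copies and `N_a` copies of allele `a`; averaged over loci. For
#' biallelic data the result lies in `[1, 2]`.
#'
#' @param dataset a [genotype_dataset()].
#' @param populations labels to summarise; default all.
#' @param g rarefaction size in gene copies; default the minimum typed copy
#'   count over all retained loci and populations (so the precondition
#'   `g <= N` always holds).
#' @return List with `per_population` (mean and SE over loci per population)
#'   and the `g` used.
#' @export
rarefied_allelic_richness <- function(dataset, populations = NULL, g = NULL) {
  if (is.null(populations)) populations <- unique(unname(dataset$populations))
  counts <- lapply(populations, function(pop) {
    gm <- dataset$geno[population_samples(dataset, pop), , drop = FALSE]
    N <- 2 * colSums(!is.na(gm))
    Na <- colSums(gm, na.rm = TRUE)  # alt copies
    cbind(N = N, Na = Na)
  })
  names(counts) <- populations
  if (is.null(g)) {
    g <- min(vapply(counts, function(cc) min(cc[cc[, "N"] > 0, "N"]), 0))
  }
  if (g < 2) stop("rarefaction size g must be >= 2")
  per_pop <- lapply(populations, function(pop) {
    cc <- counts[[pop]]
    keep <- cc[, "N"] >= g
    N <- cc[keep, "N"]; Na <- cc[keep, "Na"]
    ar <- (1 - exp(lchoose(N - Na, g) - lchoose(N, g))) +
      (1 - exp(lchoose(Na, g) - lchoose(N, g)))
    data.frame(population = pop, A_R = mean(ar),
               se = stats::sd(ar) / sqrt(length(ar)),
               n_loci = length(ar), stringsAsFactors = FALSE)
  })
  list(per_population = do.call(rbind, per_pop), g = g)
}

#' Multilocus inbreeding coefficient with bootstrap CI
#'
#' `uFIS = 1 - mean(H_O per locus) / mean(uHE per locus)` (ratio of means),
#' with a percentile 95% confidence interval from bootstrap resampling of
#' loci. Only loci retained by both heterozygosity computations (>= 2 typed
#' diploids) enter.
#'
#' @inheritParams observed_heterozygosity
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return List with `ufis`, `ci95` (2.5/97.5 percentiles), `n_loci`.
#' @export
ufis_with_ci <- function(dataset, population, n_boot = 1000, seed = 1) {
  g <- dataset$geno[population_samples(dataset, population), , drop = FALSE]
  n <- colSums(!is.na(g))
  keep <- n >= 2
  if (sum(keep) < 2) stop("need >= 2 loci with >= 2 typed diploids")
  g <- g[, keep, drop = FALSE]
  n <- n[keep]
  ho <- colSums(g == 1L, na.rm = TRUE) / n
  p <- colSums(g, na.rm = TRUE) / (2 * n)
  uhe <- (2 * n) / (2 * n - 1) * (1 - p^2 - (1 - p)^2)
  if (mean(uhe) == 0) stop("no polymorphism: mean uHE is zero")
  est <- 1 - mean(ho) / mean(uhe)
  L <- length(ho)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- matrix(sample.int(L, L * n_boot, replace = TRUE), ncol = n_boot)
  boot_ho <- colMeans(matrix(ho[idx], ncol = n_boot))
  boot_uhe <- colMeans(matrix(uhe[idx], ncol = n_boot))
  boot <- 1 - boot_ho / boot_uhe
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  list(ufis = est, ci95 = ci, n_loci = L, n_boot = n_boot)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Diversity summary table
#'
#' One row per population: observed and unbiased expected heterozygosity
#' (mean and SE over loci), rarefied allelic richness and the bootstrap
#' uFIS with its 95% CI.
#'
#' @param dataset a [genotype_dataset()].
#' @param g rarefaction size (see [rarefied_allelic_richness()]).
#' @param n_boot,seed bootstrap settings for [ufis_with_ci()].
#' @return data.frame mirroring a per-breed diversity table.
#' @export
diversity_summary <- function(dataset, g = NULL, n_boot = 1000, seed = 1) {
  pops <- unique(unname(dataset$populations))
  ar <- rarefied_allelic_richness(dataset, pops, g = g)
  rows <- lapply(pops, function(pop) {
    ho <- observed_heterozygosity(dataset, pop)
    uhe <- unbiased_expected_heterozygosity(dataset, pop)
    fis <- ufis_with_ci(dataset, pop, n_boot = n_boot, seed = seed)
    arr <- ar$per_population[ar$per_population$population == pop, ]
    data.frame(
      population = pop, n = sum(dataset$populations == pop),
      H_O = ho$mean, H_O_se = ho$se,
      uH_E = uhe$mean, uH_E_se = uhe$se,
      A_R = arr$A_R, A_R_se = arr$se,
      uF_IS = fis$ufis, uF_IS_lo = fis$ci95[1], uF_IS_hi = fis$ci95[2],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "rarefaction_g") <- ar$g
  out
}

#' PCA on the variance-standardised relationship matrix
#'
#' Genotypes are standardised per marker as `(x - 2p) / sqrt(2p(1 - p))`,
#' missing values set to zero after centering (mean imputation) and
#' monomorphic markers dropped. The genomic relationship matrix is
#' `Z Z' / m`; coordinates are its leading eigenvectors scaled by the square
#' roots of the eigenvalues.
#'
#' @param dataset a [genotype_dataset()].
#' @param n_components number of PCs to return.
#' @return List with `coords` (data.frame: sample, population, PC1..PCk),
#'   `eigenvalues` and `var_explained` (fractions of the total).
#' @export
pca_grm <- function(dataset, n_components = 2) {
  if (length(dataset$samples) < 2) stop("need >= 2 samples")
  g <- dataset$geno
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(g, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  grm <- tcrossprod(z) / ncol(z)
  e <- eigen(grm, symmetric = TRUE)
  k <- min(n_components, length(e$values))
  ev <- pmax(e$values, 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev[seq_len(k)]), k)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(
    coords = data.frame(sample = dataset$samples,
                        population = unname(dataset$populations),
                        coords, stringsAsFactors = FALSE),
    eigenvalues = e$values,
    var_explained = ev[seq_len(k)] / sum(ev)
  )
}
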