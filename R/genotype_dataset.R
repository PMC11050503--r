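#' In-memory genotype dataset
#'
#' The single genotype representation shared by every analysis stage: an
#' (individuals x markers) matrix of alternate-allele dosages together with a
#' marker table, a sample-to-population map and, when the source data were
#' phased, the two haplotype matrices.
#'
#' @param geno integer matrix, samples in rows and markers in columns, entries
#'   in `{0, 1, 2, NA}` counting copies of the alternate allele.
#' @param markers data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`; positions must be strictly increasing within each chromosome.
#' @param populations named character vector mapping sample id to population
#'   label; names must cover `rownames(geno)`.
#' @param hap1,hap2 optional binary matrices of the same shape as `geno`
#'   holding the two phased haplotypes (`hap1 + hap2 == geno` wherever typed).
#'
#' @return An object of class `genotype_dataset` (a list with elements
#'   `geno`, `markers`, `samples`, `populations`, `hap1`, `hap2`, `phased`).
#' @export
genotype_dataset <- function(geno, markers, populations, hap1 = NULL, hap2 = NULL) {
  stopifnot(is.matrix(geno), nrow(markers) == ncol(geno))
  if (is.null(rownames(geno))) stop("geno must have sample ids as rownames")
  samples <- rownames(geno)
  missing_pop <- setdiff(samples, names(populations))
  if (length(missing_pop) > 0) {
    stop("samples absent from population map: ", paste(missing_pop, collapse = ", "))
  }
  markers$chrom <- as.character(markers$chrom)
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0)) stop("marker positions not strictly increasing on ", ch)
  }
  if (!is.null(hap1) != !is.null(hap2)) stop("provide both haplotype matrices or neither")
  if (!is.null(hap1)) {
    stopifnot(dim(hap1) == dim(geno), dim(hap2) == dim(geno))
    both <- !is.na(hap1) & !is.na(hap2) & !is.na(geno)
    if (any((hap1 + hap2)[both] != geno[both])) {
      stop("haplotype sum disagrees with genotype codes")
    }
  }
  structure(
    list(
      geno = geno, markers = markers, samples = samples,
      populations = populations[samples],
      hap1 = hap1, hap2 = hap2, phased = !is.null(hap1)
    ),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "genotype_dataset: %d samples x %d markers on %d chromosome(s), %s\n",
    length(x$samples), nrow(x$markers), length(unique(x$markers$chrom)),
    if (x$phased) "phased" else "unphased"
  ))
  tab <- table(x$populations)
  cat("populations:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$geno)

#' Samples belonging to one population
#' @param dataset a [genotype_dataset()].
#' @param population population label.
#' @return Character vector of sample ids.
#' @export
population_samples <- function(dataset, population) {
  if (!population %in% dataset$populations) {
    stop("unknown population label: ", population)
  }
  dataset$samples[dataset$populations == population]
}

#' Per-population alternate-allele frequencies
#'
#' Frequencies are computed from typed genotypes only; markers with no typed
#' genotype in a population get `NA` there.
#'
#' @param dataset a [genotype_dataset()].
#' @param populations labels to include; default all.
#' @return Numeric matrix, markers x populations.
#' @export
population_frequencies <- function(dataset, populations = NULL) {
  if (is.null(populations)) populations <- unique(unname(dataset$populations))
  out <- sapply(populations, function(pop) {
    g <- dataset$geno[dataset$populations == pop, , drop = FALSE]
    colMeans(g, na.rm = TRUE) / 2
  })
  out[is.nan(out)] <- NA_real_
  colnames(out) <- populations
  out
}

#' Subset a dataset by samples and/or markers
#' @param dataset a [genotype_dataset()].
#' @param samples sample ids to keep (default all).
#' @param marker_idx integer indices of markers to keep (default all).
#' @return A new `genotype_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, marker_idx = NULL) {
  if (is.null(samples)) samples <- dataset$samples
  if (is.null(marker_idx)) marker_idx <- seq_len(nrow(dataset$markers))
  genotype_dataset(
    geno = dataset$geno[samples, marker_idx, drop = FALSE],
    markers = dataset$markers[marker_idx, , drop = FALSE],
    populations = dataset$populations,
    hap1 = if (dataset$phased) dataset$hap1[samples, marker_idx, drop = FALSE],
    hap2 = if (dataset$phased) dataset$hap2[samples, marker_idx, drop = FALSE]
  )
}
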