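#' Simulation configuration
#'
#' Describes a multi-population genotype simulation: population sizes, one or
#' more chromosomes, an expected SNP density, per-population drift away from
#' a common ancestor (Balding-Nichols model), optional implanted sweeps and
#' autozygous tracts, and a missing-genotype rate. A fixed `seed` makes every
#' downstream draw reproducible.
#'
#' @param n_populations number of populations.
#' @param samples_per_population integer vector (recycled if length 1) of
#'   diploid sample counts, each >= 2.
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param snp_density expected SNPs per bp (e.g. `1e-3` is 50 SNPs per 50 kb).
#' @param drift_fst per-population drift parameter, strictly inside (0, 1);
#'   recycled if length 1.
#' @param sweep_specs list of [sweep_spec()] objects.
#' @param roh_specs list of [roh_spec()] objects.
#' @param missing_rate fraction of genotype calls masked as missing, in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @param pop_labels population labels; default `pop1`, `pop2`, ...
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_populations = 3,
                       samples_per_population = c(20, 20, 17),
                       chromosomes = c(chr1 = 50e6),
                       snp_density = 1e-3,
                       drift_fst = 0.05,
                       sweep_specs = list(),
                       roh_specs = list(),
                       missing_rate = 0.01,
                       seed = 1,
                       pop_labels = NULL) {
  if (is.null(pop_labels)) pop_labels <- paste0("pop", seq_len(n_populations))
  stopifnot(length(pop_labels) == n_populations)
  samples_per_population <- rep_len(samples_per_population, n_populations)
  drift_fst <- rep_len(drift_fst, n_populations)
  if (any(drift_fst <= 0 | drift_fst >= 1)) {
    stop("drift_fst must be strictly inside (0, 1)")
  }
  if (any(samples_per_population < 2)) stop("need >= 2 samples per population")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (is.null(names(chromosomes))) {
    names(chromosomes) <- paste0("chr", seq_along(chromosomes))
  }
  for (sp in sweep_specs) {
    if (!sp$target_population %in% pop_labels) {
      stop("sweep target population not in config: ", sp$target_population)
    }
    if (!sp$chromosome %in% names(chromosomes)) {
      stop("sweep chromosome not in config: ", sp$chromosome)
    }
  }
  for (rs in roh_specs) {
    if (!rs$target_population %in% pop_labels) {
      stop("ROH target population not in config: ", rs$target_population)
    }
  }
  structure(
    list(
      n_populations = n_populations,
      samples_per_population = samples_per_population,
      pop_labels = pop_labels,
      chromosomes = chromosomes,
      snp_density = snp_density,
      drift_fst = stats::setNames(drift_fst, pop_labels),
      sweep_specs = sweep_specs,
      roh_specs = roh_specs,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Sweep specification
#'
#' One implanted selective sweep: inside `[start, end]` on `chromosome`, the
#' target population's allele frequency is pushed to `post_sweep_frequency`
#' (orientation chosen per marker so differentiation from the other
#' populations increases).
#'
#' @param chromosome chromosome name.
#' @param start,end 1-based inclusive bp bounds, `end > start`.
#' @param target_population population label.
#' @param post_sweep_frequency frequency after the sweep, in (0.9, 1].
#' @export
sweep_spec <- function(chromosome, start, end, target_population,
                       post_sweep_frequency = 0.98) {
  if (end <= start) stop("sweep end must exceed start")
  if (post_sweep_frequency <= 0.9 || post_sweep_frequency > 1) {
    stop("post_sweep_frequency must be in (0.9, 1]")
  }
  structure(list(chromosome = chromosome, start = start, end = end,
                 target_population = target_population,
                 post_sweep_frequency = post_sweep_frequency),
            class = "sweep_spec")
}

#' Autozygous-tract specification
#'
#' Tracts are implanted per individual of the target population: the number
#' of tracts is Poisson with mean `expected_tracts_per_individual`, each
#' tract's length class is drawn from `class_weights` over the length classes
#' 0.5-2, 2-4 and 4-8 Mb, its length uniform within the class and its start
#' uniform along the genome.
#'
#' @param target_population population label.
#' @param class_weights nonnegative weights over the three length classes,
#'   normalised internally.
#' @param expected_tracts_per_individual Poisson mean tract count.
#' @param class_bounds_mb numeric matrix-defining vector of class bounds in Mb.
#' @export
roh_spec <- function(target_population,
                     class_weights = c(0.6, 0.3, 0.1),
                     expected_tracts_per_individual = 10,
                     class_bounds_mb = c(0.5, 2, 4, 8)) {
  if (any(class_weights < 0) || sum(class_weights) <= 0) {
    stop("class weights must be nonnegative and sum to a positive value")
  }
  stopifnot(length(class_weights) == length(class_bounds_mb) - 1)
  structure(list(target_population = target_population,
                 class_weights = class_weights / sum(class_weights),
                 expected_tracts_per_individual = expected_tracts_per_individual,
                 class_bounds_mb = class_bounds_mb),
            class = "roh_spec")
}

#' Simulate ancestral and per-population allele frequencies
#'
#' Marker positions are a Poisson process along each chromosome (sorted,
#' deduplicated). Ancestral frequencies are uniform on `[0.05, 0.95]`; each
#' population's frequency is a Beta draw with mean equal to the ancestral
#' frequency and variance `F * p * (1 - p)` with `F` that population's
#' `drift_fst` (the Balding-Nichols model).
#'
#' @param config a [sim_config()].
#' @return A list with `markers` (chrom, pos), `ancestral` and `pop_freq`
#'   (markers x populations matrix).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  marker_list <- lapply(names(config$chromosomes), function(ch) {
    L <- config$chromosomes[[ch]]
    n <- stats::rpois(1, L * config$snp_density)
    pos <- sort(as.integer(ceiling(stats::runif(n, 0, L))))
    pos <- pos[!duplicated(pos)]
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, marker_list)
  m <- nrow(markers)
  anc <- stats::runif(m, 0.05, 0.95)
  pop_freq <- sapply(config$pop_labels, function(pop) {
    f <- config$drift_fst[[pop]]
    shape <- (1 - f) / f
    stats::rbeta(m, anc * shape, (1 - anc) * shape)
  })
  colnames(pop_freq) <- config$pop_labels
  list(markers = markers, ancestral = anc, pop_freq = pop_freq)
}

#' Implant a sweep into a frequency table
#'
#' Markers inside the sweep interval get frequency `post_sweep_frequency` in
#' the target population, oriented per marker so that the difference to the
#' mean frequency of the other populations increases (i.e. the frequency is
#' set to `1 - post_sweep_frequency` where the others are already high).
#' All other entries are untouched.
#'
#' @param freqs output of [simulate_frequencies()].
#' @param spec a [sweep_spec()].
#' @return `freqs` with the modified `pop_freq` and the spec appended to
#'   `attr(, "sweeps")`.
#' @export
implant_sweep <- function(freqs, spec) {
  idx <- which(freqs$markers$chrom == spec$chromosome &
                 freqs$markers$pos >= spec$start &
                 freqs$markers$pos <= spec$end)
  if (length(idx) == 0) {
    stop(sprintf("sweep interval %s:%d-%d contains no markers",
                 spec$chromosome, spec$start, spec$end))
  }
  others <- setdiff(colnames(freqs$pop_freq), spec$target_population)
  other_mean <- rowMeans(freqs$pop_freq[idx, others, drop = FALSE])
  hi <- spec$post_sweep_frequency
  freqs$pop_freq[idx, spec$target_population] <- ifelse(other_mean > 0.5, 1 - hi, hi)
  attr(freqs, "sweeps") <- c(attr(freqs, "sweeps"), list(spec))
  freqs
}

#' Simulate phased genotypes with implanted autozygous tracts
#'
#' Each haplotype allele is an independent Bernoulli draw from its
#' population's frequency (Hardy-Weinberg, linkage equilibrium outside
#' tracts; set `rho > 0` for block-copying of adjacent alleles). Tracts from
#' the config's `roh_specs` are implanted per individual by copying haplotype
#' 1 onto haplotype 2 across the tract, then genotype calls are masked at
#' `missing_rate`.
#'
#' @param freqs output of [simulate_frequencies()] (after any
#'   [implant_sweep()] calls).
#' @param config the same [sim_config()].
#' @param rho probability of copying the previous marker's allele instead of
#'   drawing fresh (simple LD knob, default 0).
#' @return A list with `dataset` (a [genotype_dataset()]) and `truth`
#'   (`sweeps` and `tracts` data.frames, 1-based inclusive coordinates).
#' @export
simulate_genotypes <- function(freqs, config, rho = 0) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- nrow(freqs$markers)
  sample_ids <- unlist(lapply(seq_along(config$pop_labels), function(i) {
    sprintf("%s_%02d", config$pop_labels[i], seq_len(config$samples_per_population[i]))
  }))
  pops <- rep(config$pop_labels, config$samples_per_population)
  names(pops) <- sample_ids
  n <- length(sample_ids)

  draw_hap <- function() {
    p <- t(freqs$pop_freq[, pops, drop = FALSE])  # samples x markers
    h <- matrix(stats::rbinom(n * m, 1L, as.vector(p)), nrow = n)
    if (rho > 0 && m > 1) {
      copy <- matrix(stats::runif(n * (m - 1)) < rho, nrow = n)
      for (j in 2:m) {
        same_chrom <- freqs$markers$chrom[j] == freqs$markers$chrom[j - 1]
        if (same_chrom) {
          cc <- copy[, j - 1]
          h[cc, j] <- h[cc, j - 1]
        }
      }
    }
    h
  }
  hap1 <- draw_hap()
  hap2 <- draw_hap()
  rownames(hap1) <- rownames(hap2) <- sample_ids

  # implant autozygous tracts: copy hap1 over hap2 across the tract
  tract_rows <- list()
  chrom_names <- names(config$chromosomes)
  chrom_len <- config$chromosomes
  for (rs in config$roh_specs) {
    for (sid in sample_ids[pops == rs$target_population]) {
      k <- stats::rpois(1, rs$expected_tracts_per_individual)
      if (k == 0) next
      cls <- sample.int(length(rs$class_weights), k, replace = TRUE,
                        prob = rs$class_weights)
      len <- stats::runif(k, rs$class_bounds_mb[cls], rs$class_bounds_mb[cls + 1]) * 1e6
      ch_i <- sample.int(length(chrom_names), k, replace = TRUE,
                         prob = chrom_len / sum(chrom_len))
      start <- pmax(1, ceiling(stats::runif(k, 0, pmax(1, chrom_len[ch_i] - len))))
      end <- pmin(chrom_len[ch_i], floor(start + len - 1))
      for (t in seq_len(k)) {
        idx <- which(freqs$markers$chrom == chrom_names[ch_i[t]] &
                       freqs$markers$pos >= start[t] & freqs$markers$pos <= end[t])
        if (length(idx) > 0) hap2[sid, idx] <- hap1[sid, idx]
        tract_rows[[length(tract_rows) + 1]] <- data.frame(
          sample = sid, chrom = chrom_names[ch_i[t]],
          start = as.integer(start[t]), end = as.integer(end[t]),
          stringsAsFactors = FALSE
        )
      }
    }
  }

  geno <- hap1 + hap2
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < config$missing_rate, nrow = n)
    geno[mask] <- NA_integer_
    hap1[mask] <- NA_integer_
    hap2[mask] <- NA_integer_
  }

  # drop markers monomorphic across the whole sample (incl. all-missing)
  typed <- colSums(!is.na(geno))
  mono <- typed == 0 |
    (apply(geno, 2, function(g) length(unique(g[!is.na(g)]))) <= 1 &
       colSums(geno == 1L, na.rm = TRUE) == 0)
  keep <- !mono
  markers <- data.frame(
    chrom = freqs$markers$chrom[keep], pos = freqs$markers$pos[keep],
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  dataset <- genotype_dataset(
    geno = geno[, keep, drop = FALSE], markers = markers, populations = pops,
    hap1 = hap1[, keep, drop = FALSE], hap2 = hap2[, keep, drop = FALSE]
  )

  sweeps <- attr(freqs, "sweeps")
  truth_sweeps <- if (length(sweeps) > 0) {
    do.call(rbind, lapply(sweeps, function(sp) data.frame(
      chrom = sp$chromosome, start = sp$start, end = sp$end,
      target_population = sp$target_population,
      post_sweep_frequency = sp$post_sweep_frequency,
      stringsAsFactors = FALSE
    )))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               target_population = character(), post_sweep_frequency = numeric(),
               stringsAsFactors = FALSE)
  }
  truth_tracts <- if (length(tract_rows) > 0) {
    do.call(rbind, tract_rows)
  } else {
    data.frame(sample = character(), chrom = character(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  }
  list(dataset = dataset,
       truth = list(sweeps = truth_sweeps, tracts = truth_tracts))
}

#' Write a simulated dataset plus truth files to disk
#'
#' Produces the file bundle every downstream stage reads: a phased VCF, a
#' population map TSV, a chromosome-length TSV, truth BEDs for sweeps and
#' implanted tracts, and a small synthetic gene/QTL annotation TSV whose
#' intervals cover the sweep regions (so annotation stages have guaranteed
#' hits).
#'
#' @param sim output of [simulate_genotypes()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @param gzip write the VCF gzip-compressed.
#' @return Named character vector of the paths written.
#' @export
write_fixture_bundle <- function(sim, config, dir, gzip = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ds <- sim$dataset
  paths <- c(
    vcf = file.path(dir, if (gzip) "genotypes.vcf.gz" else "genotypes.vcf"),
    popmap = file.path(dir, "popmap.tsv"),
    chrom_lengths = file.path(dir, "chrom_lengths.tsv"),
    truth_sweeps = file.path(dir, "truth_sweeps.bed"),
    truth_tracts = file.path(dir, "truth_tracts.bed"),
    genes = file.path(dir, "genes.tsv"),
    qtls = file.path(dir, "qtls.gff")
  )
  write_vcf(ds, paths[["vcf"]])
  utils::write.table(
    data.frame(sample_id = ds$samples, population = unname(ds$populations)),
    paths[["popmap"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(chrom = names(config$chromosomes),
               length = as.integer(config$chromosomes)),
    paths[["chrom_lengths"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  sw <- sim$truth$sweeps
  write_regions(
    data.frame(chrom = sw$chrom, start = sw$start, end = sw$end,
               name = sw$target_population, stringsAsFactors = FALSE),
    paths[["truth_sweeps"]], format = "bed"
  )
  tr <- sim$truth$tracts
  write_regions(
    data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
               name = tr$sample, stringsAsFactors = FALSE),
    paths[["truth_tracts"]], format = "bed"
  )

  genes <- synthetic_annotation(sim, config)
  utils::write.table(genes$genes, paths[["genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(genes$qtl_gff, paths[["qtls"]])
  paths
}

# Synthetic gene models and QTLs: one gene inside each sweep, plus background
# genes tiled along each chromosome; QTLs cover the sweeps with assorted
# trait classes.
synthetic_annotation <- function(sim, config) {
  sw <- sim$truth$sweeps
  gene_rows <- list()
  qtl_lines <- character()
  gi <- 0
  for (i in seq_len(nrow(sw))) {
    gi <- gi + 1
    mid <- (sw$start[i] + sw$end[i]) %/% 2
    gene_rows[[gi]] <- data.frame(
      gene_name = sprintf("SWG%03d", gi), chromosome = sw$chrom[i],
      start = mid - 5000L, end = mid + 5000L, stringsAsFactors = FALSE
    )
    qtl_lines <- c(qtl_lines, sprintf(
      "%s\tsynthQTLdb\tQTL\t%d\t%d\t.\t.\t.\tQTL_ID=Q%03d;Name=Body weight;trait_class=Production",
      sw$chrom[i], max(1L, sw$start[i] - 10000L), sw$end[i] + 10000L, gi
    ))
  }
  for (ch in names(config$chromosomes)) {
    L <- config$chromosomes[[ch]]
    starts <- seq(1e6, L - 1e6, by = 5e6)
    for (s in starts) {
      gi <- gi + 1
      gene_rows[[gi]] <- data.frame(
        gene_name = sprintf("BGG%03d", gi), chromosome = ch,
        start = as.integer(s), end = as.integer(s + 20000), stringsAsFactors = FALSE
      )
    }
  }
  list(genes = do.call(rbind, gene_rows), qtl_gff = qtl_lines)
}
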