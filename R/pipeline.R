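#' Run the full selection-signature pipeline
#'
#' Wires the stages in dependency order: input reading, diversity summary,
#' pairwise windowed ZFst scan, FLK scan, ROH detection with FROH and
#' islands, and the multi-evidence consensus caller with gene/QTL
#' annotation. Every stage writes a TSV under `out_dir`, and a run manifest
#' records parameters, seeds and input checksums so identical configs give
#' bit-identical reruns.
#'
#' @param config a named list (or path to a YAML file with the same keys):
#'   `vcf`, `popmap` (paths; required), optional `genes`, `qtls`,
#'   `exclude_chromosomes`, `window_size` (50000), `step` (10000),
#'   `top_fraction` (0.001), `min_snps_per_window` (10), `flk_cutoff_p`
#'   (1e-5), `flk_maf_min` (0.05), `roh` (list of [roh_params()] arguments),
#'   `island_threshold` (0.5), `n_boot` (1000), `seed` (1).
#' @param out_dir output directory.
#' @return Invisibly, a list with every stage's result tables and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    exclude_chromosomes = NULL, genes = NULL, qtls = NULL,
    window_size = 50000, step = 10000, top_fraction = 0.001,
    min_snps_per_window = 10, flk_cutoff_p = 1e-5, flk_maf_min = 0.05,
    roh = list(), island_threshold = 0.5, n_boot = 1000, seed = 1
  )
  config <- utils::modifyList(defaults, config)
  for (key in c("vcf", "popmap")) {
    if (is.null(config[[key]])) stop("pipeline config: missing required path '", key, "'")
    if (!file.exists(config[[key]])) stop("pipeline config: file not found: ", config[[key]])
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  results <- list()

  dataset <- stage("io", read_vcf(config$vcf, config$popmap,
                                  exclude_chromosomes = config$exclude_chromosomes))
  pops <- unique(unname(dataset$populations))

  results$diversity <- stage("diversity",
    diversity_summary(dataset, n_boot = config$n_boot, seed = config$seed))
  write_tsv(results$diversity, file.path(out_dir, "diversity.tsv"))
  results$pca <- stage("diversity", pca_grm(dataset, n_components = 3))
  write_tsv(results$pca$coords, file.path(out_dir, "pca_coords.tsv"))

  pairs <- utils::combn(pops, 2, simplify = FALSE)
  results$zfst <- stage("fst_scan", lapply(pairs, function(pr) {
    zfst_scan(dataset, pr[1], pr[2],
              window_size = config$window_size, step = config$step,
              min_snps = config$min_snps_per_window,
              top_fraction = config$top_fraction)
  }))
  all_windows <- do.call(rbind, lapply(results$zfst, `[[`, "windows"))
  all_blocks <- do.call(rbind, lapply(results$zfst, `[[`, "blocks"))
  write_tsv(all_windows, file.path(out_dir, "zfst_windows.tsv"))
  write_tsv(all_blocks, file.path(out_dir, "zfst_blocks.tsv"))

  results$flk <- stage("flk_scan", {
    kin <- kinship_from_tree(reynolds_distances(dataset))
    scan <- flk_scan(dataset, kin$F, maf_min = config$flk_maf_min)
    regions <- call_flk_regions(scan, cutoff_p = config$flk_cutoff_p,
                                merge_gap = config$step * 10)
    list(kinship = kin, scan = scan, regions = regions)
  })
  write_tsv(results$flk$scan, file.path(out_dir, "flk_scan.tsv"))
  write_tsv(results$flk$regions, file.path(out_dir, "flk_regions.tsv"))

  results$roh <- stage("roh", {
    params <- do.call(roh_params, config$roh)
    segments <- detect_runs(dataset, params = params)
    fr <- froh(segments, dataset)
    islands <- do.call(rbind, lapply(pops, function(pp) {
      roh_islands(segments, pp, dataset, threshold = config$island_threshold)
    }))
    list(segments = segments, froh = fr, islands = islands,
         length_classes = length_class_summary(segments, dataset),
         overlap = island_overlap(islands))
  })
  write_tsv(results$roh$segments, file.path(out_dir, "roh_segments.tsv"))
  write_tsv(results$roh$froh$per_population, file.path(out_dir, "froh.tsv"))
  write_tsv(results$roh$islands, file.path(out_dir, "roh_islands.tsv"))

  results$consensus <- stage("consensus_annot", {
    ev <- list()
    if (nrow(all_blocks) > 0) {
      ev[[length(ev) + 1]] <- evidence_records(
        "zfst", all_blocks$chrom, all_blocks$start, all_blocks$end,
        all_blocks$pair, all_blocks$peak_z)
    }
    if (nrow(results$flk$regions) > 0) {
      ev[[length(ev) + 1]] <- evidence_records(
        "flk", results$flk$regions$chrom, results$flk$regions$start,
        results$flk$regions$end, "all", -log10(results$flk$regions$min_p))
    }
    if (!is.null(results$roh$islands) && nrow(results$roh$islands) > 0) {
      ev[[length(ev) + 1]] <- evidence_records(
        "roh_island", results$roh$islands$chrom, results$roh$islands$start,
        results$roh$islands$end, results$roh$islands$population,
        results$roh$islands$incidence)
    }
    records <- if (length(ev) > 0) do.call(rbind, ev) else evidence_records(
      "zfst", character(), integer(), integer(), character(), numeric())
    regions <- merge_evidence(records)
    if (!is.null(config$genes) && nrow(regions) > 0) {
      dialect <- if (grepl("\\.bed$", config$genes)) "bed" else "biomart_tsv"
      regions <- annotate_genes(regions, read_intervals(config$genes, dialect))
    }
    qtl_out <- NULL
    if (!is.null(config$qtls) && nrow(regions) > 0) {
      qtl_out <- annotate_qtls(regions, read_intervals(config$qtls, "qtl_gff"))
      regions <- qtl_out$regions
    }
    list(evidence = records, regions = regions, qtl = qtl_out)
  })
  write_tsv(results$consensus$regions, file.path(out_dir, "consensus_regions.tsv"))
  if (!is.null(results$consensus$qtl)) {
    write_tsv(results$consensus$qtl$tally, file.path(out_dir, "qtl_tally.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sweepscan")),
    stages = c("io", "diversity", "fst_scan", "flk_scan", "roh", "consensus_annot"),
    parameters = config[setdiff(names(config), c("vcf", "popmap", "genes", "qtls"))],
    inputs = vapply(
      Filter(Negate(is.null), config[c("vcf", "popmap", "genes", "qtls")]),
      function(p) unname(tools::md5sum(p)), ""
    ),
    seed = config$seed
  )
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
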