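#' Read a multi-sample VCF into a genotype dataset
#'
#' Keeps biallelic SNPs only (single-base REF and ALT); multi-allelic and
#' indel records are skipped and counted. Phasing is preserved when every
#' retained genotype uses the `|` separator.
#'
#' @param path VCF file (plain or gzip; parsed with \pkg{vcfR}).
#' @param popmap_path two-column TSV (`sample_id`, `population`), with or
#'   without a header line.
#' @param exclude_chromosomes chromosome names to drop (e.g. sex chromosomes).
#' @param min_call_rate,maf_min optional marker filters, both off (0) by
#'   default.
#' @return A [genotype_dataset()]; attributes `n_skipped_records` and
#'   `n_filtered_markers` count the records removed on the way in.
#' @export
read_vcf <- function(path, popmap_path, exclude_chromosomes = NULL,
                     min_call_rate = 0, maf_min = 0) {
  popmap <- read_popmap(popmap_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  chrom <- as.character(fix[, "CHROM"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  biallelic_snp <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt, fixed = TRUE)
  keep <- biallelic_snp & !(chrom %in% exclude_chromosomes)
  n_skipped <- sum(!biallelic_snp)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  vcf_samples <- colnames(gt)
  absent <- setdiff(vcf_samples, popmap$sample_id)
  if (length(absent) > 0) {
    stop("VCF samples absent from population map: ", paste(absent, collapse = ", "))
  }

  phased <- all(grepl("|", gt[!is.na(gt)], fixed = TRUE))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  a1[a1 == "."] <- NA
  a2[a2 == "."] <- NA
  h1 <- matrix(as.integer(a1), nrow = nrow(gt))
  h2 <- matrix(as.integer(a2), nrow = nrow(gt))
  geno <- t(h1 + h2)  # samples x markers
  rownames(geno) <- vcf_samples

  markers <- data.frame(
    chrom = chrom[keep],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    stringsAsFactors = FALSE
  )
  ord <- order(match(markers$chrom, unique(markers$chrom)), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  h1 <- h1[ord, , drop = FALSE]
  h2 <- h2[ord, , drop = FALSE]
  rownames(markers) <- NULL

  n_filtered <- 0L
  if (min_call_rate > 0 || maf_min > 0) {
    call_rate <- colMeans(!is.na(geno))
    af <- colMeans(geno, na.rm = TRUE) / 2
    maf <- pmin(af, 1 - af)
    maf[is.nan(maf)] <- 0
    keep2 <- call_rate >= min_call_rate & maf >= maf_min
    n_filtered <- sum(!keep2)
    geno <- geno[, keep2, drop = FALSE]
    markers <- markers[keep2, , drop = FALSE]
    h1 <- h1[keep2, , drop = FALSE]
    h2 <- h2[keep2, , drop = FALSE]
    rownames(markers) <- NULL
  }

  pops <- stats::setNames(popmap$population, popmap$sample_id)
  ds <- genotype_dataset(
    geno = geno, markers = markers, populations = pops,
    hap1 = if (phased) t(h1 * 1L) else NULL,
    hap2 = if (phased) t(h2 * 1L) else NULL
  )
  if (phased) {
    rownames(ds$hap1) <- rownames(ds$hap2) <- vcf_samples
  }
  attr(ds, "n_skipped_records") <- n_skipped
  attr(ds, "n_filtered_markers") <- n_filtered
  ds
}

read_popmap <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^sample", first, ignore.case = TRUE)
  pm <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  names(pm)[1:2] <- c("sample_id", "population")
  pm
}

#' Read genomic intervals
#'
#' Three dialects: `bed` (0-based half-open, converted to 1-based inclusive
#' internally), `biomart_tsv` (header with gene name / chromosome / start /
#' end columns) and `qtl_gff` (GFF-style dump with `Name=` and trait-class
#' attributes in column 9).
#'
#' @param path input file.
#' @param dialect one of `"bed"`, `"biomart_tsv"`, `"qtl_gff"`.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `name`, `kind` and (for QTLs) `trait`, `trait_class`,
#'   sorted by (chromosome, start).
#' @export
read_intervals <- function(path, dialect = c("bed", "biomart_tsv", "qtl_gff")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  out <- switch(dialect,
    bed = parse_bed_lines(lines),
    biomart_tsv = parse_biomart_lines(lines),
    qtl_gff = parse_qtl_gff_lines(lines)
  )
  if (nrow(out) == 0) return(out)
  if (any(out$end < out$start)) {
    bad <- which(out$end < out$start)[1]
    stop("interval end < start at record ", bad)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

parse_bed_lines <- function(lines) {
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  if (anyNA(starts) || anyNA(ends)) {
    stop("malformed BED line ", which(is.na(starts) | is.na(ends))[1],
         ": non-numeric coordinates")
  }
  data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = starts + 1L,  # 0-based half-open -> 1-based inclusive
    end = ends,
    name = ifelse(nf >= 4, vapply(fields, function(f) f[4], ""), NA_character_),
    kind = "region",
    stringsAsFactors = FALSE
  )
}

parse_biomart_lines <- function(lines) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), kind = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) <= 1) return(empty)
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"")
  pick <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, names(tab), ignore.case = TRUE)
      if (length(hit) > 0) return(hit[1])
    }
    stop("biomart_tsv: no column matching ", paste(patterns, collapse = "/"))
  }
  data.frame(
    chrom = as.character(tab[[pick(c("chromosome", "^chrom"))]]),
    start = as.integer(tab[[pick(c("start"))]]),
    end = as.integer(tab[[pick(c("end"))]]),
    name = as.character(tab[[pick(c("gene.?name", "^name", "symbol"))]]),
    kind = "gene",
    stringsAsFactors = FALSE
  )
}

parse_qtl_gff_lines <- function(lines) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), kind = character(),
                      trait = character(), trait_class = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 9)) stop("malformed GFF line ", which(nf < 9)[1], ": fewer than 9 fields")
  attr_str <- vapply(fields, function(f) f[9], "")
  get_attr <- function(s, keys) {
    kv <- strsplit(strsplit(s, ";")[[1]], "=")
    kv <- kv[lengths(kv) == 2]
    keys_present <- vapply(kv, function(x) trimws(x[1]), "")
    vals <- vapply(kv, function(x) gsub("^\"|\"$", "", trimws(x[2])), "")
    for (k in keys) {
      hit <- which(tolower(keys_present) == tolower(k))
      if (length(hit) > 0) return(vals[hit[1]])
    }
    NA_character_
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5)))
  if (anyNA(starts) || anyNA(ends)) {
    stop("malformed GFF line ", which(is.na(starts) | is.na(ends))[1],
         ": non-numeric coordinates")
  }
  data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = starts, end = ends,  # GFF is already 1-based inclusive
    name = vapply(attr_str, get_attr, "", keys = c("QTL_ID", "ID", "Name")),
    kind = "qtl",
    trait = vapply(attr_str, get_attr, "", keys = c("trait", "Name")),
    trait_class = vapply(attr_str, get_attr, "",
                         keys = c("trait_class", "traitClass", "Trait_class")),
    stringsAsFactors = FALSE
  )
}

#' Write regions or intervals to BED or TSV
#'
#' BED output converts back to 0-based half-open coordinates; TSV output
#' keeps every column of the input as-is (1-based inclusive coordinates).
#'
#' @param records data.frame with at least `chrom`, `start`, `end`.
#' @param path output file; a `.gz` suffix gzips the output.
#' @param format `"bed"` or `"tsv"`.
#' @export
write_regions <- function(records, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (format == "bed") {
    if (nrow(records) == 0) return(invisible(path))
    name <- if ("name" %in% names(records)) records$name else "."
    lines <- paste(records$chrom, records$start - 1L, records$end,
                   ifelse(is.na(name), ".", name), sep = "\t")
    writeLines(lines, con)
  } else {
    utils::write.table(records, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Write a genotype dataset as VCF 4.2
#'
#' Emits diploid GT records (phased `|` when haplotypes are present, `./.`
#' for missing calls), one record per retained marker.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file; a `.gz` suffix gzips the output.
#' @export
write_vcf <- function(dataset, path) {
  m <- dataset$markers
  ns <- length(dataset$samples)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=sweepscan"),
    vapply(unique(m$chrom), function(ch) {
      sprintf("##contig=<ID=%s>", ch)
    }, ""),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples), collapse = "\t")
  )
  if (dataset$phased) {
    a1 <- t(dataset$hap1); a2 <- t(dataset$hap2)  # markers x samples
    gt <- matrix(paste(a1, a2, sep = "|"), nrow = nrow(m))
    gt[is.na(a1) | is.na(a2)] <- "./."
  } else {
    g <- t(dataset$geno)
    gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(m))
    gt[is.na(g)] <- "./."
  }
  body <- paste(
    m$chrom, m$pos, ".", m$ref, m$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
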