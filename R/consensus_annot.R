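#' Interval length in Mb, printed convention
#'
#' `(end - start) / 1e6`, rounded half-up to 3 decimals (the +1 bp of the
#' inclusive convention is below rounding resolution).
#'
#' @param start,end 1-based inclusive bp coordinates, `end >= start`.
#' @return Numeric length in Mb with 3 decimals.
#' @export
region_length_mb <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  floor((end - start) / 1e6 * 1000 + 0.5) / 1000
}

#' Build an evidence record table
#'
#' Normalises candidate intervals from the three scans into one table with a
#' `method` tag (`zfst`, `flk`, `roh_island`), the populations (or pair)
#' involved, and the method-native score.
#'
#' @param method one of `"zfst"`, `"flk"`, `"roh_island"`.
#' @param chrom,start,end interval coordinates (1-based inclusive).
#' @param populations population label or pair string (e.g. `"popA/popB"`).
#' @param score method-native score (ZFst, -log10 p, incidence).
#' @return data.frame of evidence records.
#' @export
evidence_records <- function(method, chrom, start, end, populations, score = NA_real_) {
  method <- match.arg(method, c("zfst", "flk", "roh_island"))
  data.frame(method = method, chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             populations = as.character(populations),
             score = as.numeric(score), stringsAsFactors = FALSE)
}

#' Merge evidence into consensus regions
#'
#' Builds the interval-overlap graph per chromosome (overlap of at least
#' 1 bp joins two records) and keeps every connected component whose members
#' span at least two distinct methods OR at least two distinct population
#' pairs (pairs are read from records whose `populations` field names two
#' populations, i.e. the pairwise ZFst scans). The region span is the union
#' of member intervals.
#'
#' @param records data.frame from [evidence_records()] (rows may be bound
#'   together from several scans).
#' @return data.frame of consensus regions: `chrom`, `start`, `end`,
#'   `length_mb`, `n_evidence`, `methods`, `populations`;
#'   `attr(, "discarded")` holds the components failing the rule.
#' @export
merge_evidence <- function(records) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length_mb = numeric(), n_evidence = integer(),
                      methods = character(), populations = character(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  stopifnot(all(records$end >= records$start))
  records$.id <- seq_len(nrow(records))
  comps <- list()
  for (ch in unique(records$chrom)) {
    d <- records[records$chrom == ch, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    # single sweep: overlapping-or-nested intervals chain into components
    comp_break <- c(TRUE, d$start[-1] > cummax(d$end)[-nrow(d)])
    cid <- cumsum(comp_break)
    comps <- c(comps, split(d, cid))
  }
  keep_rows <- list()
  discard_rows <- list()
  for (comp in comps) {
    methods <- unique(comp$method)
    pair_labels <- comp$populations[grepl("/", comp$populations, fixed = TRUE)]
    ok <- length(methods) >= 2 || length(unique(pair_labels)) >= 2
    row <- data.frame(
      chrom = comp$chrom[1], start = min(comp$start), end = max(comp$end),
      length_mb = region_length_mb(min(comp$start), max(comp$end)),
      n_evidence = nrow(comp),
      methods = paste(sort(methods), collapse = ","),
      populations = paste(sort(unique(comp$populations)), collapse = ","),
      stringsAsFactors = FALSE
    )
    if (ok) {
      row$evidence_ids <- paste(comp$.id, collapse = ",")
      keep_rows[[length(keep_rows) + 1]] <- row
    } else {
      discard_rows[[length(discard_rows) + 1]] <- row
    }
  }
  out <- if (length(keep_rows) > 0) do.call(rbind, keep_rows) else {
    empty$evidence_ids <- character(); empty
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- if (length(discard_rows) > 0) {
    do.call(rbind, discard_rows)
  } else NULL
  out
}

# 1-bp-overlap interval join: for each region row, the interval rows hitting it
interval_hits <- function(regions, intervals) {
  lapply(seq_len(nrow(regions)), function(i) {
    hit <- intervals$chrom == regions$chrom[i] &
      intervals$start <= regions$end[i] &
      intervals$end >= regions$start[i]
    w <- which(hit)
    w[order(intervals$start[w])]
  })
}

#' Attach overlapping genes to consensus regions
#'
#' A gene is attached iff its interval intersects the region span by at
#' least 1 bp; attached genes are sorted by start.
#'
#' @param regions data.frame from [merge_evidence()].
#' @param genes interval data.frame from [read_intervals()] (kind "gene").
#' @return `regions` with `genes` (comma-separated names) and `n_genes`.
#' @export
annotate_genes <- function(regions, genes) {
  hits <- interval_hits(regions, genes)
  regions$genes <- vapply(hits, function(w) {
    paste(genes$name[w], collapse = ",")
  }, "")
  regions$n_genes <- lengths(hits)
  regions
}

#' Attach overlapping QTLs and tally trait classes
#'
#' Same 1-bp intersection rule as genes. The tally table counts QTL hits per
#' (trait class, trait, region populations) with row and grand totals; QTLs
#' without a trait class are binned as "unclassified".
#'
#' @param regions data.frame from [merge_evidence()].
#' @param qtls interval data.frame from [read_intervals()] (dialect
#'   `qtl_gff`).
#' @return List with `regions` (plus `n_qtls`), `tally` (trait class, trait,
#'   populations, count) and `class_totals` (incl. a grand total row).
#' @export
annotate_qtls <- function(regions, qtls) {
  if (!"trait_class" %in% names(qtls)) qtls$trait_class <- NA_character_
  if (!"trait" %in% names(qtls)) qtls$trait <- qtls$name
  qtls$trait_class[is.na(qtls$trait_class) | qtls$trait_class == ""] <- "unclassified"
  hits <- interval_hits(regions, qtls)
  regions$n_qtls <- lengths(hits)
  rows <- list()
  for (i in seq_along(hits)) {
    w <- hits[[i]]
    if (length(w) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      trait_class = qtls$trait_class[w], trait = qtls$trait[w],
      populations = regions$populations[i], stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    tally <- data.frame(trait_class = character(), trait = character(),
                        populations = character(), count = integer(),
                        stringsAsFactors = FALSE)
    class_totals <- data.frame(trait_class = "Total", count = 0L,
                               stringsAsFactors = FALSE)
    return(list(regions = regions, tally = tally, class_totals = class_totals))
  }
  long <- do.call(rbind, rows)
  tally <- stats::aggregate(
    list(count = rep(1L, nrow(long))),
    by = long[, c("trait_class", "trait", "populations")], FUN = sum
  )
  class_totals <- stats::aggregate(list(count = tally$count),
                                   by = tally["trait_class"], FUN = sum)
  class_totals <- rbind(class_totals,
                        data.frame(trait_class = "Total",
                                   count = sum(tally$count)))
  list(regions = regions, tally = tally, class_totals = class_totals)
}
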