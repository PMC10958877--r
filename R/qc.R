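# Per-cell ATAC quality metrics: fraction of unique reads in reference
# regions (FRiDHS / FRiP), ENCODE-style TSS enrichment, Lander-Waterman
# library-complexity inversion (as in Picard), saturation, and the
# QC-based cell filter applied before matrix analysis.

#' Fraction of unique reads overlapping a region set (FRiDHS / FRiP)
#'
#' A fragment counts once if it overlaps any region by at least one base
#' pair. Region sets are expected to be merged (non-overlapping) and
#' blacklist-subtracted; see [load_regions()].
#'
#' @param fragments deduplicated fragments table.
#' @param regions `GRanges` of reference regions (e.g. DNase I
#'   hypersensitive sites), or a data.frame with `chrom`, `start`, `end`
#'   in BED convention.
#' @return data.table with `barcode`, `unique_reads`, `reads_in_regions`,
#'   `frir` (fraction in regions, in [0, 1]).
#' @export
fraction_reads_in_regions <- function(fragments, regions) {
  dt <- data.table::as.data.table(fragments)
  if (!inherits(regions, "GRanges")) {
    regions <- as.data.frame(regions)
    regions <- GenomicRanges::GRanges(
      regions$chrom,
      IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  }
  if (length(regions) == 0) {
    warning("empty region set: all fractions are zero")
    hit <- rep(FALSE, nrow(dt))
  } else {
    gr <- fragments_granges(dt)
    hit <- IRanges::overlapsAny(gr, regions)
  }
  dt$hit <- hit
  out <- dt[, list(unique_reads = .N, reads_in_regions = sum(hit)),
            by = "barcode"]
  out$frir <- out$reads_in_regions / out$unique_reads
  out[]
}

#' Load and normalize a region reference
#'
#' Reads a BED/narrowPeak file (first three columns used), merges
#' overlapping intervals, and subtracts blacklist regions at load time.
#'
#' @param path BED or narrowPeak path (plain text).
#' @param blacklist optional blacklist BED path or `GRanges`; overlapping
#'   region parts are removed.
#' @return Merged `GRanges`.
#' @export
load_regions <- function(path, blacklist = NULL) {
  bed <- data.table::fread(path, header = FALSE, select = 1:3,
                           col.names = c("chrom", "start", "end"))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    as.character(bed$chrom),
    IRanges::IRanges(start = bed$start + 1L, end = bed$end)))
  if (!is.null(blacklist)) {
    if (!inherits(blacklist, "GRanges")) {
      bl <- data.table::fread(blacklist, header = FALSE, select = 1:3,
                              col.names = c("chrom", "start", "end"))
      blacklist <- GenomicRanges::GRanges(
        as.character(bl$chrom),
        IRanges::IRanges(start = bl$start + 1L, end = bl$end))
    }
    gr <- GenomicRanges::setdiff(gr, blacklist)
  }
  gr
}

# per-base insertion depth over [-flank, +flank] around TSSs, strand
# oriented. Insertions are both fragment ends (start and end-1 in BED
# coordinates). Returns integer vector of length 2*flank + 1.
tss_profile <- function(fragments, tss, flank = 1000L) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tss)))
  ins <- data.table::data.table(
    chrom = rep(fragments$chrom, 2L),
    pos = c(fragments$start, fragments$end - 1L))
  depth <- integer(2L * flank + 1L)
  for (i in seq_len(nrow(tss))) {
    sel <- ins$chrom == tss$chrom[i]
    if (!any(sel)) next
    rel <- ins$pos[sel] - tss$pos[i]
    if (tss$strand[i] == "-") rel <- -rel
    rel <- rel[rel >= -flank & rel <= flank]
    if (length(rel))
      depth <- depth + tabulate(rel + flank + 1L, nbins = 2L * flank + 1L)
  }
  depth
}

# maximum sliding-window mean over background, from a depth profile
profile_enrichment <- function(depth, flank = 1000L, window = 100L) {
  bg <- mean(c(depth[seq_len(window)],
               depth[seq.int(length(depth) - window + 1L, length(depth))]))
  if (bg == 0) return(NA_real_)
  win_means <- stats::filter(depth, rep(1 / window, window), sides = 2)
  max(win_means, na.rm = TRUE) / bg
}

#' TSS enrichment score (ENCODE construction)
#'
#' Aggregates insertion events (both fragment ends, strand-oriented by the
#' TSS's strand) over a window of +/- `flank` bp around each TSS. The
#' background is the mean depth of the outermost `window` bp on each
#' flank, and the score is the maximum `window` bp sliding-window mean
#' divided by that background. Uniform coverage gives a score of 1. If the
#' background is zero the score is undefined (`NA`), never a division by
#' zero. In `per_cell` mode the same construction is restricted to each
#' barcode's fragments, and barcodes with fewer than `min_fragments`
#' insertion events in range get `NA`.
#'
#' @param fragments deduplicated fragments table.
#' @param tss data.frame with `chrom`, `pos` (0-based position of the TSS
#'   base), `strand` (`"+"`/`"-"`).
#' @param mode `"aggregate"` (one score) or `"per_cell"`.
#' @param flank half-window in bp (default 1000).
#' @param window sliding/background window width in bp (default 100).
#' @param min_fragments per-cell depth floor below which the score is
#'   undefined (default 100 insertions within range).
#' @return Aggregate mode: a single numeric score. Per-cell mode: a
#'   data.table with `barcode` and `tss_enrichment`.
#' @export
tss_enrichment <- function(fragments, tss, mode = c("aggregate", "per_cell"),
                           flank = 1000L, window = 100L,
                           min_fragments = 100L) {
  mode <- match.arg(mode)
  dt <- data.table::as.data.table(fragments)
  tss <- as.data.frame(tss)
  if (mode == "aggregate") {
    depth <- tss_profile(dt, tss, flank)
    return(profile_enrichment(depth, flank, window))
  }
  out <- dt[, {
    depth <- tss_profile(.SD, tss, flank)
    score <- if (sum(depth) < min_fragments) NA_real_
             else profile_enrichment(depth, flank, window)
    list(tss_enrichment = score)
  }, by = "barcode"]
  out[]
}

#' Estimate library complexity (Lander-Waterman inversion, as in Picard)
#'
#' Solves `unique = C (1 - exp(-total / C))` for the library size `C` by
#' bisection to a relative tolerance of 1e-9. When `unique == total` (no
#' duplicates observed) the estimate is unbounded and `Inf` is returned.
#'
#' @param total total read (pair) count, vectorised.
#' @param unique unique read (pair) count, `0 < unique <= total`.
#' @return Numeric vector of estimated library sizes (>= `unique`).
#' @examples
#' estimate_complexity(20000, 12642)
#' @export
estimate_complexity <- function(total, unique) {
  stopifnot(length(total) == length(unique))
  if (any(unique > total)) stop("unique count exceeds total count")
  if (any(unique <= 0) || any(total <= 0)) stop("counts must be positive")
  mapply(function(t, u) {
    if (u == t) return(Inf)
    f <- function(C) C * (1 - exp(-t / C)) - u
    lo <- u
    hi <- u
    while (f(hi) < 0) hi <- hi * 2
    # bisection to relative tolerance 1e-9
    while ((hi - lo) / hi > 1e-9) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, total, unique)
}

#' Sequencing saturation
#'
#' `1 - unique/total`: the fraction of reads that were duplicates.
#' @param total,unique read counts as in [estimate_complexity()].
#' @return Numeric vector in [0, 1].
#' @export
saturation <- function(total, unique) {
  stopifnot(all(unique <= total), all(total > 0))
  1 - unique / total
}

#' Apply matrix-stage QC filters to per-cell records
#'
#' Removes cells that violate any of: region-overlapping reads above
#' `max_region_reads` (over-depth outliers), fraction-in-regions below
#' `min_frir`, or TSS enrichment below `min_tss`. Thresholds follow the
#' defaults used at the matrix stage (20,000 / 0.2 / 2); comparisons are
#' strict, so a cell at exactly a boundary value is kept. Cells with an
#' undefined (NA) TSS score are removed.
#'
#' @param qc data.frame with `barcode`, `reads_in_regions`, `frir`,
#'   `tss_enrichment`.
#' @param max_region_reads,min_frir,min_tss thresholds (defaults 20000,
#'   0.2, 2).
#' @return Character vector of kept barcodes.
#' @export
apply_qc_filters <- function(qc, max_region_reads = 20000, min_frir = 0.2,
                             min_tss = 2) {
  qc <- as.data.frame(qc)
  stopifnot(all(c("barcode", "reads_in_regions", "frir", "tss_enrichment")
                %in% names(qc)))
  keep <- qc$reads_in_regions <= max_region_reads &
    qc$frir >= min_frir &
    !is.na(qc$tss_enrichment) & qc$tss_enrichment >= min_tss
  qc$barcode[keep]
}
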