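# Fragment-level processing: alignment filtering on a hybrid two-species
# genome, per-pair deduplication, species attribution, and the plain-text
# fragments file (chrom, start, end, barcode, dup_count; BED conventions,
# 0-based half-open). No Tn5 +4/-5 insertion shift is applied anywhere in
# this module; coordinates are the outermost mate coordinates of the pair.

#' Filter aligned read pairs and extract candidate fragments
#'
#' Keeps alignments that are confidently mapped (MAPQ >= `mapq_min`), in a
#' proper pair with both mates mapped (the `-f3 -F12` flag semantics), and
#' on an assembled nuclear contig (mitochondrial and unplaced/alt contigs
#' excluded by name pattern). The combined cell barcode is taken from the
#' read-name suffix after the last `:` (or from a BAM tag). Each retained
#' pair yields one candidate fragment spanning the outermost mate
#' coordinates, reported 0-based half-open.
#'
#' @param bam path to a coordinate- or name-sorted BAM with mate
#'   information.
#' @param barcode_from `"name"` (default: suffix after the last `:` of the
#'   read name) or a two-letter BAM tag (e.g. `"CB"`).
#' @param mapq_min minimum MAPQ (default 10).
#' @param exclude_regex contig-name pattern treated as non-nuclear or
#'   unassembled (default matches chrM/MT and `_random`/`_alt`/`chrUn`).
#' @param max_fragment maximum fragment length in bp (default 2000, the
#'   alignment insert-size limit).
#' @return List with `fragments` (data.table: `chrom`, `start`, `end`,
#'   `barcode`, `read_id`) and `report` (named counts; `kept` plus all
#'   dropped categories sums to the number of input records).
#' @export
filter_alignments <- function(bam, barcode_from = "name", mapq_min = 10L,
                              exclude_regex = "chrM|\\bMT\\b|_random|_alt|chrUn",
                              max_fragment = 2000L) {
  what <- c("qname", "flag", "rname", "pos", "mapq", "isize")
  tags <- if (barcode_from != "name") barcode_from else character()
  param <- Rsamtools::ScanBamParam(what = what, tag = tags)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_records <- length(res$qname)

  flag <- res$flag
  proper <- bitwAnd(flag, 1L) > 0L & bitwAnd(flag, 2L) > 0L &
    bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 8L) == 0L
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  mapq_ok <- !is.na(res$mapq) & res$mapq >= mapq_min
  nuclear <- !is.na(res$rname) & !grepl(exclude_regex, as.character(res$rname))

  barcode <- if (barcode_from == "name") {
    sub("^.*:", "", res$qname)
  } else {
    bc <- res$tag[[barcode_from]]
    if (is.null(bc)) rep(NA_character_, n_records) else bc
  }
  has_bc <- !is.na(barcode) & nzchar(barcode) & barcode != res$qname

  keep <- proper & primary & mapq_ok & nuclear & has_bc
  report <- c(
    input = n_records,
    kept = sum(keep),
    dropped_flag = sum(!(proper & primary)),
    dropped_mapq = sum(proper & primary & !mapq_ok),
    dropped_contig = sum(proper & primary & mapq_ok & !nuclear),
    dropped_no_barcode = sum(proper & primary & mapq_ok & nuclear & !has_bc)
  )

  # one fragment per pair: use the leftmost mate (isize > 0)
  left <- keep & !is.na(res$isize) & res$isize > 0L
  start0 <- res$pos[left] - 1L                       # BED 0-based
  end0 <- start0 + res$isize[left]
  frag_ok <- (end0 - start0) <= max_fragment & (end0 - start0) > 0L
  fragments <- data.table::data.table(
    chrom = as.character(res$rname)[left][frag_ok],
    start = start0[frag_ok],
    end = end0[frag_ok],
    barcode = barcode[left][frag_ok],
    read_id = res$qname[left][frag_ok]
  )
  report["dropped_fragment_length"] <- sum(!frag_ok)
  list(fragments = fragments, report = report)
}

#' Deduplicate fragments on (barcode, chrom, start, end)
#'
#' PCR/optical duplicates are fragments with the same combined barcode and
#' identical start and end coordinates. One record is kept per key with
#' `dup_count` equal to the multiplicity; when a `read_id` column is
#' present, the surviving representative is chosen uniformly at random
#' under `seed`. The choice of seed affects only which representative's
#' auxiliary fields survive, never counts or coordinates.
#'
#' @param fragments data.frame/data.table with `chrom`, `start`, `end`,
#'   `barcode` and optionally `read_id`.
#' @param seed RNG seed for representative choice (default 1).
#' @return data.table sorted by (chrom, start, end, barcode) with one row
#'   per key and a `dup_count` column; `sum(dup_count)` equals the input
#'   row count.
#' @export
deduplicate_fragments <- function(fragments, seed = 1L) {
  dt <- data.table::as.data.table(fragments)
  stopifnot(all(c("chrom", "start", "end", "barcode") %in% names(dt)))
  set.seed(as.integer(seed))
  has_id <- "read_id" %in% names(dt)
  # pre-permute so that the first row per key is a uniform random pick
  dt <- dt[sample.int(nrow(dt))]
  dedup <- if (has_id) {
    dt[, list(dup_count = .N, read_id = read_id[1L]),
       by = c("barcode", "chrom", "start", "end")]
  } else {
    dt[, list(dup_count = .N), by = c("barcode", "chrom", "start", "end")]
  }
  data.table::setcolorder(dedup, c("chrom", "start", "end", "barcode", "dup_count"))
  data.table::setorder(dedup, chrom, start, end, barcode)
  dedup[]
}

#' Partition each barcode's unique fragments by species
#'
#' Contig names on the hybrid genome must carry a species prefix
#' (e.g. `hg_chr1`, `mm_chr1`); the prefix is everything before the first
#' `sep`. Returns the per-barcode unique-fragment counts for each species.
#'
#' @param fragments deduplicated fragments (one row per unique fragment).
#' @param sep species/contig separator in contig names (default `"_"`).
#' @return data.table with one row per barcode: `barcode`, one count column
#'   per species prefix, and `total_unique` (the row sum).
#' @export
count_species <- function(fragments, sep = "_") {
  dt <- data.table::as.data.table(fragments)
  bad <- !grepl(sep, dt$chrom, fixed = TRUE)
  if (any(bad))
    stop("contigs without a species prefix: ",
         paste(unique(dt$chrom[bad]), collapse = ", "))
  dt$species <- sub(paste0(sep, ".*$"), "", dt$chrom)
  counts <- dt[, list(n = .N), by = c("barcode", "species")]
  wide <- data.table::dcast(counts, barcode ~ species, value.var = "n", fill = 0L)
  spcols <- setdiff(names(wide), "barcode")
  wide$total_unique <- rowSums(wide[, spcols, with = FALSE])
  wide[]
}

#' Write a fragments file
#'
#' Plain-text BED3+2 (`chrom`, `start`, `end`, `barcode`, `dup_count`),
#' sorted by (chrom, start, end, barcode), no header. Round-trips
#' losslessly through [read_fragments()].
#'
#' @param fragments data.table from [deduplicate_fragments()].
#' @param path output path (`.gz` suffix enables gzip).
#' @export
write_fragments <- function(fragments, path) {
  dt <- data.table::as.data.table(fragments)[,
    c("chrom", "start", "end", "barcode", "dup_count"), with = FALSE]
  data.table::setorder(dt, chrom, start, end, barcode)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a fragments file written by [write_fragments()]
#' @param path fragments BED path.
#' @return data.table with `chrom`, `start`, `end`, `barcode`, `dup_count`.
#' @export
read_fragments <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "barcode",
                                        "dup_count"))
  dt$chrom <- as.character(dt$chrom)
  dt$barcode <- as.character(dt$barcode)
  dt[]
}

# GRanges view of a fragments table (1-based closed internally, as GRanges
# requires; BED half-open [start, end) maps to start+1 .. end).
fragments_granges <- function(fragments) {
  GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = fragments$start + 1L,
                              end = fragments$end),
    barcode = fragments$barcode
  )
}
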