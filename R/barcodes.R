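# Three-level barcode handling: Tn5 pre-index (8 bp, read 2 prefix),
# GEM bead barcode (16 bp, index read 2), and i7 sample index (8 bp,
# index read 1). Reads carry barcodes at fixed positions, so the default
# error model is substitution-only (Hamming); a Levenshtein mode is
# available for completeness.

#: canonical 19 bp Tn5 mosaic-end spacer between the Tn5 barcode and the
#: genomic sequence in read 2.
MOSAIC_END <- "AGATGTGTATAAGAGACAG"

#' Barcode whitelist
#'
#' A validated set of fixed-length DNA barcodes for one barcode level.
#'
#' @param entries character vector of uppercase DNA barcodes, optionally
#'   named (names are treated as well identifiers, e.g. plate wells
#'   `A1..H12` for the Tn5 level).
#' @param level one of `"tn5"`, `"gem"`, `"i7"`.
#' @return Object of class `barcode_whitelist` (named character vector with
#'   `level` and `width` attributes).
#' @export
barcode_whitelist <- function(entries, level = c("tn5", "gem", "i7")) {
  level <- match.arg(level)
  entries <- stats::setNames(as.character(entries), names(entries))
  if (length(entries) == 0) stop("empty whitelist")
  w <- unique(nchar(entries))
  if (length(w) != 1) stop("whitelist entries must all have the same length")
  if (anyDuplicated(entries)) stop("whitelist entries must be unique")
  if (!all(grepl("^[ACGT]+$", entries)))
    stop("whitelist entries must be uppercase A/C/G/T")
  structure(entries, level = level, width = w, class = "barcode_whitelist")
}

#' Read a one-barcode-per-line whitelist file
#'
#' Lines may be `barcode` or `well<TAB>barcode`; in the latter case the
#' well identifiers become the names of the whitelist.
#'
#' @param path text file path.
#' @param level barcode level, see [barcode_whitelist()].
#' @return A [barcode_whitelist()].
#' @export
read_whitelist <- function(path, level = c("tn5", "gem", "i7")) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(parts) == 2L)) {
    bc <- vapply(parts, `[[`, character(1), 2L)
    names(bc) <- vapply(parts, `[[`, character(1), 1L)
  } else {
    bc <- vapply(parts, `[[`, character(1), 1L)
  }
  barcode_whitelist(bc, level = level)
}

#' Extract the Tn5 barcode and genomic portion of read 2
#'
#' Read 2 begins with the 8 bp Tn5 pre-index barcode followed by the 19 bp
#' mosaic end; the remaining bases are genomic. The first 27 bp are removed
#' and the barcode retained. Reads of 27 bp or shorter carry no genomic
#' sequence and are flagged `"too_short"` rather than silently truncated.
#'
#' @param read2_sequence character vector of read-2 sequences.
#' @param quality optional character vector of quality strings, sliced
#'   identically.
#' @param barcode_len,spacer_len barcode and mosaic-end lengths
#'   (defaults 8 and 19).
#' @return data.frame with columns `tn5_raw`, `genomic`, `status`
#'   (`"ok"`/`"too_short"`) and, when `quality` is given, `genomic_qual`.
#' @examples
#' extract_tn5(paste0("AAAAAAAA", "AGATGTGTATAAGAGACAG", "ACGT"))
#' @export
extract_tn5 <- function(read2_sequence, quality = NULL,
                        barcode_len = 8L, spacer_len = 19L) {
  trim <- barcode_len + spacer_len
  len <- nchar(read2_sequence)
  ok <- len > trim
  out <- data.frame(
    tn5_raw = substr(read2_sequence, 1L, barcode_len),
    genomic = ifelse(ok, substr(read2_sequence, trim + 1L, len), ""),
    status = ifelse(ok, "ok", "too_short"),
    stringsAsFactors = FALSE
  )
  if (!is.null(quality)) {
    stopifnot(length(quality) == length(read2_sequence))
    out$genomic_qual <- ifelse(ok, substr(quality, trim + 1L, nchar(quality)), "")
  }
  out
}

# pairwise Hamming distances between equal-length barcode vectors;
# returns length(x) x length(y) integer matrix.
hamming_matrix <- function(x, y) {
  w <- unique(c(nchar(x), nchar(y)))
  stopifnot(length(w) == 1)
  xm <- matrix(unlist(strsplit(x, "", fixed = TRUE)), ncol = w, byrow = TRUE)
  ym <- matrix(unlist(strsplit(y, "", fixed = TRUE)), ncol = w, byrow = TRUE)
  d <- matrix(0L, length(x), length(y))
  for (j in seq_len(w))
    d <- d + (outer(xm[, j], ym[, j], "!=") * 1L)
  d
}

#' Error-correct observed barcodes against a whitelist
#'
#' Each observed barcode is assigned to a whitelist entry if exactly one
#' entry lies within `max_dist` substitutions. Observations matching more
#' than one entry within `max_dist` are discarded as ambiguous (ties are
#' never broken), and observations matching none are uncorrectable.
#' Length-mismatched observations are uncorrectable.
#'
#' @param observed character vector of observed barcodes.
#' @param whitelist a [barcode_whitelist()] (or plain character vector).
#' @param max_dist maximum correction distance (default 2).
#' @param method `"hamming"` (default; substitutions at fixed positions) or
#'   `"levenshtein"` (indel-aware, via [utils::adist()]).
#' @return data.frame with columns `observed`, `corrected` (NA unless ok),
#'   `distance` (NA unless ok) and `status`
#'   (`"ok"`/`"ambiguous"`/`"uncorrectable"`).
#' @examples
#' wl <- barcode_whitelist(c("AAAAAAAA", "CCCCCCCC"), "tn5")
#' correct_barcode("AAAAAAAT", wl)
#' @export
correct_barcode <- function(observed, whitelist, max_dist = 2L,
                            method = c("hamming", "levenshtein")) {
  method <- match.arg(method)
  wl <- as.character(whitelist)
  w <- unique(nchar(wl))
  stopifnot(length(w) == 1)
  n <- length(observed)
  corrected <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  status <- rep("uncorrectable", n)

  lenok <- !is.na(observed) & nchar(observed) == w &
    grepl("^[ACGTN]+$", observed)
  if (any(lenok)) {
    obs <- observed[lenok]
    # correct each distinct observation once
    uo <- unique(obs)
    d <- if (method == "hamming") hamming_matrix(uo, wl)
         else utils::adist(uo, wl)
    within <- d <= max_dist
    nhit <- rowSums(within)
    st <- ifelse(nhit == 1L, "ok",
                 ifelse(nhit >= 2L, "ambiguous", "uncorrectable"))
    hit <- ifelse(nhit == 1L, max.col(within, ties.method = "first"), NA_integer_)
    co <- ifelse(nhit == 1L, wl[hit], NA_character_)
    di <- ifelse(nhit == 1L, d[cbind(seq_along(uo), ifelse(is.na(hit), 1L, hit))],
                 NA_integer_)
    idx <- match(obs, uo)
    corrected[lenok] <- co[idx]
    distance[lenok] <- di[idx]
    status[lenok] <- st[idx]
  }
  data.frame(observed = observed, corrected = corrected,
             distance = distance, status = status, stringsAsFactors = FALSE)
}

#' Combine the three corrected barcode levels
#'
#' The combined cell barcode is the plain concatenation
#' i7 | GEM | Tn5, invertible given the fixed level widths.
#'
#' @param i7,gem,tn5 corrected barcode vectors (no NAs allowed).
#' @return Character vector of combined barcodes.
#' @export
build_combined_barcode <- function(i7, gem, tn5) {
  if (anyNA(i7) || anyNA(gem) || anyNA(tn5))
    stop("all three barcode components must be non-missing")
  paste0(i7, gem, tn5)
}

#' Split a combined barcode back into its components
#'
#' @param combined combined barcode vector from [build_combined_barcode()].
#' @param i7_len,gem_len,tn5_len level widths (defaults 8, 16, 8).
#' @return data.frame with columns `i7`, `gem`, `tn5`.
#' @export
split_combined_barcode <- function(combined, i7_len = 8L, gem_len = 16L,
                                   tn5_len = 8L) {
  stopifnot(all(nchar(combined) == i7_len + gem_len + tn5_len))
  data.frame(
    i7 = substr(combined, 1L, i7_len),
    gem = substr(combined, i7_len + 1L, i7_len + gem_len),
    tn5 = substr(combined, i7_len + gem_len + 1L, i7_len + gem_len + tn5_len),
    stringsAsFactors = FALSE
  )
}

#' Read a sample sheet
#'
#' TSV with columns `sample`, `i7` (sample index sequence) and `tn5_wells`
#' (comma-separated Tn5 well identifiers referring to whitelist names).
#'
#' @param path TSV path.
#' @return data.frame as stored.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "i7", "tn5_wells") %in% names(ss)))
  ss
}

# expand a sample sheet into one row per (i7, tn5 well); validates that
# well assignments are disjoint across samples.
expand_sample_sheet <- function(sample_sheet, tn5_whitelist) {
  wells <- strsplit(sample_sheet$tn5_wells, ",", fixed = TRUE)
  map <- data.frame(
    sample = rep(sample_sheet$sample, lengths(wells)),
    i7 = rep(sample_sheet$i7, lengths(wells)),
    well = trimws(unlist(wells)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(map[, c("i7", "well")]))
    stop("overlapping well assignments: each (i7, Tn5 well) pair must map ",
         "to exactly one sample")
  missing <- setdiff(map$well, names(tn5_whitelist))
  if (length(missing))
    stop("sample sheet refers to unknown Tn5 wells: ",
         paste(missing, collapse = ", "))
  map$tn5 <- as.character(tn5_whitelist)[match(map$well, names(tn5_whitelist))]
  map
}

# minimal FASTQ reader: returns data.frame(id, seq, qual). The id is the
# first whitespace-delimited token of the header line.
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  data.frame(id = ids,
             seq = lines[seq(2, length(lines), by = 4L)],
             qual = lines[seq(4, length(lines), by = 4L)],
             stringsAsFactors = FALSE)
}

write_fastq <- function(df, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(df)))
  n <- nrow(df)
  lines <- character(4L * n)
  lines[seq(1, length.out = n, by = 4L)] <- paste0("@", df$id)
  lines[seq(2, length.out = n, by = 4L)] <- df$seq
  lines[seq(3, length.out = n, by = 4L)] <- "+"
  lines[seq(4, length.out = n, by = 4L)] <- df$qual
  writeLines(lines, path)
  invisible(path)
}

#' Demultiplex a sequencing run by i7 sample index and Tn5 well
#'
#' Reads the four FASTQ streams of a run (R1 genomic, R2 = Tn5 barcode +
#' mosaic end + genomic, I1 = i7 sample index, I2 = GEM barcode), corrects
#' all three barcode levels against their whitelists, assigns each fully
#' corrected read to a sample via the (i7, Tn5 well) sample sheet, and
#' writes per-sample R1/R2 FASTQs with the combined barcode appended to the
#' read name after a `:` delimiter.
#'
#' @param r1,r2,i1,i2 FASTQ paths for the four streams.
#' @param whitelists named list with elements `tn5`, `gem`, `i7`, each a
#'   [barcode_whitelist()].
#' @param sample_sheet data.frame as returned by [read_sample_sheet()].
#' @param out_dir output directory for per-sample FASTQs (created); `NULL`
#'   suppresses file output.
#' @param max_dist correction distance (default 2 for all levels).
#' @return List with `assignments` (data.frame: `id`, `sample`, `combined`,
#'   `status`), `report` (per-level and overall ok/ambiguous/uncorrectable
#'   counts; categories sum to the input read count) and `files`.
#' @export
demultiplex <- function(r1, r2, i1, i2, whitelists, sample_sheet,
                        out_dir = NULL, max_dist = 2L) {
  stopifnot(all(c("tn5", "gem", "i7") %in% names(whitelists)))
  map <- expand_sample_sheet(sample_sheet, whitelists$tn5)

  fq1 <- read_fastq(r1); fq2 <- read_fastq(r2)
  fqi1 <- read_fastq(i1); fqi2 <- read_fastq(i2)
  n <- nrow(fq2)
  stopifnot(nrow(fq1) == n, nrow(fqi1) == n, nrow(fqi2) == n,
            identical(fq1$id, fq2$id))

  ext <- extract_tn5(fq2$seq, fq2$qual)
  tn5c <- correct_barcode(ext$tn5_raw, whitelists$tn5, max_dist)
  gemc <- correct_barcode(fqi2$seq, whitelists$gem, max_dist)
  i7c <- correct_barcode(fqi1$seq, whitelists$i7, max_dist)
  tn5c$status[ext$status != "ok"] <- "uncorrectable"
  tn5c$corrected[ext$status != "ok"] <- NA_character_

  all_ok <- tn5c$status == "ok" & gemc$status == "ok" & i7c$status == "ok"
  # a read is ambiguous if any level is ambiguous (and none uncorrectable
  # takes precedence reporting-wise: uncorrectable wins)
  any_unc <- tn5c$status == "uncorrectable" | gemc$status == "uncorrectable" |
    i7c$status == "uncorrectable"
  overall <- ifelse(all_ok, "ok", ifelse(any_unc, "uncorrectable", "ambiguous"))

  combined <- rep(NA_character_, n)
  combined[all_ok] <- build_combined_barcode(
    i7c$corrected[all_ok], gemc$corrected[all_ok], tn5c$corrected[all_ok])

  # sample assignment by (i7, tn5) pair
  key <- paste(i7c$corrected, tn5c$corrected)
  mkey <- paste(map$i7, map$tn5)
  sample <- rep(NA_character_, n)
  sample[all_ok] <- map$sample[match(key[all_ok], mkey)]
  overall[all_ok & is.na(sample)] <- "unassigned"

  tab <- function(st) c(ok = sum(st == "ok"), ambiguous = sum(st == "ambiguous"),
                        uncorrectable = sum(st == "uncorrectable"))
  report <- list(
    n_reads = n,
    tn5 = tab(tn5c$status), gem = tab(gemc$status), i7 = tab(i7c$status),
    overall = c(ok = sum(overall == "ok"),
                ambiguous = sum(overall == "ambiguous"),
                uncorrectable = sum(overall == "uncorrectable"),
                unassigned = sum(overall == "unassigned"))
  )

  files <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    keep <- overall == "ok"
    for (s in unique(map$sample)) {
      sel <- keep & !is.na(sample) & sample == s
      if (!any(sel)) next
      ids <- paste0(fq1$id[sel], ":", combined[sel])
      f1 <- file.path(out_dir, paste0(s, "_R1.fastq"))
      f2 <- file.path(out_dir, paste0(s, "_R2.fastq"))
      write_fastq(data.frame(id = ids, seq = fq1$seq[sel],
                             qual = fq1$qual[sel]), f1)
      write_fastq(data.frame(id = ids, seq = ext$genomic[sel],
                             qual = ext$genomic_qual[sel]), f2)
      files[[s]] <- c(R1 = f1, R2 = f2)
    }
  }

  list(assignments = data.frame(id = fq1$id, sample = sample,
                                combined = combined, status = overall,
                                stringsAsFactors = FALSE),
       report = report, files = files)
}
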