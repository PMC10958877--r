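# SNV-driven motif gain/loss analysis: VCF filtering with replicate
# genotype concordance, hotspot assignment, Jaccard comparison against
# strain SNP sets, construction of alternative (variant-substituted) peak
# sequences, log-odds PWM scanning with an exact p-value score threshold,
# and the functional-motif association test against differential
# accessibility.

#' Filter SNVs from a multi-sample VCF
#'
#' Keeps biallelic single-nucleotide variants with Phred-scaled quality
#' `QUAL >= min_qual`, total read depth across replicates
#' `sum(DP) >= min_dp_sum`, and a concordant genotype: with three
#' replicates the same genotype call in at least two of three; with any
#' other replicate count, a strict majority (with a warning). Missing
#' genotypes never count toward concordance.
#'
#' @param vcf path to a VCF (plain text or bgzipped) with per-replicate
#'   genotypes (FORMAT fields `GT` and `DP`).
#' @param min_qual minimum QUAL (default 20).
#' @param min_dp_sum minimum summed DP across replicates (default 10).
#' @return data.frame with `chrom`, `pos` (1-based), `ref`, `alt`, `qual`,
#'   `dp_sum`, `genotype` (the modal call) and one `gt_*` column per
#'   replicate; attribute `n_dropped_non_snv` counts non-SNV records.
#' @export
filter_snvs <- function(vcf, min_qual = 20, min_dp_sum = 10) {
  v <- VariantAnnotation::readVcf(vcf)
  ref <- as.character(VariantAnnotation::ref(v))
  altl <- VariantAnnotation::alt(v)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(v))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  is_snv <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) &
    nchar(alt1) == 1L & alt1 != ref
  n_non_snv <- sum(!is_snv)

  gt <- VariantAnnotation::geno(v)$GT
  dp <- VariantAnnotation::geno(v)$DP
  if (is.null(gt) || is.null(dp)) stop("VCF must carry GT and DP per sample")
  n_rep <- ncol(gt)
  need <- if (n_rep == 3L) 2L else {
    warning("replicate count ", n_rep,
            " != 3; genotype concordance generalized to strict majority")
    floor(n_rep / 2) + 1L
  }
  modal <- apply(gt, 1L, function(g) {
    g <- g[!is.na(g) & !(g %in% c("./.", "."))]
    if (!length(g)) return(c(NA_character_, "0"))
    tab <- sort(table(g), decreasing = TRUE)
    c(names(tab)[1], as.character(tab[1]))
  })
  concord <- as.integer(modal[2L, ]) >= need & !is.na(modal[1L, ])
  dp_sum <- rowSums(dp, na.rm = TRUE)
  qual <- VariantAnnotation::qual(v)

  keep <- is_snv & !is.na(qual) & qual >= min_qual &
    dp_sum >= min_dp_sum & concord
  rr <- SummarizedExperiment::rowRanges(v)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = ref[keep], alt = alt1[keep],
    qual = qual[keep], dp_sum = dp_sum[keep],
    genotype = modal[1L, keep],
    stringsAsFactors = FALSE)
  for (j in seq_len(n_rep))
    out[[paste0("gt_", colnames(gt)[j])]] <- gt[keep, j]
  attr(out, "n_dropped_non_snv") <- n_non_snv
  out
}

#' Default SNV hotspot intervals
#'
#' The two mouse (mm10) intervals of residual donor-strain genome flanking
#' the targeted locus in the knockout line: chr8:68,000,000-93,000,000 and
#' chr19:16,500,000-26,500,000 (1-based, closed).
#' @return data.frame with `name`, `chrom`, `start`, `end`.
#' @export
default_snv_hotspots <- function() {
  data.frame(name = c("chr8_hotspot", "chr19_hotspot"),
             chrom = c("chr8", "chr19"),
             start = c(68000000, 16500000),
             end = c(93000000, 26500000),
             stringsAsFactors = FALSE)
}

#' Assign SNVs to hotspot intervals
#'
#' Intervals are interpreted 1-based closed (as printed for genomic
#' coordinates), so both boundary positions are inside.
#'
#' @param snvs data.frame with `chrom`, `pos` (1-based).
#' @param hotspots data.frame with `name`, `chrom`, `start`, `end`
#'   (default [default_snv_hotspots()]).
#' @return `snvs` with an added `hotspot` column (`name` or `"outside"`).
#' @export
assign_hotspots <- function(snvs, hotspots = default_snv_hotspots()) {
  snvs <- as.data.frame(snvs)
  hotspot <- rep("outside", nrow(snvs))
  for (i in seq_len(nrow(hotspots))) {
    inside <- snvs$chrom == hotspots$chrom[i] &
      snvs$pos >= hotspots$start[i] & snvs$pos <= hotspots$end[i]
    hotspot[inside] <- hotspots$name[i]
  }
  snvs$hotspot <- hotspot
  snvs
}

#' Jaccard similarity of two SNV sets
#'
#' Sets are keyed by (chrom, pos, ref, alt). Both sets empty gives 0 with
#' a warning.
#'
#' @param a,b data.frames with `chrom`, `pos`, `ref`, `alt`.
#' @return Jaccard index in [0, 1].
#' @export
jaccard_snv_sets <- function(a, b) {
  key <- function(x) unique(paste(x$chrom, x$pos, x$ref, x$alt, sep = ":"))
  ka <- key(a); kb <- key(b)
  u <- length(union(ka, kb))
  if (u == 0) {
    warning("both SNV sets empty; Jaccard defined as 0")
    return(0)
  }
  length(intersect(ka, kb)) / u
}

#' Substitute SNV alleles into peak sequences
#'
#' Peak sequences must be named `chrom:start-end` (1-based, closed) so
#' that VCF positions can be mapped into them. Each SNV falling inside a
#' peak replaces the reference base; a mismatch between the recorded
#' reference allele and the sequence raises an error naming the position
#' (this guards against coordinate-convention bugs). Multiple SNVs per
#' peak are applied jointly; sequence length is preserved.
#'
#' @param sequences `DNAStringSet` (or named character vector) of peak
#'   sequences with `chrom:start-end` names.
#' @param snvs data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return `DNAStringSet` of alternative sequences, same names and widths.
#' @export
apply_snvs_to_sequence <- function(sequences, snvs) {
  seqs <- as.character(Biostrings::DNAStringSet(sequences))
  coords <- parse_peak_names(names(seqs))
  for (k in seq_len(nrow(snvs))) {
    inpeak <- which(coords$chrom == snvs$chrom[k] &
                    snvs$pos[k] >= coords$start & snvs$pos[k] <= coords$end)
    for (i in inpeak) {
      off <- snvs$pos[k] - coords$start[i] + 1L
      have <- substr(seqs[i], off, off)
      if (have != snvs$ref[k])
        stop(sprintf(
          "reference mismatch at %s:%d in peak %s: sequence has %s, VCF ref is %s",
          snvs$chrom[k], snvs$pos[k], names(seqs)[i], have, snvs$ref[k]))
      substr(seqs[i], off, off) <- snvs$alt[k]
    }
  }
  Biostrings::DNAStringSet(seqs)
}

# "chrom:start-end" (1-based closed) -> data.frame(chrom, start, end)
parse_peak_names <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  if (any(lengths(m) != 4L))
    stop("peak names must have the form chrom:start-end")
  data.frame(chrom = vapply(m, `[[`, character(1), 2L),
             start = as.integer(vapply(m, `[[`, character(1), 3L)),
             end = as.integer(vapply(m, `[[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the JASPAR 2020 flat format: a `>ID name` header followed by
#' four lines `A [ counts ]`, `C [...]`, `G [...]`, `T [...]`.
#'
#' @param path JASPAR-format text file.
#' @return Named list of 4 x width count matrices (rows A, C, G, T).
#' @export
read_jaspar_pfms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  pfms <- list()
  for (h in heads) {
    id <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]][1]
    rows <- lines[h + 1:4]
    counts <- lapply(rows, function(l) {
      s <- sub("^\\s*[ACGT]", "", l)
      as.numeric(regmatches(s, gregexpr("[0-9.]+", s))[[1]])
    })
    mat <- do.call(rbind, counts)
    rownames(mat) <- c("A", "C", "G", "T")
    pfms[[id]] <- mat
  }
  pfms
}

#' Write PFMs in JASPAR text format
#' @param pfms named list of 4 x width count matrices (rows A, C, G, T).
#' @param path output path.
#' @export
write_jaspar_pfms <- function(pfms, path) {
  lines <- unlist(lapply(names(pfms), function(id) {
    m <- pfms[[id]]
    c(paste0(">", id, " ", id),
      vapply(c("A", "C", "G", "T"), function(b)
        sprintf("%s  [ %s ]", b, paste(format(m[b, ]), collapse = " ")),
        character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

# PFM -> log2-odds PWM against a 0-order background with a MOODS-style
# pseudocount: p_bj = (c_bj + pseudocount * bg_b) / (colsum_j + pseudocount)
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(nrow(pfm) == 4)
  background <- background / sum(background)
  probs <- sweep(pfm, 2L, colSums(pfm) + pseudocount, function(c, s) c / s) +
    outer(background * pseudocount, colSums(pfm) + pseudocount, "/")
  log2(probs / background)
}

# exact score threshold at tail probability <= p_value under the 0-order
# background, by dynamic programming over the discretized score
# distribution (granularity `gran` bits).
pwm_threshold <- function(pwm, background = rep(0.25, 4), p_value = 1e-4,
                          gran = 0.01) {
  background <- background / sum(background)
  q <- round(pwm / gran)                     # integer-quantized scores
  offset <- apply(q, 2L, min)
  dist <- c(1)                               # prob by (score - cumulative min)
  for (j in seq_len(ncol(q))) {
    shifted <- q[, j] - offset[j]
    width <- max(shifted)
    new <- numeric(length(dist) + width)
    for (b in 1:4) {
      s <- shifted[b]
      new[seq_along(dist) + s] <- new[seq_along(dist) + s] + background[b] * dist
    }
    dist <- new
  }
  tail_p <- rev(cumsum(rev(dist)))
  scores <- (seq_along(dist) - 1L + sum(offset)) * gran
  # epsilon absorbs float noise in the accumulated tail probabilities;
  # only realizable scores (positive mass) are threshold candidates
  ok <- which(tail_p <= p_value + 1e-12 & dist > 0)
  if (!length(ok)) return(Inf)               # no score is significant
  scores[ok[1]]
}

# scan one integer-encoded sequence (A/C/G/T -> 1..4, NA for ambiguity)
# with a PWM; returns the number of windows with score >= threshold.
# Forward strand only; windows touching an ambiguous base never count.
scan_one_strand <- function(enc, pwm, threshold) {
  w <- ncol(pwm)
  L <- length(enc)
  if (L < w) return(0L)
  idx <- outer(0:(L - w), seq_len(w), "+")   # (L-w+1) x w positions
  base <- matrix(enc[idx], nrow = nrow(idx))
  valid <- if (anyNA(base)) rowSums(is.na(base)) == 0 else rep(TRUE, nrow(base))
  base[is.na(base)] <- 1L
  sc <- matrix(pwm[cbind(as.vector(base), as.vector(col(base)))],
               nrow = nrow(base))
  scores <- rowSums(sc)
  sum(valid & scores >= threshold - 1e-9)
}

encode_dna <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]],
                                c("A", "C", "G", "T"))

#' Scan sequences with PWMs at an exact p-value threshold
#'
#' Converts each position frequency matrix to a log2-odds position weight
#' matrix against a 0-order background (default: the base composition of
#' the supplied sequences) with a pseudocount, computes the smallest score
#' whose tail probability under the background does not exceed `p_value`
#' (exactly, by dynamic programming over the discretized score
#' distribution), and counts windows at or above that score on both
#' strands. Overlapping hits are counted individually; sequences shorter
#' than the motif yield zero hits.
#'
#' @param sequences `DNAStringSet` or named character vector.
#' @param pfms named list of PFMs (4 x width count matrices).
#' @param p_value score-threshold tail probability (default 1e-4).
#' @param pseudocount PFM pseudocount (default 0.8).
#' @param background length-4 base composition (A, C, G, T); default
#'   estimated from `sequences`.
#' @param gran score discretization granularity in bits (default 0.01).
#' @return data.frame in long form: `seq`, `motif`, `hits`.
#' @export
scan_motifs <- function(sequences, pfms, p_value = 1e-4, pseudocount = 0.8,
                        background = NULL, gran = 0.01) {
  seqs <- as.character(Biostrings::DNAStringSet(sequences))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "")),
                        levels = c("A", "C", "G", "T")))
    background <- as.numeric(tab) / sum(tab)
    if (any(background == 0)) background <- rep(0.25, 4)
  }
  background <- background / sum(background)
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  enc_fwd <- lapply(seqs, encode_dna)
  enc_rev <- lapply(rcs, encode_dna)
  out <- list()
  for (mid in names(pfms)) {
    stopifnot(all(colSums(pfms[[mid]]) > 0))
    pwm <- pfm_to_pwm(pfms[[mid]], background, pseudocount)
    # quantize the PWM itself so scan and threshold share one score scale
    pwm_q <- round(pwm / gran) * gran
    thr <- pwm_threshold(pwm, background, p_value, gran)
    hits <- vapply(seq_along(seqs), function(i)
      scan_one_strand(enc_fwd[[i]], pwm_q, thr) +
        scan_one_strand(enc_rev[[i]], pwm_q, thr),
      integer(1))
    out[[mid]] <- data.frame(seq = names(seqs), motif = mid, hits = hits,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Gains and losses of motif matches between reference and alternative
#' sequences
#'
#' @param ref_hits,alt_hits data.frames from [scan_motifs()] over the same
#'   (seq, motif) grid on the reference and SNV-substituted sequences.
#' @return data.frame with `seq`, `motif`, `n_ref_hits`, `n_alt_hits`,
#'   `delta` in `{"gained", "lost", "unchanged"}`.
#' @export
motif_deltas <- function(ref_hits, alt_hits) {
  key <- function(x) paste(x$seq, x$motif, sep = "\r")
  stopifnot(setequal(key(ref_hits), key(alt_hits)))
  alt <- alt_hits[match(key(ref_hits), key(alt_hits)), ]
  d <- alt$hits - ref_hits$hits
  data.frame(seq = ref_hits$seq, motif = ref_hits$motif,
             n_ref_hits = ref_hits$hits, n_alt_hits = alt$hits,
             delta = ifelse(d > 0, "gained", ifelse(d < 0, "lost", "unchanged")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test motifs for association with differential accessibility
#'
#' For each motif with at least one gained and one lost peak, performs a
#' two-sample Student's t-test of the differential-accessibility
#' log2(fold-change) between the gained-peak and lost-peak groups, with
#' Benjamini-Hochberg adjustment across tested motifs. Motifs lacking
#' either gains or losses are skipped and reported. A motif is "opening"
#' when its gained peaks have the higher mean log2FC (motif presence
#' associated with increased accessibility) and "closing" otherwise. When
#' both groups have zero variance the t statistic is reported as +/-Inf
#' and the p-value comes from a permutation fallback.
#'
#' @param deltas data.frame from [motif_deltas()].
#' @param diff_peaks data.frame with `peak` (matching `deltas$seq`) and
#'   `log2fc`.
#' @param alpha BH significance level for the `significant` flag
#'   (default 0.05).
#' @param n_perm permutations for the zero-variance fallback (default
#'   2000).
#' @return data.frame: `motif`, `n_gain_peaks`, `n_loss_peaks`,
#'   `mean_log2fc_gain`, `mean_log2fc_loss`, `t_statistic`, `p_raw`,
#'   `p_adj`, `direction`, `significant`; attribute `skipped` lists motifs
#'   without both event types.
#' @export
functional_motif_test <- function(deltas, diff_peaks, alpha = 0.05,
                                  n_perm = 2000L) {
  stopifnot(all(c("peak", "log2fc") %in% names(diff_peaks)))
  lfc <- diff_peaks$log2fc[match(deltas$seq, diff_peaks$peak)]
  res <- list(); skipped <- character()
  for (mid in unique(deltas$motif)) {
    sel <- deltas$motif == mid & !is.na(lfc)
    g <- lfc[sel & deltas$delta == "gained"]
    l <- lfc[sel & deltas$delta == "lost"]
    if (length(g) < 1 || length(l) < 1) {
      skipped <- c(skipped, mid)
      next
    }
    if (length(g) + length(l) < 3 ||
        (stats::var(g) == 0 || is.na(stats::var(g))) &&
        (stats::var(l) == 0 || is.na(stats::var(l)))) {
      # degenerate: exact ties within groups -> permutation p
      tstat <- if (mean(g) == mean(l)) 0 else sign(mean(g) - mean(l)) * Inf
      obs <- abs(mean(g) - mean(l))
      pool <- c(g, l)
      perm <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pool), length(g))
        abs(mean(pool[idx]) - mean(pool[-idx]))
      }, numeric(1))
      p <- (sum(perm >= obs - 1e-12) + 1) / (n_perm + 1)
    } else {
      tt <- stats::t.test(g, l, var.equal = TRUE)
      tstat <- unname(tt$statistic)
      p <- tt$p.value
    }
    res[[mid]] <- data.frame(
      motif = mid, n_gain_peaks = length(g), n_loss_peaks = length(l),
      mean_log2fc_gain = mean(g), mean_log2fc_loss = mean(l),
      t_statistic = tstat, p_raw = p, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    out <- data.frame(motif = character(), n_gain_peaks = integer(),
                      n_loss_peaks = integer(), mean_log2fc_gain = numeric(),
                      mean_log2fc_loss = numeric(), t_statistic = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      direction = character(), significant = logical())
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$direction <- ifelse(out$mean_log2fc_gain > out$mean_log2fc_loss,
                          "opening", "closing")
  out$significant <- out$p_adj <= alpha
  attr(out, "skipped") <- skipped
  out
}

#' Aggregate fragments into pseudo-bulk peak counts
#'
#' Sums fragment counts over peaks for each (cell type, replicate) group
#' of cells — the input shape differential-accessibility fitting expects.
#' The differential fit itself is out of scope; this utility exists for
#' interoperability with such tools.
#'
#' @param fragments fragments table.
#' @param peaks `GRanges` or BED-convention data.frame of merged peaks.
#' @param cell_groups data.frame with `barcode`, `cell_type`,
#'   `replicate`; barcodes absent from it are ignored.
#' @return data.table in long form: `cell_type`, `replicate`, `peak`
#'   (index into `peaks`), `count`.
#' @export
pseudobulk_counts <- function(fragments, peaks, cell_groups) {
  stopifnot(all(c("barcode", "cell_type", "replicate") %in%
                  names(cell_groups)))
  dt <- data.table::as.data.table(fragments)
  idx <- match(dt$barcode, cell_groups$barcode)
  dt <- dt[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  dt$cell_type <- cell_groups$cell_type[idx]
  dt$replicate <- cell_groups$replicate[idx]
  if (!inherits(peaks, "GRanges")) {
    pk <- as.data.frame(peaks)
    peaks <- GenomicRanges::GRanges(
      pk$chrom, IRanges::IRanges(start = pk$start + 1L, end = pk$end))
  }
  ov <- GenomicRanges::findOverlaps(fragments_granges(dt), peaks)
  hits <- dt[S4Vectors::queryHits(ov)]
  hits$peak <- S4Vectors::subjectHits(ov)
  out <- hits[, list(count = .N), by = c("cell_type", "replicate", "peak")]
  data.table::setorder(out, cell_type, replicate, peak)
  out[]
}

#' Count differential peaks explained by functional motifs
#'
#' A differential peak is "explained" when it carries at least one
#' gain/loss event coherent with a significant functional motif's overall
#' direction: for an opening motif, a gained match on a peak with
#' `log2fc > 0` or a lost match on a peak with `log2fc < 0`; for a closing
#' motif, the reverse. Each peak is counted once regardless of how many
#' coherent events it carries.
#'
#' @param results data.frame from [functional_motif_test()].
#' @param deltas data.frame from [motif_deltas()].
#' @param diff_peaks data.frame with `peak`, `log2fc` and optionally
#'   `cell_type` for stratified counts.
#' @return data.frame per cell type (or one `"all"` row): `cell_type`,
#'   `explained`, `unexplained`, `total`.
#' @export
count_explained <- function(results, deltas, diff_peaks) {
  func <- results[results$significant, , drop = FALSE]
  dp <- as.data.frame(diff_peaks)
  if (!"cell_type" %in% names(dp)) dp$cell_type <- "all"
  explained_peaks <- character()
  for (i in seq_len(nrow(func))) {
    mid <- func$motif[i]
    opening <- func$direction[i] == "opening"
    dsub <- deltas[deltas$motif == mid & deltas$delta != "unchanged", ]
    lfc <- dp$log2fc[match(dsub$seq, dp$peak)]
    coherent <- if (opening) {
      (dsub$delta == "gained" & lfc > 0) | (dsub$delta == "lost" & lfc < 0)
    } else {
      (dsub$delta == "gained" & lfc < 0) | (dsub$delta == "lost" & lfc > 0)
    }
    explained_peaks <- union(explained_peaks,
                             dsub$seq[!is.na(coherent) & coherent])
  }
  dp$explained <- dp$peak %in% explained_peaks
  agg <- stats::aggregate(explained ~ cell_type, data = dp,
                          FUN = function(x) c(sum(x), length(x)))
  data.frame(cell_type = agg$cell_type,
             explained = agg$explained[, 1],
             unexplained = agg$explained[, 2] - agg$explained[, 1],
             total = agg$explained[, 2],
             stringsAsFactors = FALSE)
}
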