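# SNV filtering, hotspots, Jaccard, alternative sequences, PWM scanning
# with the exact threshold, and the functional-motif association test.

test_that("filter_snvs applies QUAL, DP-sum and concordance rules", {
  snvs <- data.frame(
    chrom = "mm_toy", pos = c(10L, 20L, 30L, 40L, 50L, 60L),
    ref = c("A", "A", "A", "A", "A", "A"),
    alt = c("G", "G", "G", "G", "G", "G"),
    qual = c(60, 19.9, 20, 60, 60, 60),
    dp1 = c(4L, 4L, 4L, 3L, 4L, 4L),
    dp2 = c(3L, 3L, 3L, 3L, 3L, 3L),
    dp3 = c(3L, 3L, 3L, 3L, 3L, 3L),
    gt1 = c("1/1", "1/1", "1/1", "1/1", "0/1", "0/1"),
    gt2 = c("1/1", "1/1", "1/1", "1/1", "0/1", "1/0"),
    gt3 = c("1/1", "1/1", "1/1", "1/1", "1/1", "0/0"))
  snvs$dp1[4] <- 3L  # DP sum 9 -> dropped
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(snvs, path)
  out <- filter_snvs(path)
  # QUAL 19.9 dropped, 20 kept; DP 9 dropped, 10 kept;
  # (0/1, 0/1, 1/1) kept by 2-of-3; all-discordant dropped
  expect_setequal(out$pos, c(10L, 30L, 50L))
  expect_identical(out$genotype[out$pos == 50L], "0/1")
})

test_that("non-SNV records are dropped and counted", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=mm_toy>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "r1", "r2", "r3", sep = "\t"),
    "mm_toy\t5\t.\tA\tG\t60\tPASS\t.\tGT:DP\t1/1:5\t1/1:5\t1/1:5",
    "mm_toy\t9\t.\tAT\tA\t60\tPASS\t.\tGT:DP\t1/1:5\t1/1:5\t1/1:5",
    "mm_toy\t15\t.\tC\tCT\t60\tPASS\t.\tGT:DP\t1/1:5\t1/1:5\t1/1:5"),
    vcf)
  out <- filter_snvs(vcf)
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "n_dropped_non_snv"), 2L)
})

test_that("hotspot assignment is 1-based closed at both boundaries", {
  snvs <- data.frame(chrom = c("chr8", "chr8", "chr8", "chr1", "chr19"),
                     pos = c(68000000, 67999999, 93000000, 100, 16500000))
  out <- assign_hotspots(snvs)
  expect_identical(out$hotspot,
                   c("chr8_hotspot", "outside", "chr8_hotspot", "outside",
                     "chr19_hotspot"))
  expect_identical(sum(table(out$hotspot)), nrow(snvs))
})

test_that("Jaccard similarity is exact set arithmetic", {
  mk <- function(pos) data.frame(chrom = rep("c", length(pos)), pos = pos,
                                 ref = rep("A", length(pos)),
                                 alt = rep("G", length(pos)))
  a <- mk(1:4); b <- mk(3:6)
  expect_equal(jaccard_snv_sets(a, b), 2 / 6)  # |A|=4 |B|=4 |int|=2 -> 1/3
  expect_equal(jaccard_snv_sets(a, a), 1)
  expect_equal(jaccard_snv_sets(a, mk(10:13)), 0)
  expect_warning(j0 <- jaccard_snv_sets(mk(integer()), mk(integer())),
                 "empty")
  expect_identical(j0, 0)
  # symmetric
  expect_equal(jaccard_snv_sets(a, b), jaccard_snv_sets(b, a))
})

test_that("apply_snvs_to_sequence substitutes and guards coordinates", {
  seqs <- c("mm_toy:11-20" = "ACGTACGTAC")
  snv <- data.frame(chrom = "mm_toy", pos = 13L, ref = "G", alt = "T")
  out <- apply_snvs_to_sequence(seqs, snv)
  expect_identical(as.character(out)[[1]], "ACTTACGTAC")
  expect_identical(Biostrings::width(out), 10L)
  # no SNVs -> identity
  ident <- apply_snvs_to_sequence(seqs, snv[0, ])
  expect_identical(as.character(ident)[[1]], "ACGTACGTAC")
  # reference mismatch raises a named error
  bad <- data.frame(chrom = "mm_toy", pos = 13L, ref = "A", alt = "T")
  expect_error(apply_snvs_to_sequence(seqs, bad), "mismatch at mm_toy:13")
})

test_that("PWM threshold from DP equals brute-force enumeration", {
  set.seed(31)
  for (rep in 1:4) {
    w <- sample(4:8, 1)
    cons <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                  collapse = "")
    pfm <- txcitools:::sharp_pfm(cons, counts = sample(c(20, 100, 997), 1))
    bg <- if (rep %% 2) rep(0.25, 4) else c(0.3, 0.2, 0.2, 0.3)
    pwm <- txcitools:::pfm_to_pwm(pfm, bg, 0.8)
    pwm_q <- round(pwm / 0.01) * 0.01
    dp_thr <- txcitools:::pwm_threshold(pwm, bg, 1e-4, 0.01)
    bf_thr <- brute_force_threshold(pwm_q, bg, 1e-4)
    expect_equal(dp_thr, bf_thr, tolerance = 1e-9)
  }
})

test_that("motif scanning is strand-symmetric and finds consensus", {
  mo <- toy_motifs()
  cons_pfm <- mo$pfms[1]
  cons <- paste(c("A", "C", "G", "T")[apply(cons_pfm[[1]], 2, which.max)],
                collapse = "")
  seq1 <- paste0(strrep("A", 30), cons, strrep("C", 30))
  names(seq1) <- "s1"
  hits <- scan_motifs(seq1, cons_pfm, background = rep(0.25, 4))
  expect_gte(hits$hits, 1)
  # reverse complement of the sequence gives the same count
  rc1 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(unname(seq1))))
  names(rc1) <- "s1rc"
  hits_rc <- scan_motifs(rc1, cons_pfm, background = rep(0.25, 4))
  expect_identical(hits$hits, hits_rc$hits)
  # sequences shorter than the motif yield zero hits
  short <- c(s = "ACG")
  expect_identical(scan_motifs(short, cons_pfm)$hits, 0L)
})

test_that("motif_deltas labels by sign of the hit-count change", {
  ref <- data.frame(seq = c("p1", "p2", "p3"), motif = "M",
                    hits = c(0L, 2L, 1L))
  alt <- data.frame(seq = c("p1", "p2", "p3"), motif = "M",
                    hits = c(1L, 1L, 1L))
  d <- motif_deltas(ref, alt)
  expect_identical(d$delta, c("gained", "lost", "unchanged"))
})

test_that("the planted functional motif is recovered end to end", {
  mo <- toy_motifs()
  snvs <- filter_snvs(mo$files$vcf)
  alt <- apply_snvs_to_sequence(mo$sequences, snvs)
  ref_hits <- scan_motifs(mo$sequences, mo$pfms)
  alt_hits <- scan_motifs(alt, mo$pfms)
  d <- motif_deltas(ref_hits, alt_hits)
  res <- functional_motif_test(d, mo$diff_peaks)
  hit <- res[res$motif == mo$truth$functional_motif, ]
  expect_true(hit$significant)
  expect_gt(hit$t_statistic, 0)
  expect_identical(hit$direction, "opening")
  # the zero-effect control motif is tested but not significant
  ctrl <- res[res$motif == mo$truth$neutral_motif, ]
  expect_identical(nrow(ctrl), 1L)
  expect_false(ctrl$significant)
  # motifs with no losses are excluded from testing
  expect_true(all(setdiff(names(mo$pfms),
                          c(mo$truth$functional_motif,
                            mo$truth$neutral_motif)) %in%
                    attr(res, "skipped")))
  # explained counts: conservation over all differential peaks
  ce <- count_explained(res, d, mo$diff_peaks)
  expect_identical(ce$explained + ce$unexplained, ce$total)
  expect_identical(sum(ce$total), nrow(mo$diff_peaks))
  # peaks coherent with the opening motif are explained
  expect_gte(sum(ce$explained), 40)
})

test_that("count_explained requires coherent direction", {
  res <- data.frame(motif = "M", direction = "opening", significant = TRUE)
  deltas <- data.frame(seq = c("up", "down"), motif = "M",
                       n_ref_hits = 0L, n_alt_hits = 1L, delta = "gained")
  dp <- data.frame(peak = c("up", "down"), log2fc = c(1, -1))
  ce <- count_explained(res, deltas, dp)
  expect_identical(ce$explained, 1L)   # only the log2fc > 0 peak
  expect_identical(ce$unexplained, 1L)
})

test_that("permutation fallback handles zero-variance groups", {
  deltas <- data.frame(seq = paste0("p", 1:8), motif = "M",
                       n_ref_hits = 0L,
                       n_alt_hits = rep(c(1L, 0L), each = 4),
                       delta = rep(c("gained", "lost"), each = 4))
  dp <- data.frame(peak = paste0("p", 1:8),
                   log2fc = rep(c(2, -2), each = 4))  # exact ties
  res <- functional_motif_test(deltas, dp)
  expect_identical(res$t_statistic, Inf)
  expect_lt(res$p_raw, 0.05)
  expect_identical(res$direction, "opening")
})

test_that("pseudobulk aggregation sums fragments per group and peak", {
  fr <- data.frame(chrom = "mm_toy",
                   start = c(10L, 20L, 500L, 15L, 505L),
                   end = c(60L, 70L, 560L, 65L, 555L),
                   barcode = c("a", "a", "a", "b", "c"))
  peaks <- data.frame(chrom = "mm_toy", start = c(0L, 450L),
                      end = c(100L, 600L))
  groups <- data.frame(barcode = c("a", "b"),
                       cell_type = c("T", "T"),
                       replicate = c("r1", "r2"))  # "c" unassigned
  pb <- pseudobulk_counts(fr, peaks, groups)
  expect_identical(pb$count[pb$replicate == "r1" & pb$peak == 1], 2L)
  expect_identical(pb$count[pb$replicate == "r1" & pb$peak == 2], 1L)
  expect_identical(pb$count[pb$replicate == "r2" & pb$peak == 1], 1L)
  expect_identical(sum(pb$count), 4L)   # fragment "c" ignored
})
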