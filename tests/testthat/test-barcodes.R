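# Barcode extraction, Hamming correction, combined barcodes, and full-run
# demultiplexing against fixture truth.

ME <- "AGATGTGTATAAGAGACAG"  # mosaic end

test_that("extract_tn5 slices read 2 at the 8 + 19 bp boundary", {
  r2 <- paste0("AAAAAAAA", ME, "ACGT")
  out <- extract_tn5(r2)
  expect_identical(out$tn5_raw, "AAAAAAAA")
  expect_identical(out$genomic, "ACGT")
  expect_identical(out$status, "ok")
  # a 100 bp read leaves 73 genomic bases
  out100 <- extract_tn5(strrep("A", 100))
  expect_identical(nchar(out100$genomic), 73L)
  # 27 bp boundary read: no genomic sequence -> flagged
  out27 <- extract_tn5(strrep("A", 27))
  expect_identical(out27$status, "too_short")
  # quality sliced identically
  q <- paste0(strrep("#", 27), "IIII")
  outq <- extract_tn5(r2, q)
  expect_identical(outq$genomic_qual, "IIII")
})

test_that("correct_barcode resolves unique hits and discards ties", {
  wl <- barcode_whitelist(c("AAAAAAAA", "CCCCCCCC"), "tn5")
  expect_identical(correct_barcode("AAAAAAAA", wl)$corrected, "AAAAAAAA")
  expect_identical(correct_barcode("AAAAAAAA", wl)$distance, 0L)
  r <- correct_barcode("AAAAAAAT", wl)
  expect_identical(r$corrected, "AAAAAAAA")
  expect_identical(r$status, "ok")
  # exhaustive-distance oracle agreement on random observations
  set.seed(42)
  wl2 <- toy_whitelists()$tn5
  obs <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = ""),
    character(1))
  got <- correct_barcode(obs, wl2)
  for (i in seq_along(obs)) {
    d <- vapply(as.character(wl2), slow_hamming, numeric(1), a = obs[i])
    n_within <- sum(d <= 2)
    if (n_within == 1) {
      expect_identical(got$corrected[i], as.character(wl2)[which(d <= 2)])
    } else {
      expect_true(is.na(got$corrected[i]))
      expect_identical(got$status[i],
                       if (n_within >= 2) "ambiguous" else "uncorrectable")
    }
  }
  # tie at distance 1 to two entries -> ambiguous
  wl3 <- barcode_whitelist(c("AAAATTTT", "AAAATTCC"), "tn5")
  amb <- correct_barcode("AAAATTTC", wl3)
  expect_identical(amb$status, "ambiguous")
  expect_true(is.na(amb$corrected))
  # length mismatch -> uncorrectable
  expect_identical(correct_barcode("AAAA", wl)$status, "uncorrectable")
})

test_that("correction is idempotent and exact at <= 1 substitution", {
  wl <- toy_whitelists()$tn5
  set.seed(7)
  truth <- sample(as.character(wl), 200, replace = TRUE)
  # flip exactly one base in each
  obs <- vapply(truth, function(bc) {
    i <- sample(8, 1)
    b <- substr(bc, i, i)
    substr(bc, i, i) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    bc
  }, character(1), USE.NAMES = FALSE)
  r1 <- correct_barcode(obs, wl)
  # exactness: every corrected value equals the planted truth
  ok <- r1$status == "ok"
  expect_identical(r1$corrected[ok], truth[ok])
  expect_identical(sum(r1$corrected[ok] != truth[ok]), 0L)
  # idempotence: correcting the corrected barcodes is the identity
  r2 <- correct_barcode(r1$corrected[ok], wl)
  expect_identical(r2$corrected, r1$corrected[ok])
  expect_identical(unique(r2$distance), 0L)
})

test_that("combined barcode concatenates and round-trips", {
  cb <- build_combined_barcode("ACGTACGT", strrep("G", 16), strrep("T", 8))
  expect_identical(nchar(cb), 32L)
  back <- split_combined_barcode(cb)
  expect_identical(back$i7, "ACGTACGT")
  expect_identical(back$gem, strrep("G", 16))
  expect_identical(back$tn5, strrep("T", 8))
  expect_error(build_combined_barcode(NA_character_, "G", "T"),
               "non-missing")
  # same triple -> same combined barcode (pure function)
  expect_identical(cb, build_combined_barcode("ACGTACGT", strrep("G", 16),
                                              strrep("T", 8)))
})

test_that("demultiplex is exact at zero error rate", {
  run <- toy_run(0)
  wl <- toy_whitelists()
  out_dir <- withr::local_tempdir()
  res <- demultiplex(run$files$r1, run$files$r2, run$files$i1, run$files$i2,
                     wl, run$sample_sheet, out_dir = out_dir)
  n <- nrow(run$truth)
  expect_identical(unname(res$report$overall["ok"]), n)
  expect_identical(res$assignments$sample, run$truth$sample)
  expect_identical(
    res$assignments$combined,
    build_combined_barcode(run$truth$i7, run$truth$gem, run$truth$tn5))
  # per-sample FASTQ reads carry the combined barcode in the name
  f <- res$files[[run$sample_sheet$sample[1]]]["R1"]
  lines <- readLines(f)
  ids <- sub("^@", "", lines[seq(1, length(lines), 4)])
  expect_true(all(grepl(":", ids, fixed = TRUE)))
})

test_that("demultiplex at 1% substitution: conservation and accuracy", {
  run <- toy_run(0.01)
  wl <- toy_whitelists()
  res <- demultiplex(run$files$r1, run$files$r2, run$files$i1, run$files$i2,
                     wl, run$sample_sheet)
  n <- nrow(run$truth)
  # conservation per level and overall
  for (lvl in c("tn5", "gem", "i7", "overall"))
    expect_identical(sum(res$report[[lvl]]), n)
  ok <- res$assignments$status == "ok"
  acc <- mean(res$assignments$sample[ok] == run$truth$sample[ok])
  expect_gte(acc, 0.999)
  # injected error fraction consistent with the binomial expectation
  # (32 sequenced barcode bases per read) within 3 sigma
  seq_err <- with(run$truth, {
    fq_tn5 <- extract_tn5(read_fastq_seqs(run$files$r2))$tn5_raw
    fq_gem <- read_fastq_seqs(run$files$i2)
    fq_i7 <- read_fastq_seqs(run$files$i1)
    fq_tn5 != tn5 | fq_gem != gem | fq_i7 != i7
  })
  p <- 1 - (1 - 0.01)^32
  expect_lt(abs(mean(seq_err) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("overlapping well assignments are rejected up front", {
  wl <- toy_whitelists()
  sheet <- data.frame(sample = c("s1", "s2"),
                      i7 = rep(as.character(wl$i7)[1], 2),
                      tn5_wells = c("A1,A2", "A2,A3"),
                      stringsAsFactors = FALSE)
  run <- toy_run(0)
  expect_error(
    demultiplex(run$files$r1, run$files$r2, run$files$i1, run$files$i2,
                wl, sheet),
    "overlapping well assignments")
})
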