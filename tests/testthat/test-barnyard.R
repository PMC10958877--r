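# Cell calling (fixed and k-means), species classification, corrected
# collision-rate estimation, and bead-multiplet merging.

test_that("fixed-threshold cell calling is a strict boundary at 1000", {
  counts <- data.frame(barcode = c("a", "b", "c"),
                       total_unique = c(999L, 1000L, 5000L))
  cc <- call_cells_fixed(counts)
  expect_identical(cc$is_cell, c(FALSE, TRUE, TRUE))
  # empty input -> empty output
  empty <- call_cells_fixed(counts[0, ])
  expect_identical(nrow(empty), 0L)
  # monotone: raising the threshold never adds cells
  cc2 <- call_cells_fixed(counts, min_reads = 2000)
  expect_true(all(cc2$is_cell <= cc$is_cell))
})

test_that("k-means calling matches the exhaustive 1-D partition", {
  counts <- data.frame(barcode = letters[1:4],
                       total_unique = round(10^c(2.1, 2.2, 3.9, 4.0)))
  cc <- call_cells_kmeans(counts, seed = 1)
  # exhaustive 2-partition of sorted 1-D data minimizing within-cluster SS
  x <- sort(log10(counts$total_unique))
  ss <- vapply(1:3, function(k)
    sum((x[1:k] - mean(x[1:k]))^2) +
      sum((x[(k + 1):4] - mean(x[(k + 1):4]))^2), numeric(1))
  expect_identical(which.min(ss), 2L)   # oracle: split between 2.2 and 3.9
  expect_identical(cc$is_cell, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(cc$threshold_used[1], round(10^3.9))
  # threshold lies strictly between the two cluster means (in counts)
  expect_gt(cc$threshold_used[1], 10^mean(c(2.1, 2.2)))
  expect_lt(cc$threshold_used[1], 10^mean(c(3.9, 4.0)))
  # seed stability on well-separated data
  cc2 <- call_cells_kmeans(counts, seed = 77)
  expect_identical(cc$is_cell, cc2$is_cell)
  # degenerate input errors with advice
  flat <- data.frame(barcode = letters[1:5], total_unique = rep(500L, 5))
  expect_error(call_cells_kmeans(flat), "degenerate")
})

test_that("k-means recovers the planted cell set on the bimodal fixture", {
  fx <- toy_barnyard()
  cs <- count_species(fx$fragments)
  cc <- call_cells_kmeans(cs, seed = 1)
  cells <- cc$barcode[cc$is_cell]
  truth_cells <- fx$truth$barcode[fx$truth$kind != "debris"]
  recovery <- mean(truth_cells %in% cells)
  purity <- mean(cells %in% truth_cells)
  expect_gte(recovery, 0.99)
  expect_gte(purity, 0.99)
})

test_that("species classification applies the 90% purity rule", {
  sc <- data.frame(barcode = c("a", "b", "c", "d"),
                   hg = c(95L, 85L, 50L, 90L),
                   mm = c(5L, 15L, 50L, 10L))
  sp <- classify_species(sc)
  expect_identical(sp$label, c("hg", "collision", "collision", "hg"))
  expect_equal(sp$major_fraction, c(0.95, 0.85, 0.5, 0.9))
})

test_that("collision correction divides by 2pq and caps at 1", {
  mk <- function(n_het, n) data.frame(
    barcode = seq_len(n),
    label = c(rep("collision", n_het),
              rep(c("hg", "mm"), length.out = n - n_het)))
  est <- estimate_collision_rate(mk(5, 100), c(0.5, 0.5))
  expect_equal(est$corrected_rate, 0.10)
  expect_equal(estimate_collision_rate(mk(0, 100), c(0.5, 0.5))$corrected_rate, 0)
  # 3/100 at p = 0.75: 2pq = 0.375 -> 0.08
  est2 <- estimate_collision_rate(mk(3, 100), c(0.75, 0.25))
  expect_equal(est2$corrected_rate, 0.03 / 0.375)
  # cap at 1
  est3 <- estimate_collision_rate(mk(80, 100), c(0.5, 0.5))
  expect_identical(est3$corrected_rate, 1)
  # degenerate mixes rejected
  expect_error(estimate_collision_rate(mk(1, 10), c(1, 0)), "heterotypic")
})

test_that("collision estimator agrees with a Monte Carlo pairing oracle", {
  # oracle: pair cells into doublets at a known rate, classify by the 90%
  # purity rule, estimate, and compare the mean estimate to truth
  true_rate <- 0.1
  n_cells <- 10000
  est <- vapply(1:50, function(s) {
    set.seed(s)
    n_coll <- round(true_rate * n_cells)
    sp1 <- sample(c("hg", "mm"), n_cells, replace = TRUE)
    sp2 <- sample(c("hg", "mm"), n_coll, replace = TRUE)  # doublet partner
    label <- sp1
    label[seq_len(n_coll)] <- ifelse(sp1[seq_len(n_coll)] == sp2,
                                     sp1[seq_len(n_coll)], "collision")
    calls <- data.frame(barcode = seq_len(n_cells), label = label)
    estimate_collision_rate(calls, c(0.5, 0.5))$corrected_rate
  }, numeric(1))
  sem <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - true_rate), 3 * sem)
})

test_that("bead-multiplet merging unions fragments per droplet group", {
  i7 <- strrep("A", 8); tn5 <- strrep("T", 8)
  bead1 <- strrep("C", 16); bead2 <- strrep("G", 16)
  bc1 <- paste0(i7, bead1, tn5); bc2 <- paste0(i7, bead2, tn5)
  fr <- data.table::data.table(
    chrom = "hg_toy",
    start = c(10L, 20L, 10L, 30L),
    end = c(60L, 70L, 60L, 80L),
    barcode = c(bc1, bc1, bc2, bc2),
    dup_count = 1L)
  # identity map: output = input counts
  ident <- data.frame(bead = c(bead1, bead2), group = c(bead1, bead2))
  out_id <- merge_bead_multiplets(fr, ident)
  expect_identical(nrow(out_id), 4L)
  # shared droplet: two beads share the (coords, Tn5) fragment at 10-60
  shared <- data.frame(bead = c(bead1, bead2), group = "drop1")
  out <- merge_bead_multiplets(fr, shared)
  # set-union oracle: 3 unique fragments (10-60 shared, 20-70, 30-80)
  expect_identical(nrow(out), 3L)
  expect_identical(sum(out$dup_count), 4L)
  expect_true(all(out$barcode == paste0(i7, "drop1", tn5)))
  # disjoint beads: merged unique count = sum
  fr2 <- fr[c(1, 4)]
  expect_identical(nrow(merge_bead_multiplets(fr2, shared)), 2L)
  # a bead in two groups is a configuration error
  dup_map <- data.frame(bead = c(bead1, bead1), group = c("g1", "g2"))
  expect_error(merge_bead_multiplets(fr, dup_map), "more than one")
})

test_that("single-Tn5 restriction keeps only pure droplets", {
  i7 <- strrep("A", 8)
  g1 <- strrep("C", 16); g2 <- strrep("G", 16)
  t1 <- strrep("T", 8); t2 <- strrep("A", 8)
  bcs <- c(paste0(i7, g1, t1), paste0(i7, g1, t1),   # droplet g1: one Tn5
           paste0(i7, g2, t1), paste0(i7, g2, t2))   # droplet g2: two Tn5s
  keep <- restrict_single_tn5(bcs)
  expect_identical(keep, c(TRUE, TRUE, FALSE, FALSE))
})
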