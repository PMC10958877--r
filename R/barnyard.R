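# Cell calling, barnyard species classification, and corrected
# collision-rate estimation. A "collision" is a single combined barcode
# carrying the contents of two or more cells; in a two-species barnyard
# only heterotypic collisions are visible, so the observed rate is scaled
# by 1 / (2 p q) where (p, q) are the species mixing proportions.

#' Call cell-containing barcodes by a fixed read threshold
#'
#' @param counts data.frame with `barcode` and `total_unique` columns
#'   (e.g. from [count_species()]).
#' @param min_reads minimum unique reads for a cell (default 1000).
#' @return data.frame `barcode`, `total_unique`, `is_cell`,
#'   `threshold_used`, `method = "fixed"`.
#' @export
call_cells_fixed <- function(counts, min_reads = 1000L) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("barcode", "total_unique") %in% names(counts)),
            all(counts$total_unique >= 0))
  data.frame(barcode = counts$barcode,
             total_unique = counts$total_unique,
             is_cell = counts$total_unique >= min_reads,
             threshold_used = rep(min_reads, nrow(counts)),
             method = rep("fixed", nrow(counts)),
             stringsAsFactors = FALSE)
}

#' Call cells by 1-D k-means on log10 unique reads
#'
#' Barcodes with at least `min_reads_floor` unique reads are clustered in
#' one dimension (log10 unique reads) with k-means (`k = 2`, `n_init`
#' random starts); members of the higher-mean cluster are called cells and
#' the data-driven threshold is that cluster's minimum read count.
#' Barcodes below the floor are never cells.
#'
#' @param counts as in [call_cells_fixed()].
#' @param min_reads_floor barcodes below this are excluded from clustering
#'   (default 100).
#' @param k number of clusters (default 2).
#' @param n_init random restarts (default 50).
#' @param seed RNG seed.
#' @return data.frame as in [call_cells_fixed()] with `method = "kmeans"`
#'   and the derived `threshold_used`.
#' @export
call_cells_kmeans <- function(counts, min_reads_floor = 100L, k = 2L,
                              n_init = 50L, seed = 1L) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("barcode", "total_unique") %in% names(counts)))
  above <- counts$total_unique >= min_reads_floor
  x <- log10(counts$total_unique[above])
  if (length(x) < k)
    stop("need at least ", k, " barcodes above the floor for k-means")
  if (length(unique(x)) < k)
    stop("degenerate read-depth distribution (all counts equal); ",
         "use call_cells_fixed() instead")
  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = k, nstart = n_init)
  hi <- which.max(km$centers)
  is_cell_above <- km$cluster == hi
  threshold <- min(counts$total_unique[above][is_cell_above])
  is_cell <- rep(FALSE, nrow(counts))
  is_cell[above] <- is_cell_above
  data.frame(barcode = counts$barcode,
             total_unique = counts$total_unique,
             is_cell = is_cell,
             threshold_used = threshold,
             method = "kmeans", stringsAsFactors = FALSE)
}

#' Classify cell barcodes by species purity
#'
#' A cell is a bona fide single cell of a species when at least `purity`
#' (default 90%) of its unique reads align to that species' genome;
#' otherwise it is a collision. No pseudo-count enters the classification
#' (a pseudo-count of 1 is conventional for log-scale plotting only).
#'
#' @param species_counts data.frame with `barcode` and exactly two species
#'   count columns (all columns other than `barcode` / `total_unique`).
#' @param purity majority-species fraction required (default 0.9).
#' @return data.frame `barcode`, `major_fraction`, `label` (one of the two
#'   species names or `"collision"`).
#' @export
classify_species <- function(species_counts, purity = 0.9) {
  df <- as.data.frame(species_counts)
  spcols <- setdiff(names(df), c("barcode", "total_unique"))
  if (length(spcols) != 2)
    stop("expected exactly two species count columns, got: ",
         paste(spcols, collapse = ", "))
  a <- df[[spcols[1]]]; b <- df[[spcols[2]]]
  total <- a + b
  if (any(total <= 0)) stop("barcodes with zero reads cannot be classified")
  major <- pmax(a, b) / total
  label <- ifelse(major >= purity,
                  ifelse(a >= b, spcols[1], spcols[2]),
                  "collision")
  data.frame(barcode = df$barcode, major_fraction = major, label = label,
             stringsAsFactors = FALSE)
}

#' Corrected collision rate from observed heterotypic collisions
#'
#' In a two-species mix with proportions `(p, q)`, only the fraction
#' `2 p q` of collisions pair cells of different species and are therefore
#' observable; at a 1:1 mix the observed heterotypic collisions reflect
#' approximately half of all collision events. The corrected rate is
#' `observed / (2 p q)`, capped at 1. The denominator of the observed rate
#' is all cells passing the read threshold, collisions included.
#'
#' @param species_calls data.frame from [classify_species()] (cells only).
#' @param mix_proportions numeric length-2 species proportions summing to
#'   1, both strictly inside (0, 1); `NULL` (default) uses the
#'   cell-count-weighted proportions among non-collision cells.
#' @return List: `n_cells`, `n_heterotypic`, `observed_rate`,
#'   `mix_proportions`, `corrected_rate`.
#' @export
estimate_collision_rate <- function(species_calls, mix_proportions = NULL) {
  df <- as.data.frame(species_calls)
  stopifnot("label" %in% names(df))
  n <- nrow(df)
  if (n == 0) stop("no cells provided")
  n_het <- sum(df$label == "collision")
  if (is.null(mix_proportions)) {
    tab <- table(df$label[df$label != "collision"])
    if (length(tab) < 2)
      stop("cannot infer mix proportions: fewer than two species observed; ",
           "supply mix_proportions explicitly")
    mix_proportions <- as.numeric(tab / sum(tab))
  }
  stopifnot(length(mix_proportions) == 2,
            abs(sum(mix_proportions) - 1) < 1e-8)
  p <- mix_proportions[1]
  if (p <= 0 || p >= 1)
    stop("mix proportions of 0 or 1 admit no heterotypic signal")
  observed <- n_het / n
  corrected <- min(1, observed / (2 * p * (1 - p)))
  list(n_cells = n, n_heterotypic = n_het, observed_rate = observed,
       mix_proportions = mix_proportions, corrected_rate = corrected)
}

#' Restrict to droplets carrying exactly one Tn5 barcode
#'
#' Diagnostic filter for in-droplet barcode swapping: keeps only cell
#' barcodes whose droplet (GEM barcode, or droplet group) is associated
#' with exactly one distinct Tn5 barcode across the supplied set. Cells
#' in droplets that mix Tn5 barcodes are excluded, so any residual
#' collision signal cannot come from Tn5 cross-talk within a droplet.
#'
#' @param barcodes character vector of combined barcodes (i7|GEM|Tn5).
#' @param i7_len,gem_len,tn5_len combined-barcode layout (defaults
#'   8/16/8).
#' @return Logical vector marking barcodes to keep.
#' @export
restrict_single_tn5 <- function(barcodes, i7_len = 8L, gem_len = 16L,
                                tn5_len = 8L) {
  parts <- split_combined_barcode(barcodes, i7_len, gem_len, tn5_len)
  n_tn5 <- tapply(parts$tn5, parts$gem, function(x) length(unique(x)))
  as.vector(n_tn5[parts$gem] == 1L)
}

#' Merge bead-multiplet barcodes given droplet-group assignments
#'
#' When several barcoded beads occupy one droplet, a cell's reads are split
#' across bead (GEM) barcodes. Given an externally inferred mapping from
#' bead barcode to droplet group, fragments are re-keyed to
#' (droplet group | Tn5 barcode) and re-deduplicated, so identical
#' fragments split across beads of one droplet collapse. Unique counts can
#' never increase.
#'
#' @param fragments fragments table (deduplicated or not) whose `barcode`
#'   is the combined i7|GEM|Tn5 barcode.
#' @param group_map data.frame with columns `bead` (GEM barcode) and
#'   `group` (droplet-group identifier); must be a partition (no bead in
#'   two groups). Beads absent from the map keep their own barcode as the
#'   group.
#' @param i7_len,gem_len,tn5_len combined-barcode layout (defaults 8/16/8).
#' @return Re-deduplicated data.table with merged `barcode` =
#'   `i7|group|tn5` and summed `dup_count`.
#' @export
merge_bead_multiplets <- function(fragments, group_map,
                                  i7_len = 8L, gem_len = 16L, tn5_len = 8L) {
  stopifnot(all(c("bead", "group") %in% names(group_map)))
  if (anyDuplicated(group_map$bead))
    stop("bead barcode assigned to more than one droplet group")
  dt <- data.table::as.data.table(fragments)
  parts <- split_combined_barcode(dt$barcode, i7_len, gem_len, tn5_len)
  grp <- group_map$group[match(parts$gem, group_map$bead)]
  grp <- ifelse(is.na(grp), parts$gem, as.character(grp))
  dt$barcode <- paste0(parts$i7, grp, parts$tn5)
  if (!"dup_count" %in% names(dt)) dt$dup_count <- 1L
  merged <- dt[, list(dup_count = sum(dup_count)),
               by = c("barcode", "chrom", "start", "end")]
  data.table::setcolorder(merged, c("chrom", "start", "end", "barcode",
                                    "dup_count"))
  data.table::setorder(merged, chrom, start, end, barcode)
  merged[]
}
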