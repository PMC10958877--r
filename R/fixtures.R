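# Synthetic, fully ground-truthed fixtures at toy scale: kilobase
# two-species genomes, hundreds to thousands of cells, planted barcode
# errors, collisions, doublets and functional motifs. Every generator is
# deterministic in the seed of its fixture_spec, and every planted truth
# is recoverable by the corresponding analysis module. These emulate file
# formats and statistical structure only -- no sequence biology.

#' Specification for a synthetic fixture set
#'
#' @param seed integer RNG seed; identical specs produce byte-identical
#'   files.
#' @param n_cells number of true cells.
#' @param genome_sizes named integer vector of contig lengths in bp, one
#'   per species; names are used as contig names and must carry the
#'   species prefix before `"_"` (default two 20 kb toy contigs `hg_toy`
#'   and `mm_toy`). Lengths below 1 kb are rejected.
#' @param error_rate per-base barcode substitution probability in [0, 1].
#' @param true_collision_fraction proportion of cell barcodes that are
#'   planted collisions (two cells sharing a barcode).
#' @param doublet_fraction proportion of planted doublets in the count
#'   matrix.
#' @param n_peaks peaks in matrix/motif fixtures (>= 50 for matrices).
#' @param n_motifs motifs in the motif fixture (>= 2).
#' @return Validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_cells = 400L,
                         genome_sizes = c(hg_toy = 20000L, mm_toy = 20000L),
                         error_rate = 0, true_collision_fraction = 0,
                         doublet_fraction = 0, n_peaks = 300L,
                         n_motifs = 6L) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_cells >= 1,
            length(genome_sizes) >= 1, all(genome_sizes >= 1000),
            !is.null(names(genome_sizes)),
            error_rate >= 0, error_rate <= 1,
            true_collision_fraction >= 0, true_collision_fraction <= 1,
            doublet_fraction >= 0, doublet_fraction <= 1,
            n_peaks >= 1, n_motifs >= 1)
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 genome_sizes = genome_sizes, error_rate = error_rate,
                 true_collision_fraction = true_collision_fraction,
                 doublet_fraction = doublet_fraction,
                 n_peaks = as.integer(n_peaks),
                 n_motifs = as.integer(n_motifs)),
            class = "fixture_spec")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# greedy random code with minimum pairwise Hamming distance; errors out if
# the request is infeasible (beyond the alphabet) or the attempt budget is
# exhausted, which catches sphere-packing violations by construction.
greedy_code <- function(n, len, min_dist, max_tries = 200L) {
  if (n > 4^len)
    stop(sprintf("cannot build %d distinct %d-mers: alphabet admits only %d",
                 n, len, 4^len))
  codes <- character(0)
  mats <- NULL
  tries_left <- max_tries * n
  while (length(codes) < n) {
    if (tries_left <= 0)
      stop(sprintf(
        "cannot build %d %d-mers at min Hamming distance %d: attempt budget exhausted (sphere-packing limit reached)",
        n, len, min_dist))
    tries_left <- tries_left - 1L
    cand <- random_dna(1L, len)
    cm <- strsplit(cand, "")[[1]]
    if (is.null(mats)) {
      codes <- cand
      mats <- matrix(cm, nrow = 1)
      next
    }
    d <- rowSums(sweep(mats, 2L, cm, "!="))
    if (all(d >= min_dist)) {
      codes <- c(codes, cand)
      mats <- rbind(mats, cm)
    }
  }
  codes
}

#' Generate the three barcode whitelists
#'
#' Builds a 96-entry Tn5 whitelist of 8-mers (named by plate well
#' `A1..H12`), a GEM whitelist of 16-mers and an i7 whitelist of 8-mers.
#' All three sets have pairwise Hamming distance >= 3, so that
#' distance-<=2 correction of a single substitution is unambiguous.
#'
#' @param spec a [fixture_spec()].
#' @param n_tn5,n_gem,n_i7 whitelist sizes (defaults 96, 384, 8).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @return Named list of [barcode_whitelist()]s: `tn5`, `gem`, `i7`.
#' @export
make_barcode_whitelists <- function(spec, n_tn5 = 96L, n_gem = 384L,
                                    n_i7 = 8L, min_dist = 3L) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  tn5 <- greedy_code(n_tn5, 8L, min_dist)
  wells <- paste0(rep(LETTERS[1:8], each = ceiling(n_tn5 / 8)),
                  rep(seq_len(ceiling(n_tn5 / 8)), 8))[seq_len(n_tn5)]
  names(tn5) <- wells
  gem <- greedy_code(n_gem, 16L, min_dist)
  i7 <- greedy_code(n_i7, 8L, min_dist)
  list(tn5 = barcode_whitelist(tn5, "tn5"),
       gem = barcode_whitelist(gem, "gem"),
       i7 = barcode_whitelist(i7, "i7"))
}

# toy genome sequences for the spec's contigs (deterministic in seed)
make_toy_genome <- function(spec) {
  set.seed(spec$seed + 104729L)
  seqs <- Biostrings::DNAStringSet(vapply(spec$genome_sizes, function(L)
    random_dna(1L, L), character(1)))
  names(seqs) <- names(spec$genome_sizes)
  seqs
}

inject_errors <- function(barcodes, error_rate) {
  if (error_rate == 0) return(barcodes)
  vapply(barcodes, function(bc) {
    ch <- strsplit(bc, "")[[1]]
    hit <- stats::runif(length(ch)) < error_rate
    if (any(hit))
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic sequencing run with planted barcode truth
#'
#' Writes the four FASTQ streams of a run (R1 genomic, R2 = 8 bp Tn5
#' barcode + 19 bp mosaic end + genomic, I1 = i7 index read, I2 = 16 bp
#' GEM barcode read) plus a truth table mapping every read id to its true
#' barcodes, species and cell. Substitution errors are injected into the
#' sequenced barcode copies at `spec$error_rate` per base; the truth table
#' always records the error-free assignment.
#'
#' @param spec a [fixture_spec()].
#' @param whitelists from [make_barcode_whitelists()].
#' @param out_dir output directory (created).
#' @param reads_per_cell mean reads per cell (default 20).
#' @param read_len genomic read length (default 50).
#' @param n_samples number of multiplexed samples; cells are split evenly
#'   across samples, each sample owning one i7 index and a disjoint block
#'   of Tn5 wells (default 2).
#' @return List with `files` (r1, r2, i1, i2, truth, sample_sheet paths),
#'   `truth` (data.frame) and `sample_sheet`.
#' @export
make_synthetic_run <- function(spec, whitelists, out_dir,
                               reads_per_cell = 20L, read_len = 50L,
                               n_samples = 2L) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)
  genome <- make_toy_genome(spec)
  species <- names(spec$genome_sizes)

  tn5 <- whitelists$tn5; gem <- whitelists$gem; i7 <- whitelists$i7
  n_wells <- length(tn5)
  wells_per_sample <- floor(n_wells / n_samples)
  sample_names <- paste0("sample", seq_len(n_samples))
  well_block <- lapply(seq_len(n_samples), function(s)
    names(tn5)[(s - 1L) * wells_per_sample + seq_len(wells_per_sample)])
  sample_sheet <- data.frame(
    sample = sample_names,
    i7 = as.character(i7)[seq_len(n_samples)],
    tn5_wells = vapply(well_block, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)

  # cells: unique (gem, tn5) combos within a sample
  n <- spec$n_cells
  cell_sample <- sample(rep_len(seq_len(n_samples), n))
  cell_well <- vapply(cell_sample, function(s) sample(well_block[[s]], 1L),
                      character(1))
  cell_gem <- sample(as.character(gem), n, replace = n > length(gem))
  cell_species <- sample(rep_len(species, n))
  cell_id <- paste0("cell", seq_len(n))

  n_reads_per_cell <- pmax(1L, stats::rpois(n, reads_per_cell))
  cell_of_read <- rep(seq_len(n), n_reads_per_cell)
  n_reads <- length(cell_of_read)
  read_id <- sprintf("read%06d", seq_len(n_reads))

  # genomic sequence drawn from the cell's species contig
  sp <- cell_species[cell_of_read]
  contig_len <- spec$genome_sizes[sp]
  starts <- floor(stats::runif(n_reads, 1, contig_len - read_len))
  genomic <- vapply(seq_len(n_reads), function(i)
    as.character(Biostrings::subseq(genome[[sp[i]]], starts[i],
                                    width = read_len)),
    character(1))

  true_tn5 <- as.character(tn5)[match(cell_well[cell_of_read], names(tn5))]
  true_gem <- cell_gem[cell_of_read]
  true_i7 <- sample_sheet$i7[cell_sample[cell_of_read]]

  obs_tn5 <- inject_errors(true_tn5, spec$error_rate)
  obs_gem <- inject_errors(true_gem, spec$error_rate)
  obs_i7 <- inject_errors(true_i7, spec$error_rate)

  q <- function(s) strrep("I", nchar(s))
  r2_seq <- paste0(obs_tn5, MOSAIC_END, genomic)
  files <- list(
    r1 = file.path(out_dir, "R1.fastq"), r2 = file.path(out_dir, "R2.fastq"),
    i1 = file.path(out_dir, "I1.fastq"), i2 = file.path(out_dir, "I2.fastq"),
    truth = file.path(out_dir, "truth.tsv"),
    sample_sheet = file.path(out_dir, "sample_sheet.tsv"))
  write_fastq(data.frame(id = read_id, seq = genomic, qual = q(genomic)),
              files$r1)
  write_fastq(data.frame(id = read_id, seq = r2_seq, qual = q(r2_seq)),
              files$r2)
  write_fastq(data.frame(id = read_id, seq = obs_i7, qual = q(obs_i7)),
              files$i1)
  write_fastq(data.frame(id = read_id, seq = obs_gem, qual = q(obs_gem)),
              files$i2)

  truth <- data.frame(
    read_id = read_id,
    cell = cell_id[cell_of_read],
    sample = sample_names[cell_sample[cell_of_read]],
    i7 = true_i7, gem = true_gem, tn5 = true_tn5,
    species = sp, stringsAsFactors = FALSE)
  utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sample_sheet, files$sample_sheet, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(files = files, truth = truth, sample_sheet = sample_sheet)
}

#' Generate a hybrid-genome fragments fixture with planted collisions
#'
#' Emulates a barnyard experiment: singlet barcodes draw at least 99% of
#' their fragments from their own species' contig; planted collision
#' barcodes mix the fragments of two cells (species drawn independently,
#' so roughly half of collisions are heterotypic at a 1:1 mix). The
#' read-depth distribution is a mixture of a log-normal cell mode and a
#' low-count debris mode, bimodal in log10 as assumed by k-means cell
#' thresholding.
#'
#' @param spec a [fixture_spec()]; `true_collision_fraction` of the cell
#'   barcodes are collisions.
#' @param cell_depth_log10,debris_depth_log10 mean log10 unique fragments
#'   for the cell and debris modes (defaults 3.3 and 2.0, i.e. ~2000 and
#'   ~100 fragments, so both modes straddle the k-means depth floor).
#' @param depth_sd_log10 log10 standard deviation of both modes (default
#'   0.25).
#' @param n_debris number of debris barcodes (default `2 * n_cells`).
#' @param purity fraction of a singlet's fragments from its own species
#'   (default 0.995).
#' @return List with `fragments` (data.table: chrom, start, end, barcode,
#'   dup_count = 1) and `truth` (data.frame: barcode, kind
#'   singlet/collision/debris, species label with `"collision"` for
#'   heterotypic mixes, n_fragments).
#' @export
make_hybrid_fragments <- function(spec, cell_depth_log10 = 3.3,
                                  debris_depth_log10 = 2.0,
                                  depth_sd_log10 = 0.25,
                                  n_debris = 2L * spec$n_cells,
                                  purity = 0.995) {
  stopifnot(inherits(spec, "fixture_spec"),
            length(spec$genome_sizes) == 2)
  set.seed(spec$seed + 2L)
  species <- names(spec$genome_sizes)
  n_coll <- round(spec$true_collision_fraction * spec$n_cells)
  n_sing <- spec$n_cells - n_coll

  draw_frags <- function(sp_vec, n_frag, barcode) {
    # sp_vec: per-fragment species
    L <- spec$genome_sizes[sp_vec]
    width <- pmin(2000L, 50L + stats::rgeom(n_frag, 1 / 150))
    start <- floor(stats::runif(n_frag, 0, L - width - 1))
    data.table::data.table(chrom = sp_vec, start = as.integer(start),
                           end = as.integer(start + width),
                           barcode = barcode, dup_count = 1L)
  }
  mix_species <- function(main, n_frag) {
    swap <- stats::runif(n_frag) >= purity
    out <- rep(main, n_frag)
    out[swap] <- sample(species, sum(swap), replace = TRUE)
    out
  }

  frags <- list(); truth <- list()
  depth <- function(n, mu) pmax(5L, round(10^stats::rnorm(n, mu, depth_sd_log10)))
  pfx <- function(s) sub("_.*$", "", s)   # truth uses the species prefix

  sing_sp <- sample(rep_len(species, n_sing))
  sing_depth <- depth(n_sing, cell_depth_log10)
  for (i in seq_len(n_sing)) {
    bc <- sprintf("SING%04d", i)
    frags[[bc]] <- draw_frags(mix_species(sing_sp[i], sing_depth[i]),
                              sing_depth[i], bc)
    truth[[bc]] <- data.frame(barcode = bc, kind = "singlet",
                              species = pfx(sing_sp[i]),
                              n_fragments = sing_depth[i])
  }
  if (n_coll > 0) {
    coll_sp1 <- sample(species, n_coll, replace = TRUE)
    coll_sp2 <- sample(species, n_coll, replace = TRUE)
    coll_depth <- depth(n_coll, cell_depth_log10 + log10(2))
    for (i in seq_len(n_coll)) {
      bc <- sprintf("COLL%04d", i)
      n1 <- round(coll_depth[i] / 2); n2 <- coll_depth[i] - n1
      sp_vec <- c(mix_species(coll_sp1[i], n1), mix_species(coll_sp2[i], n2))
      frags[[bc]] <- draw_frags(sp_vec, length(sp_vec), bc)
      truth[[bc]] <- data.frame(
        barcode = bc, kind = "collision",
        species = if (coll_sp1[i] == coll_sp2[i]) pfx(coll_sp1[i]) else "collision",
        n_fragments = coll_depth[i])
    }
  }
  if (n_debris > 0) {
    deb_sp <- sample(species, n_debris, replace = TRUE)
    deb_depth <- depth(n_debris, debris_depth_log10)
    for (i in seq_len(n_debris)) {
      bc <- sprintf("DEBR%04d", i)
      frags[[bc]] <- draw_frags(mix_species(deb_sp[i], deb_depth[i]),
                                deb_depth[i], bc)
      truth[[bc]] <- data.frame(barcode = bc, kind = "debris",
                                species = pfx(deb_sp[i]),
                                n_fragments = deb_depth[i])
    }
  }
  fragments <- data.table::rbindlist(frags)
  data.table::setorder(fragments, chrom, start, end, barcode)
  list(fragments = fragments,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate a binarized cells-by-peaks matrix with planted doublets
#'
#' Singlet cells belong to one of `n_clusters` planted clusters, each with
#' a distinct high-accessibility peak block (Bernoulli `p_high` inside the
#' block, `p_low` outside). Doublets are the element-wise OR of two
#' singlet profiles drawn from distinct clusters.
#'
#' @param spec a [fixture_spec()] (`n_peaks >= 50`); `doublet_fraction`
#'   of the `n_cells` are doublets.
#' @param n_clusters planted clusters (default 3; at toy scale a few
#'   well-separated states keep the simulated doublet-score distribution
#'   bimodal -- see the methods vignette on how cluster count interacts
#'   with the mixture threshold).
#' @param p_high,p_low within/outside-block accessibility probabilities
#'   (defaults 0.4 and 0.02).
#' @return List with `matrix` (sparse binary cells x peaks) and `truth`
#'   (data.frame: barcode, is_doublet, cluster; doublets carry
#'   `"doublet"`).
#' @export
make_count_matrix <- function(spec, n_clusters = 3L, p_high = 0.4,
                              p_low = 0.02) {
  stopifnot(inherits(spec, "fixture_spec"), spec$n_peaks >= 50)
  set.seed(spec$seed + 3L)
  n <- spec$n_cells
  n_dbl <- round(spec$doublet_fraction * n)
  n_sing <- n - n_dbl
  blocks <- split(seq_len(spec$n_peaks),
                  rep_len(seq_len(n_clusters), spec$n_peaks))

  profile <- function(cl) {
    p <- rep(p_low, spec$n_peaks)
    p[blocks[[cl]]] <- p_high
    as.integer(stats::runif(spec$n_peaks) < p)
  }
  cl_sing <- sample(rep_len(seq_len(n_clusters), n_sing))
  m_sing <- t(vapply(cl_sing, profile, integer(spec$n_peaks)))
  if (n_dbl > 0) {
    pairs <- t(vapply(seq_len(n_dbl), function(i) {
      cls <- sample(seq_len(n_clusters), 2L)   # distinct clusters
      cls
    }, integer(2)))
    m_dbl <- t(vapply(seq_len(n_dbl), function(i)
      as.integer(profile(pairs[i, 1]) | profile(pairs[i, 2])),
      integer(spec$n_peaks)))
    m <- rbind(m_sing, m_dbl)
  } else m <- m_sing
  rownames(m) <- sprintf("BC%04d", seq_len(n))
  colnames(m) <- sprintf("peak%04d", seq_len(spec$n_peaks))
  truth <- data.frame(
    barcode = rownames(m),
    is_doublet = c(rep(FALSE, n_sing), rep(TRUE, n_dbl)),
    cluster = c(as.character(cl_sing), rep("doublet", n_dbl)),
    stringsAsFactors = FALSE)
  list(matrix = methods::as(Matrix::Matrix(m, sparse = TRUE),
                            "CsparseMatrix"),
       truth = truth)
}

# a sharp PFM whose consensus scores far above the 1e-4 threshold and any
# single high-information mismatch scores below it
sharp_pfm <- function(consensus, counts = 997L) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(1, 4, nchar(consensus), dimnames = list(bases, NULL))
  idx <- match(strsplit(consensus, "")[[1]], bases)
  m[cbind(idx, seq_along(idx))] <- counts
  m
}

mutate_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Generate a motif-analysis fixture with a planted functional motif
#'
#' Builds peak sequences, a three-replicate VCF of SNVs, a JASPAR-format
#' PFM set and a differential-peak table such that the first motif is
#' functional in the requested direction: in "gain" peaks an SNV converts
#' a one-mismatch site into the motif consensus (match gained in the
#' alternative sequence), in "loss" peaks an SNV destroys an embedded
#' consensus. Gained peaks draw log2 fold-changes from
#' `N(+effect, sd)` and lost peaks from `N(-effect, sd)` for an opening
#' motif (signs flipped for closing). The second motif is planted as a
#' zero-effect control: it receives the same number of SNV-driven gains
#' and losses on other peaks, but those peaks keep null `N(0, sd)`
#' fold-changes. Remaining motifs have no planted events at all.
#'
#' @param spec a [fixture_spec()] (`n_motifs >= 2`).
#' @param n_gain,n_loss planted gain/loss peaks (defaults 25 each).
#' @param effect,sd planted log2FC shift and noise (defaults 1.5, 0.5).
#' @param peak_len peak sequence length (default 200).
#' @param direction `"opening"` (default) or `"closing"`.
#' @param out_dir optional directory; when given, writes `peaks.fa`,
#'   `snvs.vcf`, `motifs.jaspar`, `diff_peaks.tsv`.
#' @return List with `sequences` (DNAStringSet named `chrom:start-end`),
#'   `snvs`, `pfms`, `diff_peaks`, `truth` (functional motif id,
#'   direction, gain/loss peak names) and `files` (when written).
#' @export
make_motif_dataset <- function(spec, n_gain = 25L, n_loss = 25L,
                               effect = 1.5, sd = 0.5, peak_len = 200L,
                               direction = c("opening", "closing"),
                               out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), spec$n_motifs >= 2,
            spec$n_peaks >= 2L * (n_gain + n_loss) + 10L)
  direction <- match.arg(direction)
  set.seed(spec$seed + 4L)
  bases <- c("A", "C", "G", "T")

  consensus <- vapply(seq_len(spec$n_motifs), function(i)
    paste(sample(bases, 8L, replace = TRUE), collapse = ""), character(1))
  pfms <- lapply(consensus, sharp_pfm)
  names(pfms) <- sprintf("MT%04d", seq_len(spec$n_motifs))
  func_motif <- names(pfms)[1]
  neutral_motif <- names(pfms)[2]
  w <- nchar(consensus[1])

  n_pk <- spec$n_peaks
  chrom <- "mm_toy"
  starts <- seq(1L, by = peak_len + 100L, length.out = n_pk)
  peak_names <- sprintf("%s:%d-%d", chrom, starts, starts + peak_len - 1L)
  seqs <- random_dna(n_pk, peak_len)
  # scrub spontaneous matches to the planted consensi so planted events
  # are the only ones (both strands)
  scrub <- c(consensus[1:2],
             vapply(consensus[1:2], function(cs)
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(cs))), character(1)))
  for (i in seq_len(n_pk)) {
    repeat {
      pos <- -1L
      for (pat in scrub) {
        hit <- regexpr(pat, seqs[i], fixed = TRUE)
        if (hit > 0) { pos <- as.integer(hit); break }
      }
      if (pos < 0) break
      substr(seqs[i], pos, pos) <- mutate_base(substr(seqs[i], pos, pos))
    }
  }
  names(seqs) <- peak_names

  # peak roles: functional gains/losses, neutral gains/losses (no log2FC
  # association), and untouched nulls
  kind <- rep("null", n_pk)
  kind[seq_len(n_gain)] <- "gain"
  kind[n_gain + seq_len(n_loss)] <- "loss"
  kind[n_gain + n_loss + seq_len(n_gain)] <- "neutral_gain"
  kind[2L * n_gain + n_loss + seq_len(n_loss)] <- "neutral_loss"
  kind <- sample(kind)                      # shuffle placement
  gain_idx <- which(kind == "gain"); loss_idx <- which(kind == "loss")

  snvs <- list()
  plant_gain <- function(i, cons) {
    # embed consensus with one mismatch; SNV restores the consensus
    pos <- sample(seq_len(peak_len - w + 1L), 1L)
    mism <- sample(seq_len(w), 1L)
    site <- cons
    ref_base <- mutate_base(substr(cons, mism, mism))
    substr(site, mism, mism) <- ref_base
    substr(seqs[i], pos, pos + w - 1L) <<- site
    data.frame(chrom = chrom, pos = starts[i] + pos + mism - 2L,
               ref = ref_base, alt = substr(cons, mism, mism))
  }
  plant_loss <- function(i, cons) {
    # embed exact consensus; SNV destroys it
    pos <- sample(seq_len(peak_len - w + 1L), 1L)
    substr(seqs[i], pos, pos + w - 1L) <<- cons
    mism <- sample(seq_len(w), 1L)
    ref_base <- substr(cons, mism, mism)
    data.frame(chrom = chrom, pos = starts[i] + pos + mism - 2L,
               ref = ref_base, alt = mutate_base(ref_base))
  }
  for (i in gain_idx) snvs[[length(snvs) + 1L]] <- plant_gain(i, consensus[1])
  for (i in loss_idx) snvs[[length(snvs) + 1L]] <- plant_loss(i, consensus[1])
  for (i in which(kind == "neutral_gain"))
    snvs[[length(snvs) + 1L]] <- plant_gain(i, consensus[2])
  for (i in which(kind == "neutral_loss"))
    snvs[[length(snvs) + 1L]] <- plant_loss(i, consensus[2])
  snvs <- do.call(rbind, snvs)

  sgn <- if (direction == "opening") 1 else -1
  log2fc <- stats::rnorm(n_pk, 0, sd)
  log2fc[gain_idx] <- stats::rnorm(n_gain, sgn * effect, sd)
  log2fc[loss_idx] <- stats::rnorm(n_loss, -sgn * effect, sd)
  diff_peaks <- data.frame(peak = peak_names, cell_type = "toy",
                           log2fc = log2fc,
                           fdr = stats::runif(n_pk, 0, 0.05),
                           stringsAsFactors = FALSE)

  out <- list(sequences = Biostrings::DNAStringSet(seqs), snvs = snvs,
              pfms = pfms, diff_peaks = diff_peaks,
              truth = list(functional_motif = func_motif,
                           neutral_motif = neutral_motif,
                           direction = direction,
                           gain_peaks = peak_names[gain_idx],
                           loss_peaks = peak_names[loss_idx],
                           neutral_gain_peaks = peak_names[kind == "neutral_gain"],
                           neutral_loss_peaks = peak_names[kind == "neutral_loss"]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(fasta = file.path(out_dir, "peaks.fa"),
                  vcf = file.path(out_dir, "snvs.vcf"),
                  pfms = file.path(out_dir, "motifs.jaspar"),
                  diff = file.path(out_dir, "diff_peaks.tsv"))
    Biostrings::writeXStringSet(out$sequences, files$fasta)
    write_toy_vcf(snvs, files$vcf)
    write_jaspar_pfms(pfms, files$pfms)
    utils::write.table(diff_peaks, files$diff, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- files
  }
  out
}

#' Write a minimal three-replicate VCF 4.2 for fixture SNVs
#'
#' Each SNV gets QUAL 60, concordant `1/1` genotypes and DP 10 per
#' replicate, i.e. every record passes the default [filter_snvs()] rules.
#' Optional columns `qual`, `gt1`..`gt3`, `dp1`..`dp3` in `snvs` override
#' the defaults per record.
#'
#' @param snvs data.frame with `chrom`, `pos`, `ref`, `alt` and optional
#'   override columns.
#' @param path output VCF path.
#' @export
write_toy_vcf <- function(snvs, path) {
  n <- nrow(snvs)
  get <- function(col, default) if (col %in% names(snvs)) snvs[[col]]
                                else rep(default, n)
  qual <- get("qual", 60)
  gt <- cbind(get("gt1", "1/1"), get("gt2", "1/1"), get("gt3", "1/1"))
  dp <- cbind(get("dp1", 10L), get("dp2", 10L), get("dp3", 10L))
  chroms <- unique(snvs$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chroms, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "rep1", "rep2", "rep3", sep = "\t"))
  body <- vapply(seq_len(n), function(i) paste(
    snvs$chrom[i], snvs$pos[i], ".", snvs$ref[i], snvs$alt[i],
    format(qual[i]), "PASS", ".", "GT:DP",
    paste0(gt[i, 1], ":", dp[i, 1]), paste0(gt[i, 2], ":", dp[i, 2]),
    paste0(gt[i, 3], ":", dp[i, 3]), sep = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a SAM file of proper read pairs for fragment fixtures
#'
#' Emits one proper pair per fragment row (flags 99/147, MAPQ
#' configurable), with the combined barcode appended to the read name
#' after `:`. Convert with [Rsamtools::asBam()] for BAM-based tests.
#'
#' @param fragments data.frame with `chrom`, `start`, `end`, `barcode`
#'   (BED half-open coordinates) and optional `mapq` column.
#' @param contig_lengths named vector of contig lengths for the header.
#' @param path output SAM path.
#' @param read_len nominal read length (default 50; pairs shorter than
#'   `2 * read_len` get mates covering the whole fragment).
#' @export
write_toy_sam <- function(fragments, contig_lengths, path, read_len = 50L) {
  fr <- as.data.frame(fragments)
  mapq <- if ("mapq" %in% names(fr)) fr$mapq else rep(60L, nrow(fr))
  rl <- pmin(read_len, fr$end - fr$start)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(contig_lengths),
                     "\tLN:", contig_lengths))
  qname <- sprintf("frag%06d:%s", seq_len(nrow(fr)), fr$barcode)
  pos1 <- fr$start + 1L                     # SAM is 1-based
  pos2 <- fr$end - rl + 1L
  isize <- fr$end - fr$start
  seq1 <- strrep("A", rl); qual1 <- strrep("I", rl)
  cig <- paste0(rl, "M")
  r1 <- paste(qname, 99L, fr$chrom, pos1, mapq, cig, "=", pos2, isize,
              seq1, qual1, sep = "\t")
  r2 <- paste(qname, 147L, fr$chrom, pos2, mapq, cig, "=", pos1, -isize,
              seq1, qual1, sep = "\t")
  writeLines(c(header, as.vector(rbind(r1, r2))), path)
  invisible(path)
}
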