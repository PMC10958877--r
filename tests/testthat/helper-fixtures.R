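# Shared fixtures, generated once per test run and cached. All fixture
# content is deterministic in the spec seed, so caching does not couple
# tests.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fx_cache))
    assign(key, force(expr), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

toy_whitelists <- function() cached("wl", {
  make_barcode_whitelists(fixture_spec(seed = 1), n_gem = 64)
})

toy_run <- function(error_rate = 0) {
  key <- paste0("run", error_rate)
  cached(key, {
    spec <- fixture_spec(seed = 7, n_cells = 50, error_rate = error_rate)
    dir <- file.path(tempdir(), paste0("toyrun_", error_rate * 100))
    make_synthetic_run(spec, toy_whitelists(), dir)
  })
}

toy_barnyard <- function() cached("barnyard", {
  spec <- fixture_spec(seed = 3, n_cells = 100, true_collision_fraction = 0.1)
  make_hybrid_fragments(spec, n_debris = 200)
})

toy_matrix <- function() cached("matrix", {
  spec <- fixture_spec(seed = 1, n_cells = 500, doublet_fraction = 0.1,
                       n_peaks = 300)
  make_count_matrix(spec)
})

toy_motifs <- function() cached("motifs", {
  spec <- fixture_spec(seed = 5, n_cells = 50, n_peaks = 120, n_motifs = 6)
  dir <- file.path(tempdir(), "toymotifs")
  make_motif_dataset(fixture_spec(seed = 5, n_cells = 50, n_peaks = 120,
                                  n_motifs = 6), out_dir = dir)
})

read_fastq_seqs <- function(path) txcitools:::read_fastq(path)$seq
read_fastq_ids <- function(path) txcitools:::read_fastq(path)$id

# independent brute-force Hamming distance (character-by-character loop)
slow_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force PWM threshold: enumerate all 4^w windows, score with the
# (quantized) PWM, accumulate exact background probabilities per unique
# score (ties must move as a block), and return the smallest score whose
# tail probability P(score >= s) <= p.
brute_force_threshold <- function(pwm_q, background, p_value, gran = 0.01) {
  w <- ncol(pwm_q)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  si <- rowSums(matrix(round(pwm_q / gran)[cbind(
    as.vector(grid), rep(seq_len(w), each = nrow(grid)))],
    nrow = nrow(grid)))
  probs <- apply(grid, 1, function(g) prod(background[g]))
  agg <- tapply(probs, si, sum)
  u <- as.integer(names(agg))
  o <- order(u, decreasing = TRUE)
  tail_p <- cumsum(agg[o])
  ok <- which(tail_p <= p_value + 1e-12)
  if (!length(ok)) return(Inf)
  min(u[o][ok]) * gran
}
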