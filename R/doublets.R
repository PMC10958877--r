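# Simulated-doublet detection on a binarized peak-by-cell matrix:
# log(TF x IDF) normalization, PCA fit on observed cells, projection of
# simulated doublets, L2 normalization, k-nearest-neighbor doublet scores
# with the adjusted neighbor count k_adj, and a two-component Gaussian
# mixture threshold on the simulated scores. Matrices are cells x peaks
# (cells in rows).

#' Build and filter a binarized cells-by-peaks matrix
#'
#' Entry (i, j) is 1 iff at least one fragment of cell i overlaps peak j.
#' Low-support features and cells are removed: peaks present in fewer than
#' `min_cells` cells are dropped first, then cells with fewer than
#' `min_features` remaining peaks.
#'
#' @param x either a cells-by-peaks matrix (coerced to sparse binary) or a
#'   fragments table, in which case `peaks` must be supplied.
#' @param peaks `GRanges` or BED-convention data.frame of merged,
#'   blacklist-free peaks (only used when `x` is a fragments table).
#' @param min_cells minimum cells per retained peak (default 50).
#' @param min_features minimum peaks per retained cell (default 200).
#' @return Sparse `dgCMatrix` (cells x peaks, 0/1) with dimnames, plus a
#'   `provenance` attribute recording the filters applied.
#' @export
binarize_matrix <- function(x, peaks = NULL, min_cells = 50L,
                            min_features = 200L) {
  if (is.data.frame(x) || data.table::is.data.table(x)) {
    stopifnot(!is.null(peaks))
    if (!inherits(peaks, "GRanges")) {
      pk <- as.data.frame(peaks)
      peaks <- GenomicRanges::GRanges(
        pk$chrom, IRanges::IRanges(start = pk$start + 1L, end = pk$end))
    }
    gr <- fragments_granges(x)
    ov <- GenomicRanges::findOverlaps(gr, peaks)
    cells <- sort(unique(x$barcode))
    i <- match(x$barcode[S4Vectors::queryHits(ov)], cells)
    j <- S4Vectors::subjectHits(ov)
    m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(cells), length(peaks)),
                              dimnames = list(cells, paste0("peak", seq_along(peaks))))
  } else {
    m <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
    if (is.null(rownames(m))) rownames(m) <- paste0("cell", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("peak", seq_len(ncol(m)))
  }
  m@x[m@x > 0] <- 1                                # binarize
  n0 <- dim(m)
  keep_peaks <- Matrix::colSums(m) >= min_cells    # peak filter first
  m <- m[, keep_peaks, drop = FALSE]
  keep_cells <- Matrix::rowSums(m) >= min_features
  m <- m[keep_cells, , drop = FALSE]
  if (nrow(m) == 0 || ncol(m) == 0)
    stop(sprintf(
      "empty matrix after filtering (input %d cells x %d peaks; %d peaks and %d cells removed)",
      n0[1], n0[2], sum(!keep_peaks), sum(!keep_cells)))
  attr(m, "provenance") <- list(min_cells = min_cells,
                                min_features = min_features,
                                input_dim = n0,
                                peaks_removed = sum(!keep_peaks),
                                cells_removed = sum(!keep_cells))
  m
}

#' log(TF x IDF) normalization
#'
#' Term frequency is each cell's row divided by its total; inverse document
#' frequency of peak j is `n_cells / n_cells_with_peak_j`. The default
#' variant returns `log(1 + s * TF * IDF)` with scale `s = 1e4`; the raw
#' variant returns `log(TF * IDF)` evaluated only on nonzero entries.
#'
#' @param m binary cells-by-peaks matrix (no zero rows or columns).
#' @param idf optional IDF vector to reuse (e.g. the observed matrix's IDF
#'   when transforming simulated doublets); default computes from `m`.
#' @param scale_factor scale `s` inside `log1p` (default 1e4).
#' @param variant `"log1p_scaled"` (default) or `"raw_log"`.
#' @return Dense numeric matrix of the same dimensions, with an `idf`
#'   attribute.
#' @export
tfidf_log <- function(m, idf = NULL, scale_factor = 1e4,
                      variant = c("log1p_scaled", "raw_log")) {
  variant <- match.arg(variant)
  rs <- Matrix::rowSums(m)
  if (any(rs == 0)) stop("zero rows present; filter cells first")
  if (is.null(idf)) {
    df <- Matrix::colSums(m > 0)
    if (any(df == 0)) stop("zero columns present; filter peaks first")
    idf <- nrow(m) / df
  }
  stopifnot(length(idf) == ncol(m))
  tf <- as.matrix(m / rs)
  x <- sweep(tf, 2L, idf, "*")
  out <- if (variant == "log1p_scaled") log1p(scale_factor * x) else {
    y <- x
    y[y > 0] <- log(y[y > 0])
    y
  }
  attr(out, "idf") <- idf
  out
}

#' Simulate doublet profiles from observed cells
#'
#' Creates `floor(n_cells / 2)` synthetic doublets, each the binarized sum
#' (element-wise OR) of two distinct randomly sampled observed cells.
#'
#' @param m binary cells-by-peaks matrix with at least 4 cells.
#' @param seed RNG seed.
#' @return List with `matrix` (binary doublets x peaks) and `parents`
#'   (two-column matrix of parent row indices).
#' @export
simulate_doublets <- function(m, seed = 1L) {
  n <- nrow(m)
  stopifnot(n >= 4)
  set.seed(as.integer(seed))
  n_sim <- floor(n / 2)
  p1 <- sample.int(n, n_sim, replace = TRUE)
  p2 <- vapply(p1, function(i) {
    j <- sample.int(n, 1L)
    while (j == i) j <- sample.int(n, 1L)
    j
  }, integer(1))
  sim <- m[p1, , drop = FALSE] + m[p2, , drop = FALSE]
  sim@x[sim@x > 0] <- 1
  rownames(sim) <- paste0("sim", seq_len(n_sim))
  list(matrix = sim, parents = cbind(p1, p2))
}

# k-nearest neighbors among rows of `x` for the rows indexed by `query`,
# excluding self; returns index matrix (length(query) x k). Exact search
# on the full Euclidean distance matrix -- fine at the scales this
# package targets (a few thousand cells).
knn_indices <- function(x, query, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d[query, , drop = FALSE], 1L, function(row)
    order(row)[seq_len(k)]))
}

#' Embed observed and simulated cells and score doublets
#'
#' Fits a `n_components` PCA on the TF-IDF transform of the observed
#' matrix, transforms the simulated doublets with the observed IDF and
#' projects them into the same space, L2-normalizes all embeddings, and
#' computes each observed cell's doublet score from the fraction of
#' simulated doublets among its `k_adj` nearest neighbors (components 2 to
#' `n_components` are used for the neighbor search). With
#' `r = n_sim / n_obs`, `k = round(0.5 sqrt(n_obs))` and
#' `k_adj = round(k (1 + r))`, the pseudo-counted neighbor fraction is
#' `q = (n_sim_neighbors + 1) / (k_adj + 2)` and the score is the Bayesian
#' doublet posterior
#' `score = (q rho / r) / (1 - q + q rho / r)`
#' for expected doublet rate `rho`.
#'
#' @param obs binary observed matrix from [binarize_matrix()].
#' @param sim simulated doublet matrix from [simulate_doublets()].
#' @param n_components PCA components (default 30; reduced with a warning
#'   if the matrix rank is lower).
#' @param rho expected doublet rate (default 0.1).
#' @param variant TF-IDF variant, see [tfidf_log()].
#' @return List with `scores` (data.frame for observed cells: `barcode`,
#'   `q`, `score`, `k_adj`), `sim_scores` (same for simulated doublets) and
#'   `embedding`.
#' @export
embed_and_score <- function(obs, sim, n_components = 30L, rho = 0.1,
                            variant = "log1p_scaled") {
  n_obs <- nrow(obs); n_sim <- nrow(sim)
  r <- n_sim / n_obs
  obs_t <- tfidf_log(obs, variant = variant)
  sim_t <- tfidf_log(sim, idf = attr(obs_t, "idf"), variant = variant)

  max_rank <- min(dim(obs_t)) - 1L
  if (n_components > max_rank) {
    warning("n_components reduced to matrix rank limit ", max_rank)
    n_components <- max_rank
  }
  pca <- stats::prcomp(obs_t, center = TRUE, scale. = FALSE,
                       rank. = n_components)
  obs_emb <- pca$x
  sim_emb <- scale(sim_t, center = pca$center, scale = FALSE) %*% pca$rotation

  emb <- rbind(obs_emb, sim_emb)
  norms <- sqrt(rowSums(emb^2))
  norms[norms == 0] <- 1
  emb <- emb / norms                                # L2 row normalization

  dims <- seq(2L, n_components)                     # drop depth component
  k <- round(0.5 * sqrt(n_obs))
  k_adj <- round(k * (1 + r))
  is_sim <- c(rep(FALSE, n_obs), rep(TRUE, n_sim))
  nn <- knn_indices(emb[, dims, drop = FALSE], seq_len(n_obs + n_sim), k_adj)
  n_sim_nb <- rowSums(matrix(is_sim[nn], nrow = nrow(nn)))
  q <- (n_sim_nb + 1) / (k_adj + 2)
  score <- (q * rho / r) / (1 - q + q * rho / r)

  mk <- function(sel, names) data.frame(
    barcode = names, q = q[sel], score = score[sel], k_adj = k_adj,
    stringsAsFactors = FALSE)
  list(scores = mk(seq_len(n_obs), rownames(obs)),
       sim_scores = mk(n_obs + seq_len(n_sim), rownames(sim)),
       embedding = emb)
}

# two-component 1-D Gaussian mixture fit by EM with quantile-pair and
# random restarts. Doublet scores are discrete (q has k_adj + 2 levels),
# so an unconstrained Gaussian mixture can collapse a component onto a
# repeated value (unbounded likelihood); a variance floor relative to the
# overall score spread keeps the fit proper. Returns
# list(mu, sigma, pi, loglik).
fit_gmm2 <- function(x, n_restarts = 10L, seed = 1L, max_iter = 200L,
                     tol = 1e-8, sigma_floor = 0.05 * stats::sd(x)) {
  set.seed(as.integer(seed))
  sigma_floor <- max(sigma_floor, 1e-8)
  inits <- c(list(stats::quantile(x, c(0.10, 0.60), names = FALSE),
                  stats::quantile(x, c(0.25, 0.75), names = FALSE),
                  stats::quantile(x, c(0.05, 0.50), names = FALSE)),
             lapply(seq_len(n_restarts), function(i) sort(sample(x, 2L))))
  best <- NULL
  for (mu in inits) {
    if (diff(mu) == 0) mu <- mu + c(-1e-3, 1e-3)
    sg <- rep(stats::sd(x) + 1e-6, 2L)
    pi_k <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- pi_k[1] * stats::dnorm(x, mu[1], sg[1])
      d2 <- pi_k[2] * stats::dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      g <- d2 / tot
      ll <- sum(log(tot))
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
      pi_k <- c(mean(1 - g), mean(g))
      pi_k <- pmin(pmax(pi_k, 1e-6), 1 - 1e-6)
      mu <- c(sum((1 - g) * x) / sum(1 - g), sum(g * x) / sum(g))
      sg <- sqrt(c(sum((1 - g) * (x - mu[1])^2) / sum(1 - g),
                   sum(g * (x - mu[2])^2) / sum(g)))
      sg <- pmax(sg, sigma_floor)
    }
    if (is.null(best) || ll > best$loglik)
      best <- list(mu = mu, sigma = sg, pi = pi_k, loglik = ll)
  }
  o <- order(best$mu)
  list(mu = best$mu[o], sigma = best$sigma[o], pi = best$pi[o],
       loglik = best$loglik)
}

#' Threshold doublet scores on the simulated-score mixture
#'
#' Fits a two-component Gaussian mixture to the simulated doublet scores
#' (EM, 10 restarts). The lower-mean component corresponds to "embedded"
#' doublets of similar parents, the higher-mean component to "neotypic"
#' doublets of dissimilar parents. The threshold is the smallest simulated
#' score whose posterior membership in the higher-mean component is at
#' least `1 - max_uncertainty` (default 0.95). Observed cells scoring at
#' or above the threshold are flagged as doublets. If the mixture is
#' degenerate (components indistinguishable) the 95th percentile of the
#' simulated scores is used instead, with a warning.
#'
#' @param sim_scores numeric vector of simulated doublet scores (>= 50).
#' @param obs_scores optional data.frame from [embed_and_score()]
#'   (`$scores`); when supplied, per-cell calls are returned.
#' @param max_uncertainty maximum classification uncertainty (default
#'   0.05).
#' @param seed RNG seed for the EM restarts.
#' @return List with `threshold`, `mixture` (fit parameters), `fallback`
#'   (logical), and when `obs_scores` is given, `calls` (data.frame with
#'   `barcode`, `score`, `is_doublet`).
#' @export
threshold_scores <- function(sim_scores, obs_scores = NULL,
                             max_uncertainty = 0.05, seed = 1L) {
  x <- as.numeric(sim_scores)
  stopifnot(length(x) >= 50)
  fallback <- FALSE
  fit <- NULL
  if (length(unique(x)) < 3) {
    fallback <- TRUE
  } else {
    fit <- fit_gmm2(x, seed = seed)
    sep <- abs(diff(fit$mu)) / sqrt(mean(fit$sigma^2))
    if (!is.finite(sep) || sep < 0.5 || min(fit$pi) < 1e-3) fallback <- TRUE
  }
  if (fallback) {
    warning("degenerate score mixture; falling back to 95th-percentile threshold")
    threshold <- stats::quantile(x, 0.95, names = FALSE)
  } else {
    post_hi <- function(s) {
      d1 <- fit$pi[1] * stats::dnorm(s, fit$mu[1], fit$sigma[1])
      d2 <- fit$pi[2] * stats::dnorm(s, fit$mu[2], fit$sigma[2])
      d2 / (d1 + d2)
    }
    # smallest score (on a fine grid between the component means) whose
    # posterior membership in the neotypic component reaches the target
    grid <- seq(fit$mu[1], max(fit$mu[2], max(x)), length.out = 10001L)
    cand <- grid[post_hi(grid) >= 1 - max_uncertainty]
    threshold <- if (length(cand)) cand[1] else max(x) + 1e-9
  }
  out <- list(threshold = threshold, mixture = fit, fallback = fallback)
  if (!is.null(obs_scores)) {
    out$calls <- data.frame(barcode = obs_scores$barcode,
                            score = obs_scores$score,
                            is_doublet = obs_scores$score >= threshold,
                            stringsAsFactors = FALSE)
  }
  out
}

#' End-to-end doublet detection pipeline
#'
#' Runs [simulate_doublets()], [embed_and_score()] and
#' [threshold_scores()] on a filtered binary matrix.
#'
#' @param m binary cells-by-peaks matrix (already filtered, e.g. by
#'   [binarize_matrix()]).
#' @param seed RNG seed for the whole pipeline.
#' @param rho expected doublet rate (default 0.1).
#' @param n_components PCA components (default 30).
#' @return List with `calls`, `threshold`, `scores`, `sim_scores`,
#'   `fallback`.
#' @export
detect_doublets <- function(m, seed = 1L, rho = 0.1, n_components = 30L) {
  sim <- simulate_doublets(m, seed = seed)
  sc <- embed_and_score(m, sim$matrix, n_components = n_components, rho = rho)
  th <- threshold_scores(sc$sim_scores$score, sc$scores, seed = seed)
  list(calls = th$calls, threshold = th$threshold, scores = sc$scores,
       sim_scores = sc$sim_scores, fallback = th$fallback)
}

#' Write / read a binary matrix in MatrixMarket exchange form
#'
#' @param m sparse binary matrix with dimnames.
#' @param dir output directory; writes `matrix.mtx`, `barcodes.tsv`,
#'   `peaks.tsv`.
#' @return The directory path, invisibly.
#' @export
write_matrix_dir <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(m), file.path(dir, "peaks.tsv"))
  invisible(dir)
}

#' @rdname write_matrix_dir
#' @param dir directory written by [write_matrix_dir()].
#' @export
read_matrix_dir <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m * 1, "CsparseMatrix")   # pattern/logical -> numeric
  dimnames(m) <- list(readLines(file.path(dir, "barcodes.tsv")),
                      readLines(file.path(dir, "peaks.tsv")))
  m
}
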