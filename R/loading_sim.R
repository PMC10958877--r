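#' Poisson droplet-loading model
#'
#' Constructs the droplet-loading model used to compare molecular hashing
#' (Tn5 pre-indexing with `m` plate barcodes, so multi-cell droplets remain
#' deconvolutable) against cellular hashing (droplets with more than one
#' cell must be discarded). Nuclei are captured into `D` bead-containing
#' droplets after a fixed capture-loss fraction, so the mean occupancy is
#' `lambda = N / D * (1 - loss)`.
#'
#' @param N nuclei loaded on the lane (loading input).
#' @param D number of bead-containing droplets formed (default 100,000).
#' @param loss capture loss fraction in `[0, 1)` (default 0.35): dead
#'   volume, bursting and empty-droplet encapsulation.
#' @param m number of pre-index Tn5 barcodes; `NULL` selects the cellular
#'   hashing model (no molecular pre-index).
#' @param p_max per-droplet duplicate-barcode tolerance: droplets whose
#'   probability of carrying at least one duplicated Tn5 barcode exceeds
#'   `p_max` are discarded as undemultiplexable (default 0.10).
#' @return An object of class `droplet_model`: a list with fields `N`, `D`,
#'   `loss`, `lambda`, `m`, `p_max` and `strategy`
#'   (`"molecular"`/`"cellular"`).
#' @examples
#' droplet_model(100000)            # cellular hashing, lambda = 0.65
#' droplet_model(470000, m = 96)    # molecular hashing with 96 barcodes
#' @export
droplet_model <- function(N, D = 100000, loss = 0.35, m = NULL, p_max = 0.10) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 0,
            is.numeric(D), D > 0,
            is.numeric(loss), loss >= 0, loss < 1,
            is.numeric(p_max), p_max > 0, p_max <= 1)
  if (!is.null(m)) stopifnot(is.numeric(m), length(m) == 1L, m >= 1)
  structure(list(
    N = N, D = D, loss = loss,
    lambda = N / D * (1 - loss),
    m = m, p_max = p_max,
    strategy = if (is.null(m)) "cellular" else "molecular"
  ), class = "droplet_model")
}

#' @export
print.droplet_model <- function(x, ...) {
  cat(sprintf("droplet_model: %s hashing\n", x$strategy))
  cat(sprintf("  N = %g nuclei, D = %g droplets, loss = %.2f, lambda = %.4f\n",
              x$N, x$D, x$loss, x$lambda))
  if (x$strategy == "molecular")
    cat(sprintf("  m = %d barcodes, p_max = %.2f, occupancy cap = %d\n",
                x$m, x$p_max, occupancy_cap(x$m, x$p_max)))
  invisible(x)
}

#' Probability of a duplicated pre-index barcode in a droplet
#'
#' For a droplet containing `n` cells, each independently carrying one of
#' `m` equally likely Tn5 pre-index barcodes, returns the probability that
#' at least two cells share a barcode (the birthday-problem complement):
#' \deqn{P = 1 - \frac{m (m-1) \cdots (m-n+1)}{m^n}, \quad n \le m}
#' with `P = 1` for `n > m` and `P = 0` for `n <= 1`.
#'
#' @param m number of pre-index barcodes (>= 1).
#' @param n droplet occupancy (vectorised, non-negative integers).
#' @return Probability vector, same length as `n`.
#' @examples
#' duplicate_prob(96, 2)  # 1/96
#' @export
duplicate_prob <- function(m, n) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1, is.numeric(n), all(n >= 0))
  vapply(n, function(ni) {
    if (ni <= 1) return(0)
    if (ni > m) return(1)
    # product form, kept in log space for large m
    1 - exp(sum(log(m - seq_len(ni) + 1)) - ni * log(m))
  }, numeric(1))
}

#' Largest droplet occupancy tolerated by the duplicate-barcode rule
#'
#' Returns the largest occupancy `n` whose duplicate-barcode probability
#' [duplicate_prob()] does not exceed `p_max`. Droplets above this cap are
#' treated as undemultiplexable under molecular hashing. With the default
#' 10% tolerance the caps are 4, 3 and 2 cells for 96, 48 and 24 barcodes.
#'
#' @param m number of pre-index barcodes (>= 2).
#' @param p_max duplicate-probability tolerance (default 0.10).
#' @return Integer occupancy cap (>= 1).
#' @examples
#' occupancy_cap(96)  # 4
#' occupancy_cap(24)  # 2
#' @export
occupancy_cap <- function(m, p_max = 0.10) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 2)
  n <- 1L
  while (n < m + 1L && duplicate_prob(m, n + 1L) <= p_max) n <- n + 1L
  n
}

# expected usable cells per droplet-model, closed form.
# molecular: droplets with occupancy above the cap are discarded whole;
# every cell in a retained droplet is usable (accounting = "all_cells"), or
# only cells whose barcode is unique within the droplet
# (accounting = "unique_barcodes", E = n ((m-1)/m)^(n-1)).
usable_per_droplet <- function(model, accounting = c("all_cells", "unique_barcodes")) {
  accounting <- match.arg(accounting)
  lam <- model$lambda
  if (model$strategy == "cellular")
    return(lam * exp(-lam))                     # singlet droplets only
  cap <- occupancy_cap(model$m, model$p_max)
  n <- seq_len(cap)
  w <- if (accounting == "all_cells") n else n * ((model$m - 1) / model$m)^(n - 1)
  sum(w * exp(-lam + n * log(lam) - lfactorial(n)))
}

#' Expected usable and unusable cells under a loading model (closed form)
#'
#' Computes the analytic expectation of the number of usable
#' (demultiplexable) cells per lane. Under cellular hashing only singlet
#' droplets are usable, giving `D * lambda * exp(-lambda)`. Under molecular
#' hashing, droplets up to the occupancy cap from [occupancy_cap()] are
#' retained and all their cells counted:
#' `D * exp(-lambda) * sum_{n=1}^{cap} n lambda^n / n!`.
#' Unusable cells are the remainder, `D * lambda - usable`.
#'
#' @param model a [droplet_model()].
#' @param accounting `"all_cells"` (default; every cell in a retained
#'   droplet is usable) or `"unique_barcodes"` (only cells whose Tn5
#'   barcode is unique within the droplet).
#' @return A list of class `sim_result` with fields `N`, `lambda`,
#'   `expected_usable`, `expected_unusable`, `ratio`
#'   (unusable / usable) and `mode = "analytic"`.
#' @examples
#' expected_usable(droplet_model(100000 / 0.65, m = NULL))  # lambda = 1
#' @export
expected_usable <- function(model, accounting = "all_cells") {
  stopifnot(inherits(model, "droplet_model"))
  usable <- model$D * usable_per_droplet(model, accounting)
  total <- model$D * model$lambda
  structure(list(
    N = model$N, lambda = model$lambda,
    expected_usable = usable,
    expected_unusable = total - usable,
    ratio = if (usable > 0) (total - usable) / usable else NA_real_,
    mode = "analytic", seed = NULL
  ), class = "sim_result")
}

#' Monte Carlo simulation of droplet loading
#'
#' Draws the occupancy of each of the `D` droplets from a Poisson
#' distribution with mean `lambda` and applies the usable-cell rule of the
#' strategy (singlet-only for cellular hashing; the occupancy cap for
#' molecular hashing). Validates the closed form in [expected_usable()].
#'
#' @param model a [droplet_model()].
#' @param seed integer RNG seed.
#' @param n_reps number of independent lane replicates (>= 1).
#' @param accounting see [expected_usable()].
#' @return `sim_result` list with Monte Carlo means, plus `se_usable`
#'   (standard error over replicates) and `mode = "monte_carlo"`.
#' @export
simulate_loading_mc <- function(model, seed, n_reps = 10, accounting = "all_cells") {
  stopifnot(inherits(model, "droplet_model"), n_reps >= 1)
  accounting <- match.arg(accounting, c("all_cells", "unique_barcodes"))
  set.seed(as.integer(seed))
  cap <- if (model$strategy == "molecular")
    occupancy_cap(model$m, model$p_max) else 1L
  per_rep <- vapply(seq_len(n_reps), function(r) {
    occ <- stats::rpois(model$D, model$lambda)
    kept <- occ[occ >= 1L & occ <= cap]
    usable <- if (accounting == "all_cells" || model$strategy == "cellular") {
      sum(kept)
    } else {
      # count cells whose barcode draw is unique within the droplet
      sum(vapply(kept, function(n) {
        bc <- sample.int(model$m, n, replace = TRUE)
        sum(!(duplicated(bc) | duplicated(bc, fromLast = TRUE)))
      }, numeric(1)))
    }
    c(usable = usable, total = sum(occ))
  }, numeric(2))
  usable <- mean(per_rep["usable", ])
  total <- mean(per_rep["total", ])
  structure(list(
    N = model$N, lambda = model$lambda,
    expected_usable = usable,
    expected_unusable = total - usable,
    ratio = if (usable > 0) (total - usable) / usable else NA_real_,
    se_usable = stats::sd(per_rep["usable", ]) / sqrt(n_reps),
    mode = "monte_carlo", seed = as.integer(seed)
  ), class = "sim_result")
}

#' Optimize the nuclei loading input for usable-cell yield
#'
#' Sweeps the loading input `N` over a grid (default 1,000 to 1,500,000
#' nuclei in steps of 1,000), computes the expected number of usable cells
#' at each `N`, and returns the maximizing input. In analytic mode the
#' argmax is additionally refined by golden-section search on the smooth
#' closed-form curve.
#'
#' @param D,loss,m,p_max model parameters passed to [droplet_model()];
#'   `m = NULL` selects cellular hashing.
#' @param N_grid vector of loading inputs to evaluate.
#' @param mode `"analytic"` (default) or `"monte_carlo"`.
#' @param seed,n_reps used in Monte Carlo mode only.
#' @param accounting see [expected_usable()].
#' @return List with `curve` (data.frame of `N`, `lambda`, `usable`,
#'   `unusable`, `ratio`), `N_opt`, `max_usable`, and `strategy`.
#' @examples
#' opt <- optimize_loading(m = 96, N_grid = seq(1000, 1500000, 5000))
#' opt$max_usable
#' @export
optimize_loading <- function(D = 100000, loss = 0.35, m = NULL, p_max = 0.10,
                             N_grid = seq(1000, 1500000, by = 1000),
                             mode = c("analytic", "monte_carlo"),
                             seed = 1L, n_reps = 10,
                             accounting = "all_cells") {
  mode <- match.arg(mode)
  stopifnot(length(N_grid) >= 1, all(N_grid >= 0))
  eval_one <- function(N) {
    mod <- droplet_model(N, D = D, loss = loss, m = m, p_max = p_max)
    if (mode == "analytic") expected_usable(mod, accounting)
    else simulate_loading_mc(mod, seed = seed, n_reps = n_reps,
                             accounting = accounting)
  }
  res <- lapply(N_grid, eval_one)
  curve <- data.frame(
    N = N_grid,
    lambda = vapply(res, `[[`, numeric(1), "lambda"),
    usable = vapply(res, `[[`, numeric(1), "expected_usable"),
    unusable = vapply(res, `[[`, numeric(1), "expected_unusable"),
    ratio = vapply(res, `[[`, numeric(1), "ratio")
  )
  i <- which.max(curve$usable)
  N_opt <- curve$N[i]
  max_usable <- curve$usable[i]
  if (mode == "analytic" && length(N_grid) >= 3 && i > 1 && i < length(N_grid)) {
    f <- function(N) expected_usable(
      droplet_model(N, D = D, loss = loss, m = m, p_max = p_max),
      accounting)$expected_usable
    o <- stats::optimize(f, interval = c(N_grid[i - 1L], N_grid[i + 1L]),
                         maximum = TRUE, tol = 1)
    if (o$objective > max_usable) {
      N_opt <- o$maximum
      max_usable <- o$objective
    }
  }
  list(curve = curve, N_opt = N_opt, max_usable = max_usable,
       strategy = if (is.null(m)) "cellular" else "molecular", mode = mode)
}
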