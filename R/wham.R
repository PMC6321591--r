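# WHAM: weighted-histogram reconstruction of 1D/2D potentials of mean force
# from umbrella-window samples, with three-block error estimation.
#
# Self-consistent equations (standard form), with the bias U_i evaluated at
# bin centres using the SAME convention as the sampler (harmonic_bias, no 1/2
# factor):
#   p(b)  prop.to  sum_i n_i(b) / sum_i N_i exp[(f_i - U_i(b)) / kB T]
#   f_i = -kB T ln sum_b p(b) exp(-U_i(b) / kB T)
# iterated until max |delta f_i| <= tol;  F = -kB T ln p, min-shifted.

#' Construct a gridded (free) energy object
#'
#' @param edges list of bin-edge vectors, one per axis (A).
#' @param F free-energy values, kcal/mol: vector (1D) or of length
#'   `prod(nbins)` in axis-1-major order (axis 1 slowest).
#' @param mask logical vector marking occupied bins (default: finite `F`).
#' @param error optional per-bin error grid, kcal/mol.
#' @param f_windows optional per-window free-energy shifts f_i (f_1 = 0).
#' @param temperature temperature in K.
#' @param converged,iterations WHAM solver diagnostics.
#' @param meta free-form metadata list.
#' @return An object of class `pmf_grid` with bin `edges`, `centers`, `F`
#'   (NA outside the mask, min = 0 on the mask), `mask`, and any diagnostics.
#' @export
pmf_grid <- function(edges, F, mask = NULL, error = NULL, f_windows = NULL,
                     temperature = 300, converged = TRUE, iterations = 0L,
                     meta = list()) {
  if (!is.list(edges)) edges <- list(edges)
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  nb <- vapply(centers, length, 1L)
  stopifnot(length(F) == prod(nb))
  if (is.null(mask)) mask <- is.finite(F)
  F[!mask] <- NA_real_
  if (any(mask)) F <- F - min(F[mask])
  structure(list(edges = edges, centers = centers, nbins = nb, F = F,
                 mask = mask, error = error, f_windows = f_windows,
                 temperature = temperature, converged = converged,
                 iterations = as.integer(iterations), meta = meta),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("pmf_grid: %s bins, %d occupied, T = %g K%s\n",
              paste(x$nbins, collapse = " x "), sum(x$mask), x$temperature,
              if (isTRUE(x$converged)) "" else " [NOT converged]"))
  invisible(x)
}

# Matrix of bin centres, one row per (flattened) bin, axis-1-major.
.bin_center_matrix <- function(centers) {
  d <- length(centers)
  if (d == 1) return(matrix(centers[[1]], ncol = 1))
  g <- expand.grid(rev(centers), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, rev(seq_len(d)), drop = FALSE])
}

# Flat bin index (axis-1-major, left-closed bins [a, b)); 0 = out of range.
.flat_bin_index <- function(values, edges) {
  d <- ncol(values)
  nb <- vapply(edges, length, 1L) - 1L
  idx <- rep(1L, nrow(values))
  ok <- rep(TRUE, nrow(values))
  mult <- rev(cumprod(rev(c(nb[-1], 1L))))
  for (j in seq_len(d)) {
    b <- findInterval(values[, j], edges[[j]], rightmost.closed = FALSE,
                      left.open = FALSE)
    ok <- ok & b >= 1L & b <= nb[j]
    idx <- idx + (b - 1L) * mult[j]
  }
  idx[!ok] <- 0L
  idx
}

#' Bin umbrella-window samples into a shared histogram set
#'
#' Bins are left-closed, right-open (`[a, b)`); a value on an interior edge
#' belongs to the bin on its right.  Values outside the bin range are dropped
#' and counted in the `dropped` attribute.
#'
#' @param series list of `sample_series` (from [sample_window()] or
#'   [read_sample_series()]).
#' @param edges bin-edge vector (1D) or list of per-axis edge vectors.
#' @return A `histogram_set`: list with `edges`, `centers`, `counts`
#'   (bins x windows matrix), `windows`, `N` (per-window totals) and
#'   `temperature`.
#' @export
build_histograms <- function(series, edges) {
  stopifnot(length(series) >= 1)
  if (!is.list(edges)) edges <- list(edges)
  d <- ncol(series[[1]]$values)
  if (length(edges) != d)
    stop("need one edge vector per sampled axis (", d, ")")
  temps <- vapply(series, function(s) s$temperature, 1)
  if (diff(range(temps)) > 1e-9)
    stop("all windows must share one temperature")
  nb <- prod(vapply(edges, length, 1L) - 1L)
  counts <- matrix(0, nb, length(series))
  dropped <- 0L
  for (i in seq_along(series)) {
    idx <- .flat_bin_index(series[[i]]$values, edges)
    dropped <- dropped + sum(idx == 0L)
    t <- tabulate(idx[idx > 0L], nbins = nb)
    counts[, i] <- t
  }
  if (dropped > 0L)
    message(dropped, " sample(s) outside the bin range were dropped")
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(edges = edges, centers = centers, counts = counts,
                 windows = lapply(series, function(s) s$window),
                 N = colSums(counts), temperature = temps[1],
                 dropped = dropped),
            class = "histogram_set")
}

# Connected components of windows linked by sharing an occupied bin;
# returns per-bin component id (NA for empty bins).
.coverage_components <- function(counts) {
  W <- ncol(counts)
  comp <- seq_len(W)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  occ <- counts > 0
  for (b in which(rowSums(occ) > 1)) {
    wins <- which(occ[b, ])
    r <- find(wins[1])
    for (wi in wins[-1]) comp[find(wi)] <- r
  }
  wcomp <- vapply(seq_len(W), find, 1L)
  bincomp <- rep(NA_integer_, nrow(counts))
  for (b in which(rowSums(occ) > 0))
    bincomp[b] <- wcomp[which(occ[b, ])[1]]
  list(windows = wcomp, bins = bincomp,
       n = length(unique(wcomp)))
}

#' Solve the WHAM equations for a set of umbrella histograms
#'
#' Iterates the self-consistent WHAM fixed point to a tolerance on
#' `max |delta f_i|`, with window shifts anchored at `f_1 = 0`.  Bin bias
#' energies use each window's production force constant and centre through
#' [harmonic_bias()], evaluated at bin centres.  Bins with fewer than
#' `min_count` total samples are masked (excluded from the min-shift).  If
#' the windows do not overlap into a single connected component a warning is
#' issued and each component is min-shifted separately.
#'
#' @param hist a `histogram_set` from [build_histograms()].
#' @param tol convergence tolerance on the window shifts, kcal/mol.
#' @param max_iter iteration cap; if reached the result is returned with
#'   `converged = FALSE`.
#' @param min_count minimum total count for a bin to enter the PMF.
#' @return A [pmf_grid] with `F`, `mask`, window shifts `f_windows`,
#'   `iterations` and `converged`.
#' @export
solve_wham <- function(hist, tol = 1e-6, max_iter = 100000L, min_count = 1L) {
  stopifnot(inherits(hist, "histogram_set"))
  kT <- .KB * hist$temperature
  C <- .bin_center_matrix(hist$centers)
  W <- length(hist$windows)
  U <- vapply(seq_len(W), function(i)
    harmonic_bias(hist$windows[[i]]$k_prod, C, hist$windows[[i]]$centers),
    numeric(nrow(C)))
  M <- exp(-U / kT)                       # bins x windows
  n_b <- rowSums(hist$counts)
  N <- hist$N
  f <- numeric(W)
  it <- 0L; converged <- FALSE
  omega <- 1; last_delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    denom <- as.vector(M %*% (N * exp(f / kT)))
    p <- ifelse(denom > 0, n_b / denom, 0)
    p <- p / sum(p)
    fn <- -kT * log(as.vector(crossprod(M, p)))
    fn <- fn - fn[1]
    delta <- max(abs(fn - f))
    if (delta <= tol) { f <- fn; converged <- TRUE; break }
    # adaptive over-relaxation: the fixed point is unchanged, and the
    # convergence test above always uses the raw (unrelaxed) update
    if (delta < last_delta) omega <- min(omega * 1.1, 1.9) else omega <- 1
    last_delta <- delta
    f <- f + omega * (fn - f)
  }
  denom <- as.vector(M %*% (N * exp(f / kT)))
  p <- ifelse(denom > 0, n_b / denom, 0)
  p <- p / sum(p)
  mask <- n_b >= min_count & p > 0
  F <- ifelse(mask, -kT * log(p), NA_real_)
  comp <- .coverage_components(hist$counts)
  if (comp$n > 1) {
    warning("umbrella windows do not overlap into one connected component (",
            comp$n, " components); PMF min-shifted per component")
    for (cid in unique(stats::na.omit(comp$bins))) {
      sel <- mask & !is.na(comp$bins) & comp$bins == cid
      if (any(sel)) F[sel] <- F[sel] - min(F[sel])
    }
    # pmf_grid() min-shifts globally; pre-shifting per component keeps each
    # component anchored at zero afterwards.
  }
  if (!converged)
    warning("WHAM did not converge within ", max_iter, " iterations")
  pmf_grid(hist$edges, F, mask = mask, f_windows = f,
           temperature = hist$temperature, converged = converged,
           iterations = it,
           meta = list(tol = tol, min_count = min_count))
}

#' Block-averaged error estimate for a WHAM potential of mean force
#'
#' Partitions every window's production series into `n_blocks` contiguous,
#' equal-length time blocks, solves WHAM per block, aligns the block PMFs by
#' a least-squares offset over their shared occupied bins (each block PMF is
#' only defined up to a constant), and reports the per-bin standard deviation
#' from the mean across blocks.
#'
#' @inheritParams build_histograms
#' @param n_blocks number of blocks (default 3).
#' @param tol,max_iter,min_count passed to [solve_wham()].
#' @return List with `error` (per-bin sd, NA where any block is undefined),
#'   `mean` (aligned block-mean PMF, min-shifted), `blocks` (list of
#'   [pmf_grid]s) and `n_blocks`.
#' @export
block_error <- function(series, edges, n_blocks = 3L, tol = 1e-6,
                        max_iter = 100000L, min_count = 1L) {
  stopifnot(n_blocks >= 2)
  len <- vapply(series, function(s) nrow(s$values), 1L)
  if (any(len == 0L)) stop("empty sample series")
  if (any(len %% n_blocks != 0L))
    stop("every series length must be divisible by n_blocks")
  blocks <- lapply(seq_len(n_blocks), function(b) {
    sub <- lapply(series, function(s) {
      L <- nrow(s$values) / n_blocks
      s$values <- s$values[((b - 1) * L + 1):(b * L), , drop = FALSE]
      s
    })
    solve_wham(build_histograms(sub, edges), tol = tol,
               max_iter = max_iter, min_count = min_count)
  })
  FB <- vapply(blocks, function(p) p$F, numeric(length(blocks[[1]]$F)))
  for (b in seq_len(n_blocks)[-1]) {
    shared <- !is.na(FB[, 1]) & !is.na(FB[, b])
    if (!any(shared)) next
    FB[, b] <- FB[, b] - mean(FB[shared, b] - FB[shared, 1])
  }
  all_def <- rowSums(is.na(FB)) == 0
  mn <- ifelse(all_def, rowMeans(FB), NA_real_)
  er <- ifelse(all_def, apply(FB, 1, stats::sd), NA_real_)
  if (any(all_def)) mn <- mn - min(mn[all_def])
  list(error = er, mean = mn, blocks = blocks, n_blocks = n_blocks,
       edges = blocks[[1]]$edges, centers = blocks[[1]]$centers)
}
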