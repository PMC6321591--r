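# Independent oracles used by the tests.  These deliberately re-derive
# quantities by brute force (dense grids, exhaustive enumeration, plain
# Newton, sample-level reweighting) rather than calling the code paths they
# check.

# central finite-difference gradient of the potential
fd_gradient <- function(spec, x, h = 1e-4) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (eval_potential(spec, x + e) - eval_potential(spec, x - e)) / (2 * h)
  }, 1)
}

# dense-grid search for local minima of a 2D landscape (resolution in A)
dense_grid_minima <- function(spec, res = 0.005) {
  xs <- seq(spec$domain[1, 1], spec$domain[2, 1], by = res)
  ys <- seq(spec$domain[1, 2], spec$domain[2, 2], by = res)
  V <- matrix(eval_potential(spec, as.matrix(expand.grid(x = xs, y = ys))),
              nrow = length(xs))
  mins <- NULL
  nx <- length(xs); ny <- length(ys)
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    v <- V[i, j]
    if (v < V[i - 1, j] && v < V[i + 1, j] && v < V[i, j - 1] &&
        v < V[i, j + 1])
      mins <- rbind(mins, c(xs[i], ys[j], v))
  }
  mins[order(mins[, 3]), , drop = FALSE]
}

# plain multivariate Newton root search on the analytic gradient, with its
# own finite-difference Jacobian; returns the stationary point + Hessian
# eigenvalues
newton_saddle <- function(spec, x0, tol = 1e-12, max_iter = 200) {
  gf <- gradient_fun(spec)
  d <- length(x0)
  x <- x0
  jac <- function(x, h = 1e-5) {
    J <- matrix(0, d, d)
    for (j in seq_len(d)) {
      e <- numeric(d); e[j] <- h
      J[, j] <- (gf(x + e) - gf(x - e)) / (2 * h)
    }
    (J + t(J)) / 2
  }
  for (it in seq_len(max_iter)) {
    g <- gf(x)
    if (sqrt(sum(g^2)) < tol) break
    x <- x - solve(jac(x), g)
  }
  list(x = x, energy = eval_potential(spec, x),
       gradient = gf(x),
       eigenvalues = eigen(jac(x), symmetric = TRUE,
                           only.values = TRUE)$values)
}

# exhaustive minimum-total-weight simple path on a 2D energy grid
# (connectivity 4, edge weight = max of endpoint energies), by DFS with
# branch-and-bound pruning.  E is an nx x ny matrix; start/end are c(ix, iy).
brute_force_path_weight <- function(E, start, end) {
  nx <- nrow(E); ny <- ncol(E)
  best <- Inf
  visited <- matrix(FALSE, nx, ny)
  dfs <- function(ix, iy, cost) {
    if (cost >= best) return()
    if (ix == end[1] && iy == end[2]) { best <<- cost; return() }
    visited[ix, iy] <<- TRUE
    for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      jx <- ix + o[1]; jy <- iy + o[2]
      if (jx < 1 || jx > nx || jy < 1 || jy > ny) next
      if (visited[jx, jy]) next
      dfs(jx, jy, cost + max(E[ix, iy], E[jx, jy]))
    }
    visited[ix, iy] <<- FALSE
  }
  dfs(start[1], start[2], 0)
  best
}

# sample-level multistate reweighting (MBAR-type) estimate of a 1D PMF from
# umbrella samples; independent of the binned WHAM solver.
mbar_pmf <- function(series, edges, tol = 1e-10, max_iter = 50000) {
  kT <- 0.0019872041 * series[[1]]$temperature
  xs <- unlist(lapply(series, function(s) s$values[, 1]))
  N <- vapply(series, function(s) nrow(s$values), 1L)
  W <- length(series)
  U <- vapply(seq_len(W), function(i) {
    w <- series[[i]]$window
    w$k_prod * (xs - w$centers[1])^2
  }, numeric(length(xs)))
  f <- numeric(W)
  for (it in seq_len(max_iter)) {
    denom <- as.vector(exp(-U / kT) %*% (N * exp(f / kT)))
    fn <- -kT * log(colSums(exp(-U / kT) / denom))
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  wts <- 1 / as.vector(exp(-U / kT) %*% (N * exp(f / kT)))
  bin <- findInterval(xs, edges)
  nb <- length(edges) - 1
  keep <- bin >= 1 & bin <= nb
  p <- vapply(seq_len(nb), function(b) sum(wts[keep][bin[keep] == b]), 1)
  Fv <- ifelse(p > 0, -kT * log(p), NA_real_)
  Fv - min(Fv, na.rm = TRUE)
}

# brute-force Boltzmann-quadrature PMF (trapezoid on a fixed fine grid),
# used as the independent check of analytic_pmf for a 2D -> 1D projection
brute_quadrature_pmf <- function(spec, edges, axis = 1, temperature = 300,
                                 nsub = 64, north = 256) {
  kT <- 0.0019872041 * temperature
  oax <- if (axis == 1) 2 else 1
  ys <- seq(spec$domain[1, oax], spec$domain[2, oax], length.out = north)
  nb <- length(edges) - 1
  I <- numeric(nb)
  for (b in seq_len(nb)) {
    xs <- seq(edges[b], edges[b + 1], length.out = nsub)
    X <- matrix(0, nsub * north, 2)
    X[, axis] <- rep(xs, each = north)
    X[, oax] <- rep(ys, times = nsub)
    Wt <- exp(-eval_potential(spec, X) / kT)
    M <- matrix(Wt, nrow = north)
    inner <- (colSums(M) - M[1, ] / 2 - M[north, ] / 2) *
      (ys[2] - ys[1])
    I[b] <- (sum(inner) - inner[1] / 2 - inner[nsub] / 2) * (xs[2] - xs[1])
  }
  Fv <- -kT * log(I)
  Fv - min(Fv)
}
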