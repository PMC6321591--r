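# Chain-of-states paths on analytic landscapes: equidistant arc-length
# reparameterisation (default spacing 0.01 A), synchronous chain
# minimisation of the gradient component orthogonal to the path, and a
# simplified saddle ("peak") refinement with a Hessian certificate.

#' Construct a chain-of-states path
#'
#' @param points matrix of path points (one per row) in reaction-coordinate
#'   space, A; at least 3 points, no duplicate consecutive points.
#' @param spec optional [landscape_spec()] used to evaluate per-point
#'   energies.
#' @param energies optional per-point energies (kcal/mol) if no `spec`.
#' @return A `chain_path`: list with `points`, `energies`, `fixed` (logical;
#'   endpoints are always fixed).
#' @export
chain_path <- function(points, spec = NULL, energies = NULL) {
  points <- rbind(points)
  if (nrow(points) < 3) stop("a chain path needs at least 3 points")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) stop("duplicate consecutive points in chain")
  if (!is.null(spec)) energies <- eval_potential(spec, points)
  fixed <- c(TRUE, rep(FALSE, nrow(points) - 2L), TRUE)
  structure(list(points = points, energies = energies, fixed = fixed),
            class = "chain_path")
}

#' @export
print.chain_path <- function(x, ...) {
  L <- sum(sqrt(rowSums((x$points[-1, , drop = FALSE] -
                           x$points[-nrow(x$points), , drop = FALSE])^2)))
  cat(sprintf("chain_path: %d points (%dD), length %.4f A\n",
              nrow(x$points), ncol(x$points), L))
  invisible(x)
}

#' Resample a chain to equidistant arc-length spacing
#'
#' Piecewise-linear resampling at arc lengths `0, h, 2h, ...`; the endpoints
#' are preserved exactly, so the final segment may be shorter than `h`.
#' Energies are re-evaluated on the landscape if `spec` is given.
#'
#' @param path a `chain_path`.
#' @param spacing target spacing `h` in A (default 0.01).
#' @param spec optional [landscape_spec()] for energy re-evaluation.
#' @return A new `chain_path` with uniform spacing (to within 1e-9 except
#'   possibly the last segment).
#' @export
reparameterize <- function(path, spacing = 0.01, spec = NULL) {
  X <- path$points
  seg <- sqrt(rowSums((X[-1, , drop = FALSE] -
                         X[-nrow(X), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (spacing >= L) stop("spacing must be smaller than the total path length")
  targets <- seq(0, L, by = spacing)
  if (L - targets[length(targets)] > 1e-12) targets <- c(targets, L)
  d <- ncol(X)
  Y <- matrix(0, length(targets), d)
  for (j in seq_len(d))
    Y[, j] <- stats::approx(s, X[, j], xout = targets, ties = "ordered")$y
  Y[1, ] <- X[1, ]; Y[nrow(Y), ] <- X[nrow(X), ]
  chain_path(Y, spec = spec)
}

.chain_tangents <- function(X) {
  m <- nrow(X)
  T <- matrix(0, m, ncol(X))
  T[1, ] <- X[2, ] - X[1, ]
  T[m, ] <- X[m, ] - X[m - 1, ]
  if (m > 2) T[2:(m - 1), ] <- X[3:m, , drop = FALSE] -
      X[1:(m - 2), , drop = FALSE]
  T / sqrt(rowSums(T^2))
}

# uniform arc-length resampling to exactly n points (endpoints preserved)
.resample_n <- function(X, n) {
  seg <- sqrt(rowSums((X[-1, , drop = FALSE] -
                         X[-nrow(X), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-14)           # drop collapsed points
  X <- X[keep, , drop = FALSE]
  seg <- sqrt(rowSums((X[-1, , drop = FALSE] -
                         X[-nrow(X), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  targets <- seq(0, s[length(s)], length.out = n)
  Y <- matrix(0, n, ncol(X))
  for (j in seq_len(ncol(X)))
    Y[, j] <- stats::approx(s, X[, j], xout = targets, ties = "ordered")$y
  Y[1, ] <- X[1, ]; Y[n, ] <- X[nrow(X), ]
  Y
}

#' Synchronous chain minimisation
#'
#' Moves all interior points simultaneously along the negative of the
#' gradient component orthogonal to the local path tangent (normalised
#' central difference of the neighbours).  The per-iteration displacement is
#' capped at a fraction of the chain spacing and additionally controlled by
#' backtracking: a step is only accepted if the maximum per-point energy
#' does not increase.  Terminates when the largest orthogonally-projected
#' gradient magnitude over interior points drops to `tol`.  Endpoints never
#' move.  Optionally the chain is redistributed to uniform arc length
#' (keeping its number of points fixed, with a mild smoothing that damps
#' the zig-zag mode of the discrete tangent) every `respace_every`
#' iterations; redistribution stabilises chains whose points cluster, but
#' the interpolation it applies re-excites a finite projected-gradient
#' residual, so it is off by default -- the displacement cap alone keeps
#' the plain relaxation stable.
#'
#' @param spec a [landscape_spec()].
#' @param path a `chain_path` (ideally already reparameterised).
#' @param tol projected-gradient tolerance, kcal mol^-1 A^-1 (default 0.1).
#' @param max_iter iteration cap; exceeded => returned with
#'   `converged = FALSE`.
#' @param step initial step length scale, A^2 mol kcal^-1.
#' @param respace_every redistribute the chain every this many iterations
#'   (0 disables re-spacing).
#' @return The minimised `chain_path`, with attributes `converged`,
#'   `iterations` and `max_proj_gradient`.
#' @export
synchronous_chain_minimize <- function(spec, path, tol = 0.1,
                                       max_iter = 2000L, step = 0.02,
                                       respace_every = 0L) {
  X <- path$points
  m <- nrow(X); d <- ncol(X)
  lo <- spec$domain[1, ]; hi <- spec$domain[2, ]
  int <- 2:(m - 1)
  seg0 <- sqrt(rowSums((X[-1, , drop = FALSE] - X[-m, , drop = FALSE])^2))
  h0 <- mean(seg0)
  E <- .potential_matrix(spec, X)
  alpha <- step
  converged <- FALSE; res <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    G <- .gradient_matrix(spec, X)
    Tm <- .chain_tangents(X)
    Gp <- G - Tm * rowSums(G * Tm)
    Gp[c(1, m), ] <- 0
    res <- max(sqrt(rowSums(Gp[int, , drop = FALSE]^2)))
    if (res <= tol) { converged <- TRUE; break }
    a <- alpha
    dmax <- a * max(sqrt(rowSums(Gp^2)))
    if (dmax > 0.3 * h0) a <- a * 0.3 * h0 / dmax   # displacement cap
    repeat {
      Xn <- X
      Xn[int, ] <- X[int, , drop = FALSE] - a * Gp[int, , drop = FALSE]
      for (j in seq_len(d))
        Xn[, j] <- pmin(pmax(Xn[, j], lo[j]), hi[j])
      En <- .potential_matrix(spec, Xn)
      if (max(En) <= max(E) + 1e-12 || a < 1e-9) break
      a <- a / 2
    }
    X <- Xn; E <- En
    if (respace_every > 0L && it %% respace_every == 0L) {
      # mild Laplacian smoothing damps the zig-zag mode of the discrete
      # tangent before redistributing to uniform arc length
      if (m > 3) {
        lap <- X[c(1, 1:(m - 1)), , drop = FALSE] +
          X[c(2:m, m), , drop = FALSE] - 2 * X
        X[int, ] <- X[int, , drop = FALSE] + 0.2 * lap[int, , drop = FALSE]
      }
      X <- .resample_n(X, m)
      E <- .potential_matrix(spec, X)
    }
  }
  out <- chain_path(X, spec = spec)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  attr(out, "max_proj_gradient") <- res
  out
}

#' Refine the energy peak of a chain to a first-order saddle
#'
#' A simplified conjugate-peak style refinement: starting from the interior
#' energy maximum of the chain, iterate (i) a line maximisation along the
#' current unstable direction -- initially the path segment direction
#' bracketing the peak, thereafter the eigenvector of the most negative
#' finite-difference Hessian eigenvalue -- and (ii) a minimisation in the
#' orthogonal (conjugate) subspace, until the full gradient norm drops to
#' `tol`.  The result is certified as a saddle when the finite-difference
#' Hessian has exactly one negative eigenvalue; if the certificate fails the
#' point is still returned, flagged.
#'
#' @param spec a [landscape_spec()].
#' @param path a `chain_path` whose energy maximum is interior.
#' @param tol gradient-norm tolerance at the saddle, kcal mol^-1 A^-1.
#' @param max_iter iteration cap.
#' @return List with `point`, `energy`, `gradient_norm`, `eigenvalues`,
#'   `certified`, `converged`, and `path` (the input chain with the refined
#'   saddle inserted at its arc-length position).
#' @export
refine_peak <- function(spec, path, tol = 1e-5, max_iter = 200L) {
  vf <- potential_fun(spec); gf <- gradient_fun(spec)
  e <- if (is.null(path$energies)) .potential_matrix(spec, path$points)
       else path$energies
  m <- nrow(path$points)
  i0 <- which.max(e)
  if (i0 == 1L || i0 == m)
    stop("the chain has no interior energy maximum")
  x <- path$points[i0, ]
  d <- length(x)
  lo <- spec$domain[1, ]; hi <- spec$domain[2, ]
  u <- path$points[min(i0 + 1L, m), ] - path$points[max(i0 - 1L, 1L), ]
  u <- u / sqrt(sum(u^2))
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    g <- gf(x)
    if (sqrt(sum(g^2)) <= tol) { conv <- TRUE; break }
    H <- .fd_hessian(spec, x)
    ei <- eigen(H, symmetric = TRUE)
    if (it > 1L && ei$values[d] < 0) u <- ei$vectors[, d]
    # (i) line maximisation along u
    h <- 0.2
    tmax <- stats::optimize(function(t) vf(x + t * u),
                            interval = c(-h, h), maximum = TRUE,
                            tol = 1e-12)$maximum
    x <- pmin(pmax(x + tmax * u, lo), hi)
    if (d > 1) {
      # (ii) minimisation in the orthogonal subspace
      B <- qr.Q(qr(cbind(u, diag(d))))[, -1, drop = FALSE]
      fn <- function(s) vf(x + as.vector(B %*% s))
      gr <- function(s) as.vector(crossprod(B, gf(x + as.vector(B %*% s))))
      r <- stats::optim(rep(0, d - 1), fn, gr, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 200))
      x <- pmin(pmax(x + as.vector(B %*% r$par), lo), hi)
    }
  }
  g <- gf(x)
  ev <- eigen(.fd_hessian(spec, x), symmetric = TRUE,
              only.values = TRUE)$values
  certified <- sqrt(sum(g^2)) <= tol && sum(ev < 0) == 1
  if (!certified)
    warning("saddle certificate failed (gradient norm ",
            format(sqrt(sum(g^2))), ", ", sum(ev < 0),
            " negative Hessian eigenvalue(s))")
  # insert the refined point at its arc-length position
  X <- path$points
  proj_seg <- function(i) {
    a <- X[i, ]; b <- X[i + 1, ]
    tt <- sum((x - a) * (b - a)) / sum((b - a)^2)
    if (tt > 0 && tt < 1) sqrt(sum((x - (a + tt * (b - a)))^2)) else Inf
  }
  dists <- vapply(seq_len(m - 1), proj_seg, 1)
  k <- if (all(!is.finite(dists))) i0 - 1L else which.min(dists)
  Xn <- rbind(X[seq_len(k), , drop = FALSE], x,
              X[(k + 1):m, , drop = FALSE])
  dup <- c(FALSE, rowSums((Xn[-1, , drop = FALSE] -
                             Xn[-nrow(Xn), , drop = FALSE])^2) < 1e-20)
  Xn <- Xn[!dup, , drop = FALSE]
  list(point = x, energy = vf(x), gradient_norm = sqrt(sum(g^2)),
       eigenvalues = ev, certified = certified, converged = conv,
       path = chain_path(Xn, spec = spec))
}
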