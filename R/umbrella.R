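# Umbrella-sampling windows and the biased Metropolis sampler.
#
# Protocol emulated: one biased run per point of a regular reaction-coordinate
# grid (default spacing 0.1 A), harmonic bias with force constant
# 1000 kcal mol^-1 A^-2 during equilibration and 200 kcal mol^-1 A^-2 during
# production, at 300 K.  The restraint convention is the CHARMM one,
# U = k (x - c)^2 with NO factor 1/2; the WHAM module uses the identical
# convention through harmonic_bias().

#' Harmonic restraint energy (shared bias convention)
#'
#' \eqn{U = k \sum_d (x_d - c_d)^2} in kcal/mol -- note the absence of the
#' 1/2 factor.  This single function defines the bias convention used by both
#' the sampler and the WHAM solver.
#'
#' @param k force constant, kcal mol^-1 A^-2.
#' @param x point (numeric vector) or matrix of points (rows), A.
#' @param center restraint centre, A.
#' @return Bias energy in kcal/mol (vectorised over rows of `x`).
#' @export
harmonic_bias <- function(k, x, center) {
  if (is.null(dim(x))) return(k * sum((x - center)^2))
  C <- matrix(center, nrow(x), ncol(x), byrow = TRUE)
  k * rowSums((x - C)^2)
}

#' One umbrella window
#'
#' @param window_id character identifier.
#' @param centers per-axis bias centre, A.
#' @param k_equil,k_prod harmonic force constants (kcal mol^-1 A^-2) for the
#'   equilibration and production phases.
#' @param n_equil,n_prod step counts for the two phases; `n_prod` must be
#'   divisible by `stride * n_blocks` used downstream (checked at sampling /
#'   blocking time).
#' @param temperature temperature in K.
#' @param seed integer RNG seed for this window.
#' @return An object of class `bias_window`.
#' @export
bias_window <- function(window_id, centers, k_equil = 1000, k_prod = 200,
                        n_equil = 10000, n_prod = 60000,
                        temperature = 300, seed = 1L) {
  stopifnot(k_equil > 0, k_prod > 0, n_equil >= 0, n_prod > 0,
            temperature > 0)
  structure(list(window_id = as.character(window_id),
                 centers = as.numeric(centers),
                 k_equil = k_equil, k_prod = k_prod,
                 n_equil = as.integer(n_equil), n_prod = as.integer(n_prod),
                 temperature = temperature, seed = as.integer(seed)),
            class = "bias_window")
}

#' Derive a per-window seed from a master seed
#'
#' Splittable scheme `(master, index) -> seed`: a fixed affine map modulo the
#' Mersenne-like prime 2147483629, keeping results in 32-bit integer range so
#' that windows can be sampled independently (and in any order) while the
#' whole run remains reproducible from one master seed.
#'
#' @param master master seed (integer).
#' @param index window index (1-based integer).
#' @return An integer seed in `[1, 2147483628]`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483629
  s <- (as.double(master) %% m) * 48271 + as.double(index) * 16807 + 1
  as.integer(s %% m)
}

#' Build a regular grid of umbrella windows
#'
#' Window centres form the same regular grid used by the potential-energy
#' scans (default spacing 0.1 A), inclusive of both range ends.
#'
#' @param ranges numeric vector `c(lo, hi)` for 1D, or a list of such vectors
#'   (one per axis) for 2D.  Each range width must be a positive multiple of
#'   `spacing` (to within 1e-9), otherwise an error suggests the nearest
#'   commensurate bound.
#' @param spacing grid spacing in A (default 0.1).
#' @param master_seed master seed; per-window seeds come from [derive_seed()].
#' @inheritParams bias_window
#' @return A list of [bias_window()] objects, in row-major grid order.
#' @examples
#' length(build_window_grid(c(-1.5, 1.6)))             # 32 windows
#' length(build_window_grid(list(c(1.6, 3.2), c(1.6, 3.2))))  # 289 windows
#' @export
build_window_grid <- function(ranges, spacing = 0.1,
                              k_equil = 1000, k_prod = 200,
                              n_equil = 10000, n_prod = 60000,
                              temperature = 300, master_seed = 1L) {
  if (!is.list(ranges)) ranges <- list(ranges)
  stopifnot(spacing > 0)
  axes <- lapply(seq_along(ranges), function(j) {
    r <- ranges[[j]]
    stopifnot(length(r) == 2, r[2] > r[1])
    n <- (r[2] - r[1]) / spacing
    if (abs(n - round(n)) > 1e-9 * max(1, abs(n))) {
      near <- r[1] + round(n) * spacing
      stop(sprintf(paste0(
        "range [%g, %g] on axis %d is not commensurate with spacing %g; ",
        "nearest commensurate upper bound is %g"),
        r[1], r[2], j, spacing, near))
    }
    seq(r[1], by = spacing, length.out = round(n) + 1)
  })
  grid <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(axes)), drop = FALSE]  # first axis slowest
  lapply(seq_len(nrow(grid)), function(i)
    bias_window(sprintf("w%04d", i), as.numeric(grid[i, ]),
                k_equil = k_equil, k_prod = k_prod,
                n_equil = n_equil, n_prod = n_prod,
                temperature = temperature,
                seed = derive_seed(master_seed, i)))
}

#' Bias energy of an umbrella window at a point
#'
#' @param window a [bias_window()].
#' @param point numeric vector (or matrix of points), A.
#' @param phase `"production"` or `"equilibration"` (selects the force
#'   constant).
#' @return Bias energy in kcal/mol.
#' @examples
#' w <- bias_window("w", 0, k_prod = 200)
#' bias_energy(w, 0.1)  # 200 * 0.01 = 2 kcal/mol
#' @export
bias_energy <- function(window, point, phase = c("production",
                                                 "equilibration")) {
  phase <- match.arg(phase)
  k <- if (phase == "production") window$k_prod else window$k_equil
  harmonic_bias(k, point, window$centers)
}

# Metropolis random-walk core.  Pre-generates all proposal displacements and
# acceptance draws; optional width tuning (equilibration only) targets ~40%
# acceptance.  Proposals outside the domain are rejected, which is Metropolis
# on V + U_bias with V = +Inf outside -- detailed balance is preserved.
.mc_run <- function(vf, lo, hi, center, k, kT, x, nsteps, w,
                    tune = FALSE, record_every = 0L) {
  d <- length(x)
  nrec <- if (record_every > 0L) nsteps %/% record_every else 0L
  out <- if (nrec > 0L) matrix(0, nrec, d) else NULL
  Z <- matrix(stats::rnorm(nsteps * d), nsteps, d)
  LU <- log(stats::runif(nsteps))
  e <- vf(x) + k * sum((x - center)^2)
  nacc <- 0L; bacc <- 0L; irec <- 0L
  for (i in seq_len(nsteps)) {
    xp <- x + w * Z[i, ]
    if (all(xp >= lo) && all(xp <= hi)) {
      ep <- vf(xp) + k * sum((xp - center)^2)
      if (LU[i] < (e - ep) / kT) {
        x <- xp; e <- ep; nacc <- nacc + 1L; bacc <- bacc + 1L
      }
    }
    if (tune && i %% 200L == 0L) {
      w <- w * exp(bacc / 200 - 0.40)
      w <- min(max(w, 1e-6), max(hi - lo))
      bacc <- 0L
    }
    if (record_every > 0L && i %% record_every == 0L) {
      irec <- irec + 1L
      out[irec, ] <- x
    }
  }
  list(x = x, w = w, rate = nacc / nsteps, values = out)
}

#' Sample one umbrella window by Metropolis Monte Carlo
#'
#' Runs a random-walk Metropolis chain on `V + U_bias` at the window
#' temperature: an equilibration phase (discarded, force constant `k_equil`,
#' proposal width auto-tuned towards ~40% acceptance) followed by a
#' production phase (force constant `k_prod`, fixed width rescaled by
#' `sqrt(k_equil / k_prod)` so the step stays matched to the wider production
#' distribution) whose reaction-coordinate values are recorded every `stride`
#' steps.  The sampler is exactly reproducible from the window seed; the
#' caller's RNG state is left untouched.
#'
#' @param spec a [landscape_spec()].
#' @param window a [bias_window()] whose centre lies inside the domain.
#' @param stride record every `stride`-th production step (default 10).
#' @param proposal_width optional fixed Gaussian proposal s.d. in A
#'   (disables auto-tuning).
#' @return A `sample_series`: list with `window_id`, `values` (matrix, one
#'   recorded step per row, one column per axis), `stride`, `window`,
#'   `temperature`, `acceptance`.  A warning (not an error) is raised if the
#'   production acceptance rate falls outside (0.05, 0.95).
#' @export
sample_window <- function(spec, window, stride = 10L,
                          proposal_width = NULL) {
  stopifnot(inherits(spec, "landscape_spec"), inherits(window, "bias_window"))
  .check_domain(spec, matrix(window$centers, nrow = 1))
  if (window$n_prod %% stride != 0L)
    stop("n_prod must be divisible by the recording stride")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(window$seed)
  vf <- potential_fun(spec)
  kT <- .KB * window$temperature
  lo <- spec$domain[1, ]; hi <- spec$domain[2, ]
  tune <- is.null(proposal_width)
  w0 <- if (tune) 2.4 * sqrt(kT / (2 * window$k_equil)) else proposal_width
  x <- window$centers
  if (window$n_equil > 0L) {
    eq <- .mc_run(vf, lo, hi, window$centers, window$k_equil, kT, x,
                  window$n_equil, w0, tune = tune)
    x <- eq$x
    w0 <- if (tune) eq$w * sqrt(window$k_equil / window$k_prod) else w0
  }
  pr <- .mc_run(vf, lo, hi, window$centers, window$k_prod, kT, x,
                window$n_prod, w0, tune = FALSE, record_every = stride)
  if (pr$rate <= 0.05 || pr$rate >= 0.95)
    warning(sprintf("window %s: production acceptance rate %.2f outside (0.05, 0.95)",
                    window$window_id, pr$rate))
  vals <- pr$values
  colnames(vals) <- spec$axis_names
  structure(list(window_id = window$window_id, values = vals,
                 stride = as.integer(stride), window = window,
                 temperature = window$temperature, acceptance = pr$rate),
            class = "sample_series")
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("sample_series %s: %d records x %d axis(es), stride %d, acc %.2f\n",
              x$window_id, nrow(x$values), ncol(x$values), x$stride,
              x$acceptance))
  invisible(x)
}
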