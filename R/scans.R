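# Constrained potential-energy scans.
#
# At each value of the scanned coordinate(s) the remaining coordinates are
# relaxed by quasi-Newton minimisation (warm-started from the previous grid
# point) and the *unbiased* potential at the relaxed point is reported.  The
# restraint force constant used in the molecular protocol is carried in the
# result metadata; on an explicit reaction-coordinate landscape holding the
# scanned coordinate at the grid value plays the role of the stiff restraint.

#' One- or two-dimensional constrained scan of a landscape
#'
#' @param spec a [landscape_spec()].
#' @param axes axis name(s) or index(es) to scan.
#' @param values numeric vector of scan values (1 axis), or a matrix/list of
#'   per-axis value vectors whose full grid is scanned.
#' @param grad_tol convergence tolerance on the orthogonal gradient norm,
#'   kcal mol^-1 A^-1 (default 0.001).
#' @param restraint_k restraint force constant recorded with the scan
#'   protocol, kcal mol^-1 A^-2 (default 1000; metadata only on an explicit
#'   coordinate landscape).
#' @param direction `"forward"` (ascending warm start), `"backward"`, or
#'   `"both"` (returns a list of the two scans, exposing hysteresis).
#' @return A `scan_result`: data frame of scanned values, relaxed orthogonal
#'   coordinates, unbiased `energy` (kcal/mol) and a `converged` flag, with
#'   the protocol recorded as attributes.  Non-convergence at a point flags
#'   that point and the scan continues.
#' @export
constrained_scan <- function(spec, axes = 1, values, grad_tol = 0.001,
                             restraint_k = 1000,
                             direction = c("forward", "backward", "both")) {
  direction <- match.arg(direction)
  if (direction == "both") {
    return(list(
      forward = constrained_scan(spec, axes, values, grad_tol, restraint_k,
                                 "forward"),
      backward = constrained_scan(spec, axes, values, grad_tol, restraint_k,
                                  "backward")))
  }
  if (is.character(axes)) axes <- match(axes, spec$axis_names)
  if (anyNA(axes)) stop("unknown scan axis name")
  stopifnot(all(axes %in% seq_len(spec$dim)))
  if (is.list(values)) {
    g <- expand.grid(rev(values), KEEP.OUT.ATTRS = FALSE)
    values <- as.matrix(g[, rev(seq_along(values)), drop = FALSE])
  }
  V <- if (is.null(dim(values))) matrix(values, ncol = 1) else values
  stopifnot(ncol(V) == length(axes))
  ord <- seq_len(nrow(V))
  if (direction == "backward") ord <- rev(ord)
  orth <- setdiff(seq_len(spec$dim), axes)
  vf <- potential_fun(spec); gf <- gradient_fun(spec)
  lo <- spec$domain[1, ]; hi <- spec$domain[2, ]
  x_warm <- (lo + hi)[orth] / 2
  n <- nrow(V)
  energy <- numeric(n); converged <- logical(n)
  relaxed <- matrix(0, n, spec$dim, dimnames = list(NULL, spec$axis_names))
  for (i in ord) {
    pt <- numeric(spec$dim)
    pt[axes] <- V[i, ]
    if (length(orth) == 0L) {
      energy[i] <- vf(pt); converged[i] <- TRUE
      relaxed[i, ] <- pt
      next
    }
    fn <- function(y) { pt[orth] <- y; vf(pt) }
    gr <- function(y) { pt[orth] <- y; gf(pt)[orth] }
    res <- stats::optim(x_warm, fn, gr, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    y <- pmin(pmax(res$par, lo[orth]), hi[orth])
    gnorm <- sqrt(sum(gr(y)^2))
    pt[orth] <- y
    relaxed[i, ] <- pt
    energy[i] <- vf(pt)
    converged[i] <- gnorm <= grad_tol
    x_warm <- y
  }
  out <- as.data.frame(V)
  names(out) <- paste0("scan_", spec$axis_names[axes])
  out <- cbind(out, as.data.frame(relaxed), energy = energy,
               converged = converged)
  structure(out, class = c("scan_result", "data.frame"),
            axes = spec$axis_names[axes], grad_tol = grad_tol,
            restraint_k = restraint_k, direction = direction)
}

#' Report sudden energy jumps (kinks) along a scan profile
#'
#' A kink -- an energy change between adjacent grid points exceeding
#' `threshold` -- is the diagnostic that the scanned coordinate misses a
#' degree of freedom (typically an orthogonal coordinate snapping to another
#' basin, i.e. scan hysteresis).
#'
#' @param result a `scan_result` from [constrained_scan()] (>= 3 points), or
#'   any data frame with an `energy` column.
#' @param threshold jump magnitude threshold in kcal/mol (default 1).
#' @return Data frame with one row per kink: `index` (left grid point),
#'   `location` (midpoint of the two scan values, first scanned axis) and
#'   `jump` (signed energy change, kcal/mol), ordered along the scan.
#' @export
profile_kink_report <- function(result, threshold = 1) {
  e <- result$energy
  if (length(e) < 3) stop("a kink report needs at least 3 grid points")
  d <- diff(e)
  idx <- which(abs(d) > threshold)
  scan_cols <- grep("^scan_", names(result), value = TRUE)
  loc <- if (length(scan_cols) > 0)
    (result[[scan_cols[1]]][idx] + result[[scan_cols[1]]][idx + 1]) / 2
  else (idx + 0.5)
  data.frame(index = idx, location = loc, jump = d[idx])
}
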