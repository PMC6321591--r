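# Minimum-(free-)energy paths on gridded 2D surfaces.
#
# The grid of energy values becomes a weighted graph: occupied bins are
# nodes, each node is linked to its next neighbours (connectivity 4 or 8),
# and every edge carries the HIGHER of the two node energies as its weight.
# The path between the reactant and product minima is the shortest path on
# this graph (Dijkstra, summed edge weights; a minimax criterion is offered
# for comparison only).

#' Convert a gridded 2D energy surface into a weighted graph
#'
#' @param grid a 2D [pmf_grid], or a list with `centers` (list of two axis
#'   centre vectors) and `F` (energy vector/matrix; NA = masked bin).
#' @param connectivity 4 (nearest neighbours) or 8 (+ diagonals).
#' @return A `grid_graph`: node energies on the full grid (NA where masked),
#'   axis centres, dimensions and connectivity.  Node ids run axis-1-major
#'   (axis 1 slowest), giving a lexicographic (ix, iy) order.
#' @export
grid_to_graph <- function(grid, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  if (inherits(grid, "pmf_grid")) {
    if (length(grid$centers) != 2) stop("a 2D grid is required")
    x <- grid$centers[[1]]; y <- grid$centers[[2]]
    E <- grid$F
  } else {
    x <- grid$centers[[1]]; y <- grid$centers[[2]]
    E <- as.vector(t(as.matrix(grid$F)))
    if (is.matrix(grid$F)) {
      stopifnot(nrow(grid$F) == length(x), ncol(grid$F) == length(y))
      E <- as.vector(t(grid$F))  # axis-1-major flattening
    }
  }
  nx <- length(x); ny <- length(y)
  stopifnot(length(E) == nx * ny)
  if (sum(!is.na(E)) < 2) stop("need at least 2 occupied bins")
  structure(list(dims = c(nx, ny), x = x, y = y, energy = E,
                 occupied = !is.na(E), connectivity = connectivity),
            class = "grid_graph")
}

#' @export
print.grid_graph <- function(x, ...) {
  cat(sprintf("grid_graph: %d x %d bins (%d occupied), connectivity %d\n",
              x$dims[1], x$dims[2], sum(x$occupied), x$connectivity))
  invisible(x)
}

.neighbour_offsets <- function(connectivity) {
  o <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8)
    o <- rbind(o, c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  o
}

#' Enumerate the edges of a grid graph
#'
#' Each undirected edge is listed once (`from < to`) with its weight, the
#' maximum of the two endpoint energies.
#'
#' @param graph a `grid_graph`.
#' @return Data frame with columns `from`, `to`, `weight`.
#' @export
graph_edges <- function(graph) {
  nx <- graph$dims[1]; ny <- graph$dims[2]
  offs <- .neighbour_offsets(graph$connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    dx <- offs[r, 1]; dy <- offs[r, 2]
    ix <- rep(seq_len(nx), each = ny); iy <- rep(seq_len(ny), times = nx)
    jx <- ix + dx; jy <- iy + dy
    ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
    a <- (ix - 1L) * ny + iy
    b <- pmin(pmax((jx - 1L) * ny + jy, 1L), nx * ny)
    keep <- ok & graph$occupied[a] & graph$occupied[b] & a < b
    from <- c(from, a[keep]); to <- c(to, b[keep])
  }
  data.frame(from = from, to = to,
             weight = pmax(graph$energy[from], graph$energy[to]))
}

#' Local minima of a gridded surface
#'
#' Occupied bins whose energy is strictly below all occupied neighbours
#' (using the graph's connectivity), ordered by increasing energy.
#'
#' @param graph a `grid_graph`.
#' @return Data frame with `node`, `ix`, `iy`, axis values and `energy`.
#' @export
find_grid_minima <- function(graph) {
  nx <- graph$dims[1]; ny <- graph$dims[2]
  offs <- .neighbour_offsets(graph$connectivity)
  is_min <- graph$occupied
  for (r in seq_len(nrow(offs))) {
    ix <- rep(seq_len(nx), each = ny); iy <- rep(seq_len(ny), times = nx)
    jx <- ix + offs[r, 1]; jy <- iy + offs[r, 2]
    ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
    a <- (ix - 1L) * ny + iy
    b <- ifelse(ok, (jx - 1L) * ny + jy, a)
    nb_occ <- ok & graph$occupied[b]
    worse <- nb_occ & graph$energy[b] <= graph$energy[a]
    is_min <- is_min & !worse
  }
  node <- which(is_min)
  ix <- (node - 1L) %/% ny + 1L
  iy <- (node - 1L) %% ny + 1L
  out <- data.frame(node = node, ix = ix, iy = iy,
                    x = graph$x[ix], y = graph$y[iy],
                    energy = graph$energy[node])
  out[order(out$energy), , drop = FALSE]
}

.node_of <- function(graph, at) {
  ny <- graph$dims[2]
  if (length(at) == 1L) return(as.integer(at))
  if (length(at) == 2L) return((as.integer(at[1]) - 1L) * ny +
                                 as.integer(at[2]))
  stop("give a node id or a c(ix, iy) bin index pair")
}

#' Shortest (minimum-energy) path on a grid graph
#'
#' Dijkstra's algorithm on the weighted grid graph.  The total path cost is
#' the sum of edge weights (each the max of its endpoint energies); ties in
#' the priority queue are broken deterministically towards the smallest node
#' id (lexicographic (ix, iy) order), and a relaxation only replaces a
#' predecessor on strict improvement, so the returned path is unique and
#' stable.  `criterion = "minimax"` instead minimises the largest edge
#' weight along the path (comparison mode).
#'
#' @param graph a `grid_graph`.
#' @param from,to start / end bins as `c(ix, iy)` pairs or node ids.  If
#'   omitted, the two lowest distinct local minima are used (the lower-energy
#'   one as `from`).
#' @param criterion `"sum"` (default) or `"minimax"`.
#' @return A `grid_path`: data frame with node ids, bin indices, axis values
#'   (A), per-node `energy`, accumulated Euclidean `length` (A), plus
#'   attributes `total_weight` and `criterion`.  Errors if the endpoints are
#'   masked or not connected.
#' @export
shortest_path <- function(graph, from = NULL, to = NULL,
                          criterion = c("sum", "minimax")) {
  criterion <- match.arg(criterion)
  if (is.null(from) || is.null(to)) {
    m <- find_grid_minima(graph)
    if (nrow(m) < 2)
      stop("fewer than two local minima; give `from` and `to` explicitly")
    if (is.null(from)) from <- m$node[1]
    if (is.null(to)) to <- m$node[2]
  }
  s <- .node_of(graph, from); t <- .node_of(graph, to)
  if (s == t) stop("start and end nodes must differ")
  if (!graph$occupied[s] || !graph$occupied[t])
    stop("start or end bin is masked (unoccupied)")
  if (min(graph$energy, na.rm = TRUE) < 0)
    stop("negative node energies: Dijkstra needs non-negative edge ",
         "weights -- min-shift the grid (as a PMF is by construction)")
  nx <- graph$dims[1]; ny <- graph$dims[2]
  n <- nx * ny
  offs <- .neighbour_offsets(graph$connectivity)
  dist <- rep(Inf, n); dist[s] <- 0
  prev <- rep(NA_integer_, n)
  done <- !graph$occupied           # masked bins never enter the queue
  E <- graph$energy
  repeat {
    u <- which.min(replace(dist, done, Inf))  # first min = smallest node id
    if (!is.finite(dist[u]) || done[u])
      stop("no path between the requested nodes (grid disconnected)")
    done[u] <- TRUE
    if (u == t) break
    uix <- (u - 1L) %/% ny + 1L; uiy <- (u - 1L) %% ny + 1L
    for (r in seq_len(nrow(offs))) {
      vx <- uix + offs[r, 1]; vy <- uiy + offs[r, 2]
      if (vx < 1L || vx > nx || vy < 1L || vy > ny) next
      v <- (vx - 1L) * ny + vy
      if (done[v]) next
      w <- max(E[u], E[v])
      alt <- if (criterion == "sum") dist[u] + w else max(dist[u], w)
      if (alt < dist[v]) { dist[v] <- alt; prev[v] <- u }
    }
  }
  path <- t
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  ix <- (path - 1L) %/% ny + 1L
  iy <- (path - 1L) %% ny + 1L
  px <- graph$x[ix]; py <- graph$y[iy]
  seg <- sqrt(diff(px)^2 + diff(py)^2)
  out <- data.frame(node = path, ix = ix, iy = iy, x = px, y = py,
                    energy = E[path], length = c(0, cumsum(seg)))
  structure(out, class = c("grid_path", "data.frame"),
            total_weight = dist[t], criterion = criterion)
}

#' Energy profile along a path
#'
#' The abscissa is the accumulated Euclidean path length in
#' reaction-coordinate space (the canonical reaction coordinate), starting
#' at zero.
#'
#' @param path a `grid_path` (from [shortest_path()]) or `chain_path`.
#' @return Data frame with columns `length` (A) and `energy` (kcal/mol).
#' @export
profile_along_path <- function(path) {
  if (inherits(path, "chain_path")) {
    len <- canonical_rc(path)
    return(data.frame(length = len, energy = path$energies))
  }
  data.frame(length = path$length, energy = path$energy)
}

# Collapse runs of (numerically) equal consecutive energies to the run
# midpoint; returns indices into the original profile.
.collapse_plateaus <- function(e, eps = 1e-9) {
  keep <- integer(0)
  i <- 1L
  n <- length(e)
  while (i <= n) {
    j <- i
    while (j < n && abs(e[j + 1] - e[i]) <= eps) j <- j + 1L
    keep <- c(keep, (i + j) %/% 2L)
    i <- j + 1L
  }
  keep
}

#' Label stationary states along a reaction profile
#'
#' Finds the interior strict local extrema of an energy-vs-path-length
#' profile (after optional moving-average smoothing; plateau runs are
#' collapsed to their midpoint), labels them alternately as transition
#' states (`TS1`, `TS2`, ...) and intermediates (`IM1`, ...), with the path
#' endpoints labelled `reactant` and `product`.  The barrier is the energy
#' of the HIGHEST transition state minus the reference energy; the reaction
#' energy is `E(product) - E(reference)`.
#'
#' @param profile data frame with `length` and `energy` (>= 3 points), e.g.
#'   from [profile_along_path()].
#' @param smoothing odd moving-average window width in points (0 = none).
#' @param reference label of the reference state (default `"reactant"`,
#'   i.e. the state the transfer starts from).
#' @param min_prominence drop adjacent extremum pairs whose energy contrast
#'   is below this value (kcal/mol); 0 keeps all strict extrema.
#' @return A `stationary_report`: data frame of labelled states (label,
#'   path position, energy, energy relative to the reference) with
#'   attributes `barrier`, `reaction_energy`, `reference` and `no_ts` (TRUE
#'   for a monotone profile without interior maximum).
#' @export
locate_states <- function(profile, smoothing = 0, reference = "reactant",
                          min_prominence = 0) {
  e <- profile$energy; len <- profile$length
  if (length(e) < 3) stop("profile needs at least 3 points")
  if (smoothing > 1) {
    k <- as.integer(smoothing); if (k %% 2L == 0L) k <- k + 1L
    pad <- (k - 1L) %/% 2L
    ep <- c(rep(e[1], pad), e, rep(e[length(e)], pad))
    e <- as.numeric(stats::filter(ep, rep(1 / k, k), sides = 2))[
      (pad + 1):(pad + length(profile$energy))]
  }
  keep <- .collapse_plateaus(e)
  ec <- e[keep]
  m <- length(ec)
  kind <- character(0); idx <- integer(0)
  if (m >= 3) {
    for (i in 2:(m - 1)) {
      if (ec[i] > ec[i - 1] && ec[i] > ec[i + 1]) {
        kind <- c(kind, "max"); idx <- c(idx, i)
      } else if (ec[i] < ec[i - 1] && ec[i] < ec[i + 1]) {
        kind <- c(kind, "min"); idx <- c(idx, i)
      }
    }
  }
  # prominence pruning: repeatedly drop the adjacent extremum pair with the
  # smallest contrast until all contrasts >= min_prominence
  if (min_prominence > 0 && length(idx) > 0) {
    repeat {
      if (length(idx) == 0) break
      ev <- ec[idx]
      contr <- abs(diff(c(ec[1], ev, ec[m])))
      # contrast of pair (i, i+1) within the alternating sequence
      pair_contr <- abs(diff(ev))
      if (length(pair_contr) == 0) {
        if (min(contr) < min_prominence) { idx <- integer(0); kind <- character(0) }
        break
      }
      worst <- which.min(pair_contr)
      if (pair_contr[worst] >= min_prominence) break
      idx <- idx[-c(worst, worst + 1)]
      kind <- kind[-c(worst, worst + 1)]
    }
  }
  labs <- character(length(idx))
  labs[kind == "max"] <- paste0("TS", seq_len(sum(kind == "max")))
  labs[kind == "min"] <- paste0("IM", seq_len(sum(kind == "min")))
  all_idx <- c(1L, idx, m)
  all_lab <- c("reactant", labs, "product")
  orig <- keep[all_idx]
  states <- data.frame(label = all_lab, position = len[orig],
                       index = orig, energy = profile$energy[orig])
  ref_row <- match(reference, states$label)
  if (is.na(ref_row)) stop("reference label '", reference, "' not found")
  eref <- states$energy[ref_row]
  states$relative_energy <- states$energy - eref
  no_ts <- !any(kind == "max")
  barrier <- if (no_ts) NA_real_ else
    max(states$energy[grepl("^TS", states$label)]) - eref
  reaction <- states$energy[states$label == "product"] - eref
  structure(states, class = c("stationary_report", "data.frame"),
            barrier = barrier, reaction_energy = reaction,
            reference = reference, no_ts = no_ts)
}

#' @export
print.stationary_report <- function(x, ...) {
  cat("Stationary states along the path (reference: ",
      attr(x, "reference"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (isTRUE(attr(x, "no_ts"))) {
    cat("No interior transition state (monotone profile)\n")
  } else {
    cat(sprintf("barrier: %.3f kcal/mol   reaction energy: %.3f kcal/mol\n",
                attr(x, "barrier"), attr(x, "reaction_energy")))
  }
  invisible(x)
}
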