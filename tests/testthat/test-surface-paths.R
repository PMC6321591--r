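grid2d <- function(E) {
  # E: nx x ny energy matrix on unit-spaced centers
  list(centers = list(seq_len(nrow(E)), seq_len(ncol(E))), F = E)
}

test_that("edge weights are the max of the endpoint energies", {
  g <- grid_to_graph(grid2d(matrix(c(1, 3), 2, 1)))
  e <- graph_edges(g)
  expect_identical(nrow(e), 1L)
  expect_equal(e$weight, 3)

  g2 <- grid_to_graph(grid2d(matrix(7, 2, 2)))
  e2 <- graph_edges(g2)
  expect_identical(nrow(e2), 4L)
  expect_true(all(e2$weight == 7))

  set.seed(5)
  E <- matrix(runif(9, 0, 10), 3, 3)
  e3 <- graph_edges(grid_to_graph(grid2d(E)))
  Ef <- as.vector(t(E))   # axis-1-major node energies
  expect_equal(e3$weight, pmax(Ef[e3$from], Ef[e3$to]))
})

test_that("Dijkstra avoids the expensive corner and sums max-edge weights", {
  E <- matrix(c(0, 1, 10, 0), 2, 2, byrow = TRUE)  # (1,1)=0 (1,2)=1
  p <- shortest_path(grid_to_graph(grid2d(E)), from = c(1, 1), to = c(2, 2))
  expect_equal(attr(p, "total_weight"), 2)          # through the 1-node
  expect_identical(p$ix, c(1L, 1L, 2L))
  expect_identical(p$iy, c(1L, 2L, 2L))

  flat <- matrix(2.5, 4, 5)
  pf <- shortest_path(grid_to_graph(grid2d(flat)), from = c(1, 1),
                      to = c(4, 5))
  expect_equal(attr(pf, "total_weight"), 2.5 * (3 + 4))  # Manhattan distance
})

test_that("random grids match the exhaustive-enumeration optimum", {
  for (seed in 1:25) {
    set.seed(seed)
    E <- matrix(sample(0:9, 16, replace = TRUE), 4, 4)
    p <- shortest_path(grid_to_graph(grid2d(E)), from = c(1, 1),
                       to = c(4, 4))
    expect_equal(attr(p, "total_weight"),
                 brute_force_path_weight(E, c(1, 1), c(4, 4)))
  }
})

test_that("path cost is monotone under raising a node and shifts under constants", {
  set.seed(9)
  E <- matrix(runif(25, 0, 5), 5, 5)
  g <- grid_to_graph(grid2d(E))
  p <- shortest_path(g, from = c(1, 1), to = c(5, 5))
  w0 <- attr(p, "total_weight")
  for (r in 1:10) {
    E2 <- E
    i <- sample(25, 1)
    E2[i] <- E2[i] + runif(1, 0, 5)
    p2 <- shortest_path(grid_to_graph(grid2d(E2)), from = c(1, 1),
                        to = c(5, 5))
    expect_gte(attr(p2, "total_weight"), w0 - 1e-12)
  }
  p3 <- shortest_path(grid_to_graph(grid2d(E + 11)), from = c(1, 1),
                      to = c(5, 5))
  expect_identical(p3$node, p$node)   # same path
  n_edges <- nrow(p) - 1
  expect_equal(attr(p3, "total_weight"), w0 + 11 * n_edges)
})

test_that("masked bins and disconnected grids are reported", {
  E <- matrix(0, 3, 3)
  E[2, ] <- NA   # wall of masked bins
  g <- grid_to_graph(grid2d(E))
  expect_error(shortest_path(g, from = c(2, 1), to = c(3, 3)), "masked")
  expect_error(shortest_path(g, from = c(1, 1), to = c(3, 3)),
               "no path|disconnected")
  expect_error(shortest_path(g, from = c(1, 1), to = c(1, 1)), "differ")
})

test_that("accumulated path length is Euclidean in coordinate units", {
  pts <- list(centers = list(c(0, 0.02, 0.04), c(0, 0.02)),
              F = matrix(1, 3, 2))
  g <- grid_to_graph(pts)
  p <- shortest_path(g, from = c(1, 1), to = c(3, 1))
  expect_equal(p$length, c(0, 0.02, 0.04))
  g8 <- grid_to_graph(pts, connectivity = 8)
  p8 <- shortest_path(g8, from = c(1, 1), to = c(2, 2))
  expect_equal(p8$length, c(0, 0.02 * sqrt(2)))
  prof <- profile_along_path(p)
  expect_true(all(diff(prof$length) > 0))
})

test_that("minimax criterion bounds the summed-weight bottleneck", {
  set.seed(13)
  E <- matrix(runif(36, 0, 8), 6, 6)
  g <- grid_to_graph(grid2d(E))
  psum <- shortest_path(g, from = c(1, 1), to = c(6, 6))
  pmax_ <- shortest_path(g, from = c(1, 1), to = c(6, 6),
                         criterion = "minimax")
  expect_lte(attr(pmax_, "total_weight"),
             max(pmax(psum$energy[-1], psum$energy[-nrow(psum)])) + 1e-12)
})

test_that("stationary-state labelling follows the highest-TS convention", {
  prof <- data.frame(length = c(0, 1, 2), energy = c(0, 5.4, -6.8))
  rep <- locate_states(prof)
  expect_identical(rep$label, c("reactant", "TS1", "product"))
  expect_equal(attr(rep, "barrier"), 5.4)
  expect_equal(attr(rep, "reaction_energy"), -6.8)

  mono <- data.frame(length = 0:4, energy = c(0, 1, 2, 3, 4))
  rep2 <- locate_states(mono)
  expect_true(attr(rep2, "no_ts"))
  expect_identical(rep2$label, c("reactant", "product"))

  two <- data.frame(length = 0:6,
                    energy = c(0, 3, 1, 7, 2, 2.5, -1))
  rep3 <- locate_states(two)
  expect_equal(attr(rep3, "barrier"), 7)   # the higher of the two maxima

  plateau <- data.frame(length = 0:5, energy = c(0, 4, 4, 4, 1, 2))
  rep4 <- locate_states(plateau)
  ts <- rep4[rep4$label == "TS1", ]
  expect_identical(ts$index, 3L)           # plateau collapsed to midpoint
})

test_that("default endpoints are the two lowest grid minima", {
  sp <- landscape_spec("two_basin_2d")
  xs <- seq(-1.8, 1.8, 0.05); ys <- seq(-1.2, 1.2, 0.05)
  E <- matrix(eval_potential(sp, as.matrix(expand.grid(xs, ys))),
              length(xs))
  # negative energies are rejected (Dijkstra needs non-negative weights);
  # a min-shifted grid -- the PMF convention -- is accepted
  expect_error(shortest_path(grid_to_graph(
    list(centers = list(xs, ys), F = E))), "min-shift")
  g <- grid_to_graph(list(centers = list(xs, ys), F = E - min(E)))
  m <- find_grid_minima(g)
  expect_identical(nrow(m), 2L)
  p <- shortest_path(g)
  expect_identical(p$node[1], m$node[1])
  expect_identical(p$node[nrow(p)], m$node[2])
  # the path's highest point is within a bin of the true saddle (0, 0)
  top <- p[which.max(p$energy), ]
  expect_lt(abs(top$x), 0.05 + 1e-9)
  expect_lt(abs(top$y), 0.05 + 1e-9)
})

test_that("grid paths cross the step-like surfaces at the saddle", {
  for (form in c("psp_step1_like", "psp_step2_like")) {
    sp <- landscape_spec(form)
    xs <- seq(sp$domain[1, 1], sp$domain[2, 1], 0.02)
    ys <- seq(sp$domain[1, 2], sp$domain[2, 2], 0.02)
    E <- matrix(eval_potential(sp, as.matrix(expand.grid(xs, ys))),
                length(xs))
    g <- grid_to_graph(list(centers = list(xs, ys), F = E - min(E)))
    rep <- landscape_report(sp)
    mins <- rep[rep$label == "min", ]
    sad <- rep[rep$label == "saddle", ][1, ]
    near <- function(px, py) c(which.min(abs(xs - px)),
                               which.min(abs(ys - py)))
    from <- near(mins$OPO[1], mins$OHO[1])
    to <- near(mins$OPO[2], mins$OHO[2])
    # minimax (bottleneck) path: highest point within one bin of the saddle
    pm <- shortest_path(g, from = from, to = to, criterion = "minimax")
    topm <- pm[which.max(pm$energy), ]
    expect_lt(abs(topm$x - sad$OPO), 0.02 + 1e-9)
    expect_lt(abs(topm$y - sad$OHO), 0.02 + 1e-9)
    # summed-weight path: the ridge is plateau-like along OHO, so the
    # crossing can drift along the ridge, but its height matches the
    # saddle and its OPO position pins the ridge
    ps <- shortest_path(g, from = from, to = to)
    tops <- ps[which.max(ps$energy), ]
    expect_lt(abs(tops$x - sad$OPO), 0.1 + 1e-9)
    expect_lt(abs(max(ps$energy) - (sad$energy - min(E))), 0.6)
  }
})
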