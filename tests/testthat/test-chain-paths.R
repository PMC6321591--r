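test_that("arc-length resampling hits the requested spacing", {
  cp <- chain_path(rbind(c(0, 0), c(0.05, 0), c(0.1, 0)))
  rp <- reparameterize(cp, spacing = 0.01)
  expect_identical(nrow(rp$points), 11L)
  seg <- diff(rp$points[, 1])
  expect_true(all(abs(seg - 0.01) < 1e-9))
  expect_identical(rp$points[1, ], cp$points[1, ])
  expect_identical(rp$points[11, ], cp$points[3, ])
  expect_error(reparameterize(cp, spacing = 0.2), "spacing")
})

test_that("resampling an already-equidistant chain is the identity", {
  x <- seq(0, 1, 0.01)
  cp <- chain_path(cbind(x, 0.5 * x))
  rp <- reparameterize(cp, spacing = sqrt(1 + 0.25) * 0.01)
  expect_identical(nrow(rp$points), nrow(cp$points))
  expect_lt(max(abs(rp$points - cp$points)), 1e-12)
})

test_that("resampled arc lengths are uniform on a circular arc", {
  set.seed(17)
  th <- c(0, sort(runif(60, 0, pi / 2)), pi / 2)
  cp <- chain_path(cbind(cos(th), sin(th)))
  rp <- reparameterize(cp, spacing = 0.02)
  # dense oracle: arc length along the original polyline, 1000x oversampled
  th_d <- seq(0, pi / 2, length.out = 60000)
  dense <- cbind(cos(th_d), sin(th_d))
  arc_of <- function(p) {
    i <- which.min((dense[, 1] - p[1])^2 + (dense[, 2] - p[2])^2)
    th_d[i]
  }
  arcs <- apply(rp$points, 1, arc_of)
  # chord spacing 0.02 on a unit circle ~ arc spacing 0.02 (to O(h^3));
  # uniformity of consecutive differences is the property under test
  d <- diff(arcs[-length(arcs)])
  expect_lt(max(abs(d - mean(d))), 2e-3)
})

test_that("chain minimisation settles an offset chain onto the valley floor", {
  # flat along x, stiff along y: a true separable valley with floor y = 0
  sp <- landscape_spec("harmonic", params = list(stiffness = c(0, 2),
                                                 center = c(0, 0)))
  x <- seq(-1, 1, 0.05)
  cp <- chain_path(cbind(x, 0.4))       # offset from the y = 0 valley
  out <- synchronous_chain_minimize(sp, cp, tol = 4e-4,
                                    respace_every = 0, max_iter = 20000)
  expect_true(attr(out, "converged"))
  m <- nrow(out$points)
  # the fixed endpoints (y = 0.4) tilt the local tangent at their
  # neighbours, shrinking the projected gradient there; deep interior
  # points reach the floor tightly, endpoint neighbours less so
  expect_lt(max(abs(out$points[3:(m - 2), 2])), 1e-3)
  expect_lt(max(abs(out$points[c(2, m - 1), 2])), 5e-3)
  # endpoints never move
  expect_identical(out$points[1, ], cp$points[1, ])
  expect_identical(out$points[nrow(out$points), ], cp$points[nrow(cp$points), ])
})

test_that("a chain already on the valley floor is a fixed point", {
  sp <- landscape_spec("harmonic", params = list(stiffness = 2,
                                                 center = c(0, 0)))
  x <- seq(-1, 1, 0.05)
  cp <- chain_path(cbind(x, 0))
  out <- synchronous_chain_minimize(sp, cp, tol = 0.01, respace_every = 0)
  expect_true(attr(out, "converged"))
  expect_identical(attr(out, "iterations"), 1L)
  expect_lt(max(abs(out$points - cp$points)), 1e-12)
})

test_that("the chain maximum never increases during minimisation", {
  sp <- landscape_spec("two_basin_2d")
  x <- seq(-0.94, 0.94, length.out = 41)
  cp <- chain_path(cbind(x, -0.38 + 0.76 * (x + 0.94) / 1.88 + 0.3))
  maxes <- c()
  path <- cp
  for (k in 1:40) {
    path <- synchronous_chain_minimize(sp, path, tol = 1e-6, max_iter = 1,
                                       respace_every = 0)
    maxes <- c(maxes, max(path$energies))
  }
  expect_true(all(diff(maxes) <= 1e-10))
})

test_that("chain + peak refinement find the two-basin saddle", {
  sp <- landscape_spec("two_basin_2d")
  rep <- landscape_report(sp)
  mins <- rep[rep$label == "min", ]
  cp <- chain_path(rbind(
    as.numeric(mins[1, c("x", "y")]),
    c(0, 0.3),
    as.numeric(mins[2, c("x", "y")])))
  cp <- reparameterize(cp, spacing = 0.05, spec = sp)
  cp <- synchronous_chain_minimize(sp, cp, tol = 0.05)
  ref <- refine_peak(sp, cp)
  oracle <- newton_saddle(sp, c(0.05, -0.03))
  expect_true(ref$certified)
  expect_lt(sqrt(sum((ref$point - oracle$x)^2)), 1e-3)
  expect_lt(abs(ref$energy - oracle$energy), 1e-3)
  expect_identical(sum(ref$eigenvalues < 0), 1L)
  # converged chain barrier matches the known saddle energy
  expect_lt(abs(max(cp$energies) - oracle$energy), 0.05)
})

test_that("peak refinement recovers the closed-form double-well barrier", {
  sp <- landscape_spec("double_well_1d", params = list(h = 5, a = 1))
  cp <- chain_path(cbind(seq(-1, 1, 0.05)), spec = sp)
  ref <- refine_peak(sp, cp)
  expect_lt(abs(ref$point - 0), 1e-8)
  expect_equal(ref$energy, 5, tolerance = 1e-10)
  expect_true(ref$certified)
  # saddle of the step-1 surface agrees with the Newton oracle
  sp1 <- landscape_spec("psp_step1_like")
  rep <- landscape_report(sp1)
  sad <- rep[rep$label == "saddle", ][1, ]
  mins <- rep[rep$label == "min", ]
  cp1 <- reparameterize(chain_path(rbind(
    as.numeric(mins[1, c("OPO", "OHO")]),
    as.numeric(sad[c("OPO", "OHO")]) + c(0.05, -0.05),
    as.numeric(mins[2, c("OPO", "OHO")]))), spacing = 0.05, spec = sp1)
  ref1 <- refine_peak(sp1, cp1)
  oracle1 <- newton_saddle(sp1, as.numeric(sad[c("OPO", "OHO")]))
  expect_lt(sqrt(sum((ref1$point - oracle1$x)^2)), 1e-3)
  expect_lt(abs(ref1$energy - oracle1$energy), 1e-3)
})

test_that("refine_peak rejects a chain without an interior maximum", {
  sp <- landscape_spec("harmonic", params = list(stiffness = 2))
  cp <- chain_path(cbind(seq(0.1, 1, 0.1)), spec = sp)
  expect_error(refine_peak(sp, cp), "interior")
})
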