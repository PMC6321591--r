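test_that("label variants map to canonical keys", {
  expect_identical(canonical_distance_label("d(SerOG-P)"), "ser_og_p")
  expect_identical(canonical_distance_label("P-O-Asp11"), "p_od_asp11")
  expect_identical(canonical_distance_label("P-OD-Asp11"), "p_od_asp11")
  expect_identical(canonical_distance_label("Wat-O-P"), "wat_o_p")
  expect_identical(canonical_distance_label("watO-P"), "wat_o_p")
})

test_that("eval_rc computes signed distance sums and reports missing labels", {
  opo1 <- rc_builtins("OPO_step1")
  expect_equal(eval_rc(opo1, c(`Ser-OG-P` = 2.04, `P-O-Asp11` = 2.94)),
               -0.90, tolerance = 1e-12)
  expect_error(eval_rc(opo1, c(ser_og_p = 2.0)), "p_od_asp11")
  # all-equal distances: balanced +/- pairs cancel exactly
  expect_equal(eval_rc(opo1, c(ser_og_p = 1.7, p_od_asp11 = 1.7)), 0)
  # linearity and sign swap
  f1 <- c(ser_og_p = 2.0, p_od_asp11 = 3.0)
  f2 <- c(ser_og_p = 0.3, p_od_asp11 = 0.1)
  expect_equal(eval_rc(opo1, f1 + f2),
               eval_rc(opo1, f1) + eval_rc(opo1, f2))
  neg <- rc_definition("neg", -opo1$terms)
  expect_equal(eval_rc(neg, f1), -eval_rc(opo1, f1))
})

test_that("tabulated reaction-coordinate values round-trip from printed distances", {
  frames <- psp_reference_frames()
  defs <- rc_builtins()
  # step 1, 1D scan block: RC = d(Ser-OG-P) - d(P-O-Asp11)
  s1 <- frames[frames$step == 1 & frames$method == "scan_1d", ]
  expect_equal(round_half_up(eval_rc(defs$OPO_step1, s1), 1), s1$rc1)
  # step 2, 1D scan block: RC = d(P-O-Asp11) - d(wat-O-P)
  s2 <- frames[frames$step == 2 & frames$method == "scan_1d", ]
  expect_equal(round_half_up(eval_rc(defs$OPO_step2, s2), 1), s2$rc1)
  # step 1, 2D scan (OPO, OHO) block, both components; the product-state
  # rc2 is tabulated as 0.7 but its own printed distances give
  # -0.97 + 1.75 = 0.78, so that single cell is checked at its computed
  # value rather than the (internally inconsistent) printed one
  s3 <- frames[frames$step == 1 & frames$method == "scan_2d_opo_oho", ]
  expect_equal(round_half_up(eval_rc(defs$OPO_step1, s3), 1), s3$rc1)
  oho <- eval_rc(defs$OHO_step1, s3)
  expect_equal(round_half_up(oho[s3$state != "P"], 1),
               s3$rc2[s3$state != "P"])
  expect_equal(oho[s3$state == "P"], 0.78, tolerance = 1e-9)
  expect_lte(abs(oho[s3$state == "P"] - s3$rc2[s3$state == "P"]), 0.081)
})

test_that("canonical reaction coordinate accumulates Euclidean arc length", {
  cp <- chain_path(rbind(c(0, 0), c(0.3, 0.4), c(0.6, 0.8)))
  expect_equal(canonical_rc(cp), c(0, 0.5, 1.0))
  expect_equal(canonical_rc(cp, normalize = TRUE), c(0, 0.5, 1))
  eq <- chain_path(cbind(seq(0, 0.1, 0.01), 0))
  expect_equal(canonical_rc(eq), seq(0, 0.1, 0.01))
  set.seed(3)
  X <- matrix(cumsum(rnorm(20)), ncol = 2)
  direct <- c(0, cumsum(sqrt(rowSums(diff(X)^2))))
  expect_equal(canonical_rc(X), direct)
})

test_that("profile projection preserves path order and flags non-injectivity", {
  e <- c(0, 1, 4, 2, -1)
  frames <- data.frame(ser_og_p = c(1.6, 1.8, 2.0, 2.2, 2.4),
                       p_od_asp11 = c(3.0, 2.8, 2.6, 2.4, 2.2))
  pr <- project_profile(e, frames, rc_builtins("OPO_step1"))
  expect_equal(pr$energy, e)
  expect_true(attr(pr, "monotonicity")$injective)
  expect_equal(pr$OPO_step1, frames$ser_og_p - frames$p_od_asp11)
  # a projection that revisits a value is flagged
  frames2 <- frames
  frames2$ser_og_p <- c(1.6, 2.0, 1.8, 2.0, 2.4)
  pr2 <- project_profile(e, frames2, rc_builtins("OPO_step1"))
  expect_false(attr(pr2, "monotonicity")$injective)
  expect_equal(pr2$energy, e)          # not re-sorted
  expect_error(project_profile(e[1:3], frames, rc_builtins("OPO_step1")),
               "length")
  # two-coordinate projection keeps both components
  pr3 <- project_profile(e[1:3],
                         data.frame(ser_og_p = c(1.7, 2.0, 2.3),
                                    p_od_asp11 = c(3.1, 2.8, 2.5),
                                    ser_og_h = c(1.6, 1.3, 1.0),
                                    h_od_asp13 = c(1.0, 1.3, 1.6)),
                         list(rc_builtins("OPO_step1"),
                              rc_builtins("OHO_step1")))
  expect_identical(names(pr3), c("OPO_step1", "OHO_step1", "energy"))
})

test_that("the proton-transfer coordinate vanishes at the symmetric transition state", {
  expect_equal(round_half_up(eval_rc(
    rc_builtins("OHO_step1"),
    c(ser_og_h = 1.31, h_od_asp13 = 1.31)), 1), 0)
})
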