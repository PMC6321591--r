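test_that("window grids reproduce the scan-grid arithmetic", {
  expect_length(build_window_grid(c(-1.5, 1.6), 0.1), 32)
  expect_length(build_window_grid(list(c(1.6, 3.2), c(1.6, 3.2)), 0.1), 289)
  expect_error(build_window_grid(c(0, 0.25), 0.1), "commensurate")
})

test_that("bias energy follows the k(x-c)^2 convention (no 1/2 factor)", {
  w <- bias_window("w", 0, k_prod = 200, k_equil = 1000)
  expect_identical(bias_energy(w, 0), 0)
  expect_equal(bias_energy(w, 0.1), 2.0)
  w2 <- bias_window("w", c(0, 0), k_prod = 200, k_equil = 1000)
  expect_equal(bias_energy(w2, c(0.1, -0.1), phase = "equilibration"), 20.0)
  expect_gte(bias_energy(w2, c(-0.3, 0.2)), 0)
})

test_that("sampling is reproducible from the seed and seed-sensitive", {
  sp <- landscape_spec("double_well_1d")
  w1 <- bias_window("w", 0.5, n_equil = 500, n_prod = 2000, seed = 7)
  a <- sample_window(sp, w1)
  b <- sample_window(sp, w1)
  expect_identical(a$values, b$values)
  w2 <- bias_window("w", 0.5, n_equil = 500, n_prod = 2000, seed = 8)
  c2 <- sample_window(sp, w2)
  expect_gt(max(abs(a$values - c2$values)), 1e-6)
  # the caller's RNG stream is untouched
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(sample_window(sp, w1)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("single-window variance matches kT/(2k) on a flat landscape", {
  sp <- landscape_spec("harmonic", params = list(stiffness = 0))
  w <- bias_window("w", 0, n_equil = 5000, n_prod = 100000,
                   seed = derive_seed(3, 1))
  s <- sample_window(sp, w, stride = 1)
  target <- 0.0019872041 * 300 / (2 * 200)
  expect_lt(abs(var(s$values[, 1]) / target - 1), 0.05)
})

test_that("sample mean matches the product-of-Gaussians closed form", {
  s_land <- 10; c_land <- 0.3; k <- 200; c_bias <- 0
  sp <- landscape_spec("harmonic",
                       params = list(stiffness = s_land, center = c_land),
                       domain = rbind(-2, 2))
  w <- bias_window("w", c_bias, n_equil = 5000, n_prod = 60000, seed = 19)
  s <- sample_window(sp, w, stride = 1)
  x <- s$values[, 1]
  want <- (s_land * c_land + 2 * k * c_bias) / (s_land + 2 * k)
  # batch-means standard error (20 batches) absorbs autocorrelation
  bm <- tapply(x, rep(1:20, each = length(x) / 20), mean)
  se <- sd(bm) / sqrt(20)
  expect_lt(abs(mean(x) - want), 3 * se)
})

test_that("window means sit at the biased-potential minimum on the step-1 surface", {
  sp <- landscape_spec("psp_step1_like")
  wins <- build_window_grid(list(c(-1.8, 1.4), c(-1.0, 1.0)), 0.4,
                            n_equil = 2000, n_prod = 8000, master_seed = 5)
  vf <- potential_fun(sp)
  for (w in wins) {
    s <- sample_window(sp, w, stride = 4)
    # oracle: numerical minimisation of V + U_bias from the window centre
    fn <- function(x) vf(x) + harmonic_bias(w$k_prod, x, w$centers)
    opt <- optim(w$centers, fn, method = "BFGS")
    mu <- colMeans(s$values)
    n <- nrow(s$values)
    bm <- apply(s$values, 2, function(v)
      tapply(v, rep(1:10, each = n / 10), mean))
    se <- apply(bm, 2, sd) / sqrt(10)
    expect_true(all(abs(mu - opt$par) <= 3 * se + 0.01))
  }
})

test_that("the production histogram follows exp(-(V+U)/kT)", {
  sp <- landscape_spec("harmonic", params = list(stiffness = 0))
  w <- bias_window("w", 0, n_equil = 5000, n_prod = 125000, seed = 23)
  s <- sample_window(sp, w, stride = 25)
  x <- s$values[, 1]
  sigma <- sqrt(0.0019872041 * 300 / (2 * 200))
  edges <- seq(-4 * sigma, 4 * sigma, length.out = 21)  # 20 bins
  x <- x[x >= edges[1] & x < edges[21]]
  counts <- tabulate(findInterval(x, edges), nbins = 20)
  p <- diff(pnorm(edges, 0, sigma))
  ct <- suppressWarnings(chisq.test(counts, p = p, rescale.p = TRUE))
  expect_gt(ct$p.value, 0.01)
})

test_that("recorded series preserve time ordering", {
  sp <- landscape_spec("harmonic", params = list(stiffness = 0))
  w <- bias_window("w", 0, n_equil = 1000, n_prod = 20000, seed = 31)
  s <- sample_window(sp, w, stride = 1)
  x <- s$values[, 1]
  # consecutive records of an unshuffled random walk are strongly correlated
  expect_gt(cor(x[-1], x[-length(x)]), 0.5)
})

test_that("derived seeds are deterministic, distinct and 32-bit safe", {
  s <- vapply(1:500, function(i) derive_seed(123456, i), 1L)
  expect_identical(s, vapply(1:500, function(i) derive_seed(123456, i), 1L))
  expect_identical(anyDuplicated(s), 0L)
  expect_true(all(s > 0 & s < 2^31))
})
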