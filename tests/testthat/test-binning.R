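test_that("snapshot means average the window and match global coords", {
  s <- sample_ensemble(tiny_spec(n_snapshots = 200))
  m <- snapshot_means(s, "h_twist", window = 2:5)
  g <- global_coords(s, 2:5)
  expect_equal(m * 4, unname(g$omega), tolerance = 1e-12)
  expect_error(snapshot_means(s, "roll"), "unknown parameter")
  expect_error(snapshot_means(s, "h_twist", window = integer(0)), "empty")
})

test_that("bin means of an exact line lie on the line", {
  x <- seq(-2, 2, length.out = 5000)
  y <- 2 * x
  b <- bin_xy(x, y, bin_width = 0.2)
  expect_equal(b$mean, 2 * b$x_mean, tolerance = 1e-12)
  f <- fit_slope(b, fit_halfwidth = 1.5)
  expect_equal(f$slope, 2, tolerance = 1e-8)
  expect_lt(f$slope_se, 1e-6)
  # doubling the window leaves the slope of linear data unchanged
  f2 <- fit_slope(b, fit_halfwidth = 3)
  expect_equal(f2$slope, f$slope, tolerance = 1e-8)
})

test_that("bin means of a bivariate Gaussian follow the conditional slope", {
  set.seed(8)
  n <- 50000
  beta <- 0.6
  x <- stats::rnorm(n, mean = 32, sd = 1)
  y <- 3.3 + beta * (x - 32) + stats::rnorm(n, sd = 0.3)
  b <- bin_xy(x, y, bin_width = 0.2)
  inside <- abs(b$center - 32) <= 1.5
  resid <- b$mean - (3.3 + beta * (b$center - mean(x)))
  expect_true(all(abs(resid[inside]) <= 4 * b$sem[inside]))
  f <- fit_slope(b)
  expect_lt(abs(f$slope - beta), 3 * f$slope_se)
  expect_gte(min(b$count), 50)
  # SEM definition: SD / sqrt(count) in each bin
  k <- which.max(b$count)
  sel <- floor(x / 0.2) == floor(b$center[k] / 0.2)
  expect_equal(b$sem[k], stats::sd(y[sel]) / sqrt(sum(sel)),
               tolerance = 1e-12)
})

test_that("degenerate and small inputs are handled", {
  b1 <- bin_xy(rep(1, 10), rep(2, 10), bin_width = 0.5)
  expect_equal(nrow(b1), 1)
  expect_true(is.finite(b1$sem))
  expect_error(bin_xy(numeric(0), numeric(0)), "empty")
  expect_error(fit_slope(b1), "need >= 3")
})

test_that("block errors behave like the SD of block means", {
  be <- block_errors(rep(5, 100), n_blocks = 5)
  expect_equal(be$error, 0)
  expect_equal(be$mean, 5)
  set.seed(9)
  v <- stats::rnorm(5000)
  be <- block_errors(v, n_blocks = 5)
  expect_equal(be$error, 1 / sqrt(1000), tolerance = 0.8)
  expect_equal(length(be$block_means), 5)
  # n_blocks = n reduces to the sample SD
  w <- stats::rnorm(20)
  expect_equal(block_errors(w, n_blocks = 20)$error, stats::sd(w),
               tolerance = 1e-12)
  expect_error(block_errors(1:3, n_blocks = 5), "shorter")
})

test_that("pmf surface is an occupancy free energy", {
  # near-uniform occupancy -> all-zero surface
  x <- rep(seq(0.05, 0.95, by = 0.1), each = 100)
  y <- rep(rep(seq(0.05, 0.95, by = 0.1), each = 10), 10)
  su <- pmf_surface(x, y, x_bin = 0.5, y_bin = 0.5, min_count = 1)
  expect_true(all(abs(su$value[!is.na(su$value)]) < 1e-12))
  # bivariate Gaussian: quadratic surface with Hessian kB T C^-1
  set.seed(10)
  n <- 200000
  X <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(matrix(c(1, .5, .5, 1), 2))
  su <- pmf_surface(X[, 1], X[, 2], x_bin = 0.25, y_bin = 0.25,
                    min_count = 200)
  xc <- (su$x_edges[-1] + su$x_edges[-length(su$x_edges)]) / 2
  yc <- (su$y_edges[-1] + su$y_edges[-length(su$y_edges)]) / 2
  d <- expand.grid(x = xc, y = yc)
  d$v <- as.vector(su$value)
  d$w <- as.vector(su$count)
  d <- d[!is.na(d$v), ]
  fit <- stats::lm(v ~ I(x^2) + I(x * y) + I(y^2) + x + y, data = d,
                   weights = d$w)
  H <- matrix(c(2 * stats::coef(fit)[["I(x^2)"]], stats::coef(fit)[["I(x * y)"]],
                stats::coef(fit)[["I(x * y)"]], 2 * stats::coef(fit)[["I(y^2)"]]),
              2, 2)
  H_expected <- 0.0019872 * 300 * solve(matrix(c(1, .5, .5, 1), 2))
  expect_equal(H, H_expected, tolerance = 0.2, ignore_attr = TRUE)
  expect_error(pmf_surface(numeric(0), numeric(0)), "empty")
})

test_that("surface valley tilt tracks the sign of the planted coupling", {
  for (cfg in list(list("dna", 0.032, +1), list("rna", -0.037, -1))) {
    sp <- plant_coupling(duplex_preset(cfg[[1]], seed = 17), cfg[[2]])
    s <- sample_ensemble(sp, n_snapshots = 20000)
    su <- pmf_surface(snapshot_means(s, "h_twist"),
                      snapshot_means(s, "h_rise"),
                      x_bin = 0.1, y_bin = 0.01, min_count = 20)
    expect_equal(sign(twistretch:::surface_tilt(su)), cfg[[3]])
  }
})
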