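test_that("global coordinates sum twist and rise over the window", {
  arr <- array(0, c(5, 12, 6),
               dimnames = list(NULL, NULL, twistretch:::.param_names))
  arr[, , "h_twist"] <- 32
  arr[, , "h_rise"] <- 3.3
  arr[, , "x_disp"] <- -1
  s <- helical_series(arr)
  g <- global_coords(s, 2:11)
  expect_equal(unname(g$omega), rep(320, 5))
  expect_equal(unname(g$l), rep(33, 5))
  g1 <- global_coords(s, 4)
  expect_equal(unname(g1$omega), rep(32, 5))
  expect_error(global_coords(s, 8:20), "\\[1, 12\\]")
})

test_that("covariance2 is the unbiased sample covariance", {
  arr <- array(0, c(2, 2, 6),
               dimnames = list(NULL, NULL, twistretch:::.param_names))
  # two snapshots with (omega, l) = (0, 0) and (2, 2) over a 2-step window
  arr[2, , "h_twist"] <- 1
  arr[2, , "h_rise"] <- 1
  arr[1, , "h_rise"] <- 1e-12  # keep rise positive
  g <- global_coords(helical_series(arr), 1:2)
  cv <- covariance2(g)
  expect_equal(cv$c11, 2)
  expect_equal(cv$c22, 2, tolerance = 1e-9)
  expect_equal(cv$c12, 2, tolerance = 1e-9)
  # degenerate series
  arr[2, , ] <- arr[1, , ]
  expect_error(covariance2(global_coords(helical_series(arr), 1:2)),
               "degenerate|zero variance")
})

test_that("stiffness is kB T times the inverse covariance", {
  cv <- cov2(1, 0, 1)
  k <- stiffness_from_cov(cv, temperature = 300)
  expect_equal(k$k11, 0.59616, tolerance = 1e-10)
  expect_equal(k$k22, 0.59616, tolerance = 1e-10)
  expect_equal(k$k12, 0)
  set.seed(1)
  for (i in 1:20) {
    cv <- random_cov2()
    k <- stiffness_from_cov(cv, temperature = 300)
    prod <- as.matrix(k) %*% as.matrix(cv)
    expect_equal(prod, 0.0019872 * 300 * diag(2), tolerance = 1e-10,
                 ignore_attr = TRUE)
    k2 <- stiffness_from_cov(cv, temperature = 600)
    expect_equal(k2$k12, 2 * k$k12, tolerance = 1e-12)
  }
})

test_that("deformation energy matches the completed-square form", {
  k <- stiffness2(2, 0, 2)
  expect_equal(deformation_energy(k, c(0, 0)), 0)
  expect_equal(deformation_energy(k, c(1, 1)), 2)
  set.seed(2)
  for (i in 1:200) {
    cv <- random_cov2()
    k <- stiffness_from_cov(cv)
    dw <- stats::rnorm(2, sd = 3)
    e1 <- deformation_energy(k, dw)
    e4 <- 0.5 * ((k$k11 - k$k12^2 / k$k22) * dw[1]^2 +
                 k$k22 * (k$k12 / k$k22 * dw[1] + dw[2])^2)
    expect_equal(e1, e4, tolerance = 1e-10)
  }
})

test_that("constrained minimum agrees with brute-force minimization", {
  set.seed(3)
  for (i in 1:20) {
    k <- stiffness_from_cov(random_cov2())
    dom <- stats::rnorm(1, sd = 2)
    dl <- constrained_minimum(k, dom)
    e <- function(x) deformation_energy(k, c(dom, x))
    rough <- stats::optimize(e, interval = dom + c(-20, 20))$minimum
    # parabolic refinement: exact for a quadratic energy
    d <- 0.1
    brute <- rough - d / 2 * (e(rough + d) - e(rough - d)) /
      (e(rough + d) - 2 * e(rough) + e(rough - d))
    expect_equal(dl, brute, tolerance = 1e-8)
  }
  k0 <- stiffness2(1, 0, 5)
  expect_equal(constrained_minimum(k0, 3), 0)
})

test_that("the stiffness and covariance coupling routes coincide", {
  set.seed(4)
  for (i in 1:50) {
    cv <- random_cov2()
    k <- stiffness_from_cov(cv)
    expect_equal(constrained_minimum(k, 1), coupling_l_per_omega(cv),
                 tolerance = 1e-10)
  }
})

test_that("coupling coefficients follow the covariance elements", {
  cv <- cov2(5.566, 0.178, 0.055)
  expect_equal(coupling_l_per_omega(cv), 0.178 / 5.566, tolerance = 1e-12)
  expect_equal(coupling_l_per_omega(cv), 0.03198, tolerance = 1e-3)
  expect_equal(coupling_omega_per_l(cv), 0.178 / 0.055, tolerance = 1e-12)
  expect_equal(coupling_l_per_omega(cov2(1, 0, 1)), 0)
  set.seed(5)
  for (i in 1:50) {
    cv <- random_cov2()
    prod <- coupling_l_per_omega(cv) * coupling_omega_per_l(cv)
    expect_gte(prod, 0)
    expect_lt(prod, 1)
    expect_equal(sign(coupling_l_per_omega(cv)), sign(coupling_omega_per_l(cv)))
  }
})

test_that("bootstrap SEs are deterministic and shrink with sample size", {
  sp <- tiny_spec(n_snapshots = 8000, r_tr = 0.3)
  s <- sample_ensemble(sp)
  g <- global_coords(s, 1:6)
  b1 <- bootstrap_coupling(g, n_boot = 300, seed = 9)
  b2 <- bootstrap_coupling(g, n_boot = 300, seed = 9)
  expect_identical(b1$l_per_omega_se, b2$l_per_omega_se)
  g_small <- global_coords(
    helical_series(s$params[1:2000, , , drop = FALSE]), 1:6)
  b_small <- bootstrap_coupling(g_small, n_boot = 300, seed = 9)
  ratio <- b_small$l_per_omega_se / b1$l_per_omega_se
  expect_gt(ratio, 1.3)  # expect ~2 for a 4x size change, generous band
  expect_lt(ratio, 3.1)
  expect_error(bootstrap_coupling(g, n_boot = 50), "n_boot")
  tiny_g <- global_coords(helical_series(s$params[1:50, , , drop = FALSE]))
  expect_error(bootstrap_coupling(tiny_g, n_boot = 300), "at least 100")
})

test_that("bootstrap intervals cover a planted coupling", {
  sp <- plant_coupling(duplex_preset("dna"), 0.032)
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    s <- sample_ensemble(sp, n_snapshots = 1500, seed = 1000 + r)
    b <- bootstrap_coupling(global_coords(s), n_boot = 200, seed = r)
    if (abs(b$l_per_omega - 0.032) <= 3 * b$l_per_omega_se) hits <- hits + 1
  }
  expect_gte(hits, n_rep - 2)  # ±3 SE should cover essentially always
})

test_that("fluctuation estimates implement the per-step formulas", {
  fe <- fluctuation_estimates(P = 50, C_twist = 109, S = 1000, h = 0.34)
  expect_equal(fe$theta, 180 / pi * sqrt(2 * 0.34 / 50), tolerance = 1e-12)
  expect_equal(fe$theta, 6.68, tolerance = 1e-3)
  expect_equal(fe$tau, 0.720, tolerance = 1e-3)
  expect_gt(fe$z, 0)
  fe4 <- fluctuation_estimates(P = 200, C_twist = 109, S = 1000, h = 0.34)
  expect_equal(fe4$theta, fe$theta / 2, tolerance = 1e-12)
  expect_error(fluctuation_estimates(-1, 100, 400, 0.28), "positive")
})
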