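test_that("canonical B build places origins on the axis with the right extent", {
  m <- build_duplex(uniform_params(11, h_twist = 36, h_rise = 3.4))
  expect_equal(max(abs(m$origins[, 1:2])), 0, tolerance = 1e-12)
  expect_equal(unclass(duplex_extent(m)), 34.0, ignore_attr = TRUE)
  expect_equal(attr(duplex_extent(m), "end_to_end"), 34.0)
  # 360 degree closure: frame 11 x-axis parallel to frame 1 x-axis
  expect_equal(m$orientations[, 1, 11], m$orientations[, 1, 1],
               tolerance = 1e-10)
  expect_equal(helix_radius(m), 0, tolerance = 1e-12)
})

test_that("A-form-like build sits at the x-displacement radius", {
  p <- uniform_params(12, x_disp = -4.4, incl = 17.5, h_twist = 32.7,
                      h_rise = 2.6)
  m <- build_duplex(p)
  r <- sqrt(m$origins[, 1]^2 + m$origins[, 2]^2)
  expect_equal(r, rep(4.4, 12), tolerance = 1e-10)
  expect_equal(helix_radius(m), 4.4, tolerance = 1e-10)
  expect_equal(unclass(duplex_extent(m)), 11 * 2.6, ignore_attr = TRUE)
  # origin z equals the cumulative rise exactly
  expect_equal(m$origins[, 3], seq(0, by = 2.6, length.out = 12),
               tolerance = 1e-12)
  # radius shrinks monotonically with |x_disp|
  radii <- sapply(c(4.4, 3.0, 1.5, 0.2), function(xd)
    helix_radius(build_duplex(uniform_params(8, x_disp = -xd,
                                             h_twist = 33, h_rise = 2.8))))
  expect_true(all(diff(radii) < 0))
})

test_that("extract inverts build on random valid parameter sets", {
  for (r in 1:25) {
    p <- random_params(8, seed = 100 + r)
    m <- build_duplex(p)
    expect_params_equal(extract_params(m), p, tol = 1e-8)
  }
})

test_that("identity frames stacked along z extract as pure rise", {
  m <- build_duplex(uniform_params(5, h_twist = 0, h_rise = 3.4))
  p <- extract_params(m)
  expect_equal(p$h_twist, rep(0, 5), tolerance = 1e-12)
  expect_equal(p$h_rise, c(0, rep(3.4, 4)), tolerance = 1e-12)
  expect_equal(unlist(p[c("x_disp", "y_disp", "incl", "tip")]),
               rep(0, 20), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("measurements are invariant under rigid z-rotation and translation", {
  p <- random_params(14, seed = 77)
  m <- build_duplex(p)
  Rz <- twistretch:::rot_z(25)
  m2 <- m
  m2$origins <- t(Rz %*% t(m$origins) + c(0, 0, 7.5))
  for (i in 1:14) m2$orientations[, , i] <- Rz %*% m$orientations[, , i]
  expect_params_equal(extract_params(m2), p, tol = 1e-8)
  expect_equal(duplex_extent(m2), duplex_extent(m), tolerance = 1e-10)
  expect_equal(helix_radius(m2), helix_radius(m), tolerance = 1e-10)
  pb <- build_duplex(uniform_params(20, h_twist = 34, h_rise = 3.2,
                                    x_disp = -2))
  pb2 <- pb
  pb2$origins <- t(Rz %*% t(pb$origins) + c(0, 0, -3))
  for (i in 1:20) pb2$orientations[, , i] <- Rz %*% pb$orientations[, , i]
  expect_equal(groove_widths(pb2)$minor, groove_widths(pb)$minor,
               tolerance = 1e-9)
})

test_that("builder rejects degenerate and invalid inputs", {
  expect_error(build_duplex(uniform_params(5, incl = 95)), "90 deg")
  expect_error(build_duplex(uniform_params(5, tip = -90)), "90 deg")
  expect_error(build_duplex(uniform_params(1)), "at least 2")
  p <- uniform_params(5); p$h_rise[3] <- -1
  expect_error(build_duplex(p), "positive")
})

test_that("groove widths: B-form minor < major, correction subtracts exactly", {
  m <- build_duplex(uniform_params(20, h_twist = 36, h_rise = 3.4))
  gw <- groove_widths(m)
  expect_true(all(gw$minor < gw$major))
  expect_true(all(gw$minor >= 0))
  # canonical B-DNA groove widths by the phosphate-distance convention
  expect_equal(mean(gw$minor), 5.8, tolerance = 0.05)
  expect_equal(mean(gw$major), 11.8, tolerance = 0.05)
  m0 <- build_duplex(uniform_params(20, h_twist = 36, h_rise = 3.4),
                     backbone = backbone_geometry(
                       phosphate_radius_correction = 0))
  gw0 <- groove_widths(m0)
  expect_equal(gw0$minor - gw$minor, rep(5.8, nrow(gw)), tolerance = 1e-10)
  expect_error(groove_widths(build_duplex(uniform_params(6))),
               "need >= ")
})

test_that("overtwisting an A-form helix closes the major groove", {
  gw_at <- function(tw) {
    m <- build_duplex(uniform_params(26, x_disp = -4.4, incl = 17.5,
                                     h_twist = tw, h_rise = 2.6))
    mean(groove_widths(m)$major)
  }
  widths <- sapply(c(30, 31.5, 33, 34.5), gw_at)
  expect_true(all(diff(widths) < 0))
})

test_that("stack_to_rise matches the two-frame builder oracle", {
  expect_equal(stack_to_rise(3.4, inclination = 0, x_disp = 0, twist = 36),
               3.4, tolerance = 1e-9)
  expect_equal(stack_to_rise(2.9, inclination = 0, x_disp = 0, twist = 10),
               2.9, tolerance = 1e-9)
  # independent check against the two-frame builder: project the
  # inter-origin vector of a fresh build at the returned rise onto the
  # mean base normal and recover the stacking distance
  builder_proj <- function(h, incl, xd, tw) {
    m <- build_duplex(uniform_params(2, x_disp = xd, h_rise = h,
                                     incl = incl, h_twist = tw))
    nrm <- m$orientations[, 3, 1] + m$orientations[, 3, 2]
    nrm <- nrm / sqrt(sum(nrm^2))
    abs(sum((m$origins[2, ] - m$origins[1, ]) * nrm))
  }
  h <- stack_to_rise(3.4, inclination = 17.5, x_disp = -4.4, twist = 32.7)
  expect_equal(builder_proj(h, 17.5, -4.4, 32.7), 3.4, tolerance = 1e-9)
  # coarse-to-fine brute-force scan lands on the same root
  hs <- seq(0.05, 6, by = 0.01)
  h0 <- hs[which.min(abs(sapply(hs, builder_proj, 17.5, -4.4, 32.7) - 3.4))]
  hs <- seq(h0 - 0.01, h0 + 0.01, by = 1e-4)
  h1 <- hs[which.min(abs(sapply(hs, builder_proj, 17.5, -4.4, 32.7) - 3.4))]
  expect_equal(h, h1, tolerance = 1e-4)
  # at fixed stacking with inclined pairs, a growing in-plane chord eats
  # into the achievable rise
  rises <- sapply(c(0, 2, 4, 5), function(xd)
    stack_to_rise(3.4, inclination = 20, x_disp = -xd, twist = 33))
  expect_true(all(diff(rises) < 0) || all(diff(rises) > 0))
  expect_gt(max(abs(diff(rises))), 0.01)
  expect_error(stack_to_rise(0.5, inclination = 60, x_disp = -5,
                             twist = 60), "minimum feasible")
})
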