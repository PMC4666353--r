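# Shared fixture builders. Everything is generated in code; seeds are
# fixed so the suite is deterministic.

# A small uncorrelated spec for fast structural tests.
tiny_spec <- function(n_bp = 6, n_snapshots = 500, seed = 42,
                      rho = 0, r_tr = 0) {
  R <- diag(6)
  dimnames(R) <- list(twistretch:::.param_names,
                      twistretch:::.param_names)
  R["h_twist", "h_rise"] <- R["h_rise", "h_twist"] <- r_tr
  ensemble_spec(n_bp = n_bp, n_snapshots = n_snapshots,
                means = c(x_disp = -0.7, y_disp = 0, h_rise = 3.3,
                          incl = 2, tip = 0, h_twist = 32),
                sds = c(x_disp = 0.5, y_disp = 0.4, h_rise = 0.11,
                        incl = 3, tip = 3, h_twist = 1.1),
                intra_step_correlation = R,
                neighbor_twist_correlation = rho,
                seed = seed, label = "tiny")
}

# Random valid helical parameter table whose first row has zero step
# twist/rise (the anchor base pair carries no preceding step).
random_params <- function(n_bp, seed = NULL) {
  draw <- function() data.frame(
    x_disp = stats::runif(n_bp, -5, 2),
    y_disp = stats::runif(n_bp, -2, 2),
    h_rise = c(0, stats::runif(n_bp - 1, 2.0, 4.0)),
    incl = stats::runif(n_bp, -60, 60),
    tip = stats::runif(n_bp, -60, 60),
    h_twist = c(0, stats::runif(n_bp - 1, -170, 170)))
  if (is.null(seed)) draw() else twistretch:::with_seed(seed, draw())
}

# Random SPD 2x2 covariance as a cov2.
random_cov2 <- function() {
  A <- matrix(stats::rnorm(4), 2, 2)
  S <- crossprod(A) + diag(0.1, 2)
  cov2(S[1, 1], S[1, 2], S[2, 2])
}

expect_params_equal <- function(a, b, tol = 1e-8) {
  for (col in twistretch:::.param_names)
    expect_equal(a[[col]], b[[col]], tolerance = tol,
                 ignore_attr = TRUE, label = col)
}
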