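# The user-facing model fit: series -> global coordinates -> covariance ->
# stiffness -> coupling coefficients, with optional bootstrap uncertainty.

#' Fit the harmonic twist-stretch model to a helical series
#'
#' Condenses a helical-coordinate series to the two global coordinates
#' (total twist `omega`, length `l` over `window`), estimates their
#' covariance `C`, converts it to the stiffness matrix `K = kB T C^-1`, and
#' reports both twist-stretch coupling coefficients: `c12/c11` (Angstrom of
#' length change per degree of constrained twist change) and `c12/c22`
#' (degrees of twist change per Angstrom of constrained elongation).
#'
#' @param series A [helical_series()], e.g. from [sample_ensemble()] or
#'   [read_series()].
#' @param window Contiguous step window; default the central 10 steps.
#' @param temperature Temperature in K used in `K = kB T C^-1`.
#' @param n_boot Bootstrap replicates for coupling SEs; 0 disables.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `twist_stretch_fit` with components
#'   `coords` ([global_coords()]), `covariance` ([cov2()]), `stiffness`
#'   ([stiffness2()]), `coupling` (list or [bootstrap_coupling()] result),
#'   and `call`.
#' @examples
#' s <- sample_ensemble(duplex_preset("dna", seed = 1), n_snapshots = 2000)
#' fit <- twist_stretch_fit(s)
#' coef(fit)
#' @seealso [coupling_l_per_omega()], [torque_scan()], [bin_xy()]
#' @export
twist_stretch_fit <- function(series, window = NULL, temperature = 300,
                              n_boot = 0, seed = NULL) {
  g <- global_coords(series, window)
  cv <- covariance2(g)
  k <- stiffness_from_cov(cv, temperature)
  coupling <- if (n_boot > 0) {
    bootstrap_coupling(g, n_boot = n_boot, seed = seed)
  } else {
    structure(list(l_per_omega = coupling_l_per_omega(cv),
                   omega_per_l = coupling_omega_per_l(cv),
                   l_per_omega_se = NA_real_, omega_per_l_se = NA_real_,
                   n_snapshots = length(g$omega), n_boot = 0L),
              class = "coupling_result")
  }
  structure(list(coords = g, covariance = cv, stiffness = k,
                 coupling = coupling, temperature = temperature,
                 label = series$label, call = match.call()),
            class = "twist_stretch_fit")
}

#' @export
print.twist_stretch_fit <- function(x, ...) {
  cat("Harmonic twist-stretch model fit",
      if (nzchar(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat(sprintf("  window: steps %d..%d, %d snapshots, T = %g K\n",
              min(x$coords$window), max(x$coords$window),
              length(x$coords$omega), x$temperature))
  cat(sprintf("  mean twist %.2f deg/step, mean rise %.3f A/step\n",
              x$coords$omega0 / length(x$coords$window),
              x$coords$l0 / length(x$coords$window)))
  se <- x$coupling$l_per_omega_se
  cat(sprintf("  coupling l/omega: %+.4f%s A/deg\n", x$coupling$l_per_omega,
              if (is.na(se)) "" else sprintf(" +/- %.4f", se)))
  se2 <- x$coupling$omega_per_l_se
  cat(sprintf("  coupling omega/l: %+.3f%s deg/A\n", x$coupling$omega_per_l,
              if (is.na(se2)) "" else sprintf(" +/- %.3f", se2)))
  invisible(x)
}

#' @export
coef.twist_stretch_fit <- function(object, ...) {
  c(l_per_omega = object$coupling$l_per_omega,
    omega_per_l = object$coupling$omega_per_l)
}

#' @export
vcov.twist_stretch_fit <- function(object, ...) as.matrix(object$covariance)

#' @export
summary.twist_stretch_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.twist_stretch_fit")
}

#' @export
print.summary.twist_stretch_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$fit$covariance)
  cat("\n")
  print(x$fit$stiffness)
  invisible(x)
}

#' Predict relaxed elongation for imposed twist changes
#'
#' For each imposed total-twist deviation (deg) returns the
#' energy-minimizing length deviation (Angstrom), `c12/c11 * delta_omega`.
#'
#' @param object A `twist_stretch_fit`.
#' @param delta_omega Numeric vector of twist deviations (deg).
#' @param ... Unused.
#' @export
predict.twist_stretch_fit <- function(object, delta_omega = 0, ...) {
  coupling_l_per_omega(object$covariance) * delta_omega
}

#' @export
residuals.twist_stretch_fit <- function(object, ...) {
  g <- object$coords
  (g$l - g$l0) - coupling_l_per_omega(object$covariance) * (g$omega - g$omega0)
}

#' Simulate global coordinates from a fitted model
#'
#' Draws `(omega, l)` pairs from the bivariate Gaussian with the fitted
#' means and covariance.
#'
#' @param object A `twist_stretch_fit`.
#' @param nsim Number of draws.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with columns `omega`, `l`.
#' @export
simulate.twist_stretch_fit <- function(object, nsim = 1, seed = NULL, ...) {
  L <- chol(as.matrix(object$covariance))
  Z <- with_seed(seed, matrix(stats::rnorm(2 * nsim), nsim, 2))
  X <- Z %*% L
  data.frame(omega = object$coords$omega0 + X[, 1],
             l = object$coords$l0 + X[, 2])
}

#' Plot a fitted twist-stretch model
#'
#' Binned mean rise per step against mean twist per step (SEM error bars)
#' with the fitted coupling line through the grand mean, the standard
#' visual of the twist-stretch correlation.
#'
#' @param x A `twist_stretch_fit`.
#' @param bin_width Twist bin width in degrees (default 0.2).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.twist_stretch_fit <- function(x, bin_width = 0.2, ...) {
  m <- length(x$coords$window)
  tw <- x$coords$omega / m
  ri <- x$coords$l / m
  b <- bin_xy(tw, ri, bin_width = bin_width,
              x_name = "mean twist (deg)", y_name = "mean rise (A)")
  graphics::plot(b$x_mean, b$mean, pch = 16,
                 xlab = "mean helical twist per step (deg)",
                 ylab = "mean helical rise per step (A)", ...)
  graphics::arrows(b$x_mean, b$mean - b$sem, b$x_mean, b$mean + b$sem,
                   angle = 90, code = 3, length = 0.02)
  slope <- coupling_l_per_omega(x$covariance)  # A/deg, same per-step scale
  graphics::abline(a = mean(ri) - slope * mean(tw), b = slope, col = 2)
  graphics::abline(v = mean(tw), lty = 3)
  invisible(x)
}
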