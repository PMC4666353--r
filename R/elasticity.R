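# The harmonic stiffness model in global coordinates: total twist omega
# (deg) and duplex length l (A, the sum of helical rises) over an analysis
# window. Deformation energy E = 1/2 dw' K dw with K = kB T C^-1, C the
# coordinate covariance. The off-diagonal elements carry the twist-stretch
# coupling: l change per constrained twist change is c12/c11 (equivalently
# -k12/k22), twist change per constrained elongation is c12/c22.

#' 2x2 covariance of total twist and length
#'
#' Container for the covariance matrix of the global coordinates
#' `(omega, l)`: `c11` in deg^2, `c12` in deg*Angstrom, `c22` in
#' Angstrom^2. Positive variances are required and the determinant may
#' not be negative (a singular boundary case -- perfectly correlated
#' coordinates -- is representable, but cannot be inverted into a
#' stiffness).
#'
#' @param c11,c12,c22 Matrix elements.
#' @return An object of class `cov2`.
#' @export
cov2 <- function(c11, c12, c22) {
  ok <- c11 > 0 && c22 > 0 && c12^2 <= c11 * c22 * (1 + 1e-12)
  if (!ok)
    stop(sprintf("invalid covariance (c11=%.4g, c12=%.4g, c22=%.4g)",
                 c11, c12, c22), call. = FALSE)
  structure(list(c11 = c11, c12 = c12, c22 = c22), class = "cov2")
}

#' @export
as.matrix.cov2 <- function(x, ...) {
  matrix(c(x$c11, x$c12, x$c12, x$c22), 2, 2,
         dimnames = list(c("omega", "l"), c("omega", "l")))
}

#' @export
print.cov2 <- function(x, ...) {
  cat("Covariance of (total twist [deg], length [A]):\n")
  print(as.matrix(x))
  invisible(x)
}

#' 2x2 stiffness matrix of total twist and length
#'
#' Stiffness (inverse-covariance times kB T) of the global coordinates:
#' `k11` in kcal/mol/deg^2, `k12` in kcal/mol/deg/Angstrom, `k22` in
#' kcal/mol/Angstrom^2. Positive definiteness (`k22 > 0` and
#' `k11 - k12^2/k22 > 0`) is enforced.
#'
#' @param k11,k12,k22 Matrix elements.
#' @param temperature Temperature in K at which the stiffness is defined.
#' @return An object of class `stiffness2`.
#' @export
stiffness2 <- function(k11, k12, k22, temperature = 300) {
  if (!(k22 > 0 && k11 - k12^2 / k22 > 0))
    stop("stiffness matrix not positive definite", call. = FALSE)
  structure(list(k11 = k11, k12 = k12, k22 = k22,
                 temperature = temperature), class = "stiffness2")
}

#' @export
as.matrix.stiffness2 <- function(x, ...) {
  matrix(c(x$k11, x$k12, x$k12, x$k22), 2, 2,
         dimnames = list(c("omega", "l"), c("omega", "l")))
}

#' @export
print.stiffness2 <- function(x, ...) {
  cat(sprintf("Stiffness of (total twist, length) at %g K [kcal/mol units]:\n",
              x$temperature))
  print(as.matrix(x))
  invisible(x)
}

#' Global coordinates of a helical series
#'
#' Per-snapshot total twist `omega = sum of step twists` (deg) and duplex
#' length `l = sum of helical rises` (Angstrom) over a contiguous window of
#' steps, with their means `omega0`, `l0`. The default window is the
#' central 10 steps, excluding the frayed termini from analysis.
#'
#' @param series A `helical_series`.
#' @param window Contiguous 1-based step indices (default [inner_window()]
#'   of the series).
#' @return An object of class `global_coords`: list with per-snapshot
#'   `omega`, `l`, scalars `omega0`, `l0`, and the `window` used.
#' @export
global_coords <- function(series, window = NULL) {
  stopifnot(inherits(series, "helical_series"))
  n_bp <- dim(series$params)[2]
  if (is.null(window)) window <- inner_window(n_bp, min(10, n_bp))
  window <- check_window(window, n_bp)
  tw <- series$params[, window, "h_twist", drop = FALSE]
  ri <- series$params[, window, "h_rise", drop = FALSE]
  omega <- rowSums(tw, dims = 1)
  l <- rowSums(ri, dims = 1)
  structure(list(omega = omega, l = l, omega0 = mean(omega), l0 = mean(l),
                 window = window), class = "global_coords")
}

#' Sample covariance of the global coordinates
#'
#' Unbiased (n-1) sample covariance of the per-snapshot `(omega, l)` pairs.
#'
#' @param g A [global_coords()] object.
#' @return A [cov2()].
#' @export
covariance2 <- function(g) {
  stopifnot(inherits(g, "global_coords"))
  if (length(g$omega) < 2) stop("need at least 2 snapshots", call. = FALSE)
  c11 <- stats::var(g$omega)
  c22 <- stats::var(g$l)
  c12 <- stats::cov(g$omega, g$l)
  if (c11 <= 0 || c22 <= 0)
    stop("degenerate series: a coordinate has zero variance", call. = FALSE)
  cov2(c11, c12, c22)
}

#' Stiffness from covariance
#'
#' The fluctuation relation `K = kB T C^-1` linking the coordinate
#' covariance of the canonical ensemble to the harmonic stiffness matrix,
#' with kB = 0.0019872 kcal/mol/K. Degrees and Angstrom are retained, so
#' the coupling coefficients come out in the conventional A/deg and deg/A.
#'
#' @param c A [cov2()].
#' @param temperature Temperature in K (default 300).
#' @return A [stiffness2()].
#' @export
stiffness_from_cov <- function(c, temperature = 300) {
  stopifnot(inherits(c, "cov2"), temperature > 0)
  Kc <- .kB_kcal * temperature * solve(as.matrix(c))
  stiffness2(Kc[1, 1], Kc[1, 2], Kc[2, 2], temperature = temperature)
}

#' Harmonic deformation energy
#'
#' `E = 1/2 dw' K dw` for a deviation `dw = (d_omega, d_l)` from the
#' equilibrium coordinates, in kcal/mol. Algebraically identical to the
#' completed-square form
#' `2E = (k11 - k12^2/k22) d_omega^2 + k22 (k12/k22 d_omega + d_l)^2`,
#' which makes the constrained minimum explicit.
#'
#' @param k A [stiffness2()].
#' @param dw Length-2 numeric `(d_omega [deg], d_l [A])`.
#' @return Energy in kcal/mol.
#' @export
deformation_energy <- function(k, dw) {
  stopifnot(inherits(k, "stiffness2"), length(dw) == 2)
  dw <- as.numeric(dw)
  0.5 * (k$k11 * dw[1]^2 + 2 * k$k12 * dw[1] * dw[2] + k$k22 * dw[2]^2)
}

#' Energy-minimizing elongation at fixed twist
#'
#' With total twist constrained to deviate by `delta_omega` and length
#' free, the energy is minimal when the second square of the
#' completed-square energy vanishes: `d_l = -(k12/k22) delta_omega`. This
#' is the stiffness-matrix expression of the twist-stretch coupling.
#'
#' @param k A [stiffness2()].
#' @param delta_omega Imposed twist deviation (deg), vectorized.
#' @return The relaxed length deviation(s) in Angstrom.
#' @export
constrained_minimum <- function(k, delta_omega) {
  stopifnot(inherits(k, "stiffness2"))
  -(k$k12 / k$k22) * delta_omega
}

#' Twist-stretch coupling coefficients from the covariance
#'
#' `coupling_l_per_omega` is the length change per constrained unit change
#' of total twist, `c12 / c11` (Angstrom/deg); positive means overtwisting
#' lengthens (DNA-like), negative means overtwisting shortens (RNA-like).
#' `coupling_omega_per_l` is the complementary twist change per constrained
#' elongation, `c12 / c22` (deg/Angstrom). Their product is the squared
#' correlation `c12^2 / (c11 c22)`, always in `[0, 1)`.
#'
#' @param c A [cov2()].
#' @return A single number.
#' @export
coupling_l_per_omega <- function(c) {
  stopifnot(inherits(c, "cov2"))
  c$c12 / c$c11
}

#' @rdname coupling_l_per_omega
#' @export
coupling_omega_per_l <- function(c) {
  stopifnot(inherits(c, "cov2"))
  c$c12 / c$c22
}

#' Bootstrap uncertainty of the coupling coefficients
#'
#' Plain snapshot-resampling bootstrap of both coupling coefficients.
#' Snapshots are exchangeable in this package's ensembles, so resampling
#' whole snapshots is the appropriate scheme.
#'
#' @param g A [global_coords()] object with at least 100 snapshots.
#' @param n_boot Number of bootstrap replicates (>= 100, default 1000).
#' @param seed Integer seed for the resampling (deterministic results).
#' @return Object of class `coupling_result`: point estimates
#'   `l_per_omega`, `omega_per_l`, bootstrap SEs `l_per_omega_se`,
#'   `omega_per_l_se`, and `n_snapshots`.
#' @export
bootstrap_coupling <- function(g, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(g, "global_coords"))
  n <- length(g$omega)
  if (n < 100) stop("need at least 100 snapshots to bootstrap", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  cv <- covariance2(g)
  reps <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    vapply(seq_len(n_boot), function(b) {
      o <- g$omega[idx[, b]]; l <- g$l[idx[, b]]
      c11 <- stats::var(o); c22 <- stats::var(l); c12 <- stats::cov(o, l)
      c(c12 / c11, c12 / c22)
    }, numeric(2))
  })
  structure(list(l_per_omega = coupling_l_per_omega(cv),
                 omega_per_l = coupling_omega_per_l(cv),
                 l_per_omega_se = stats::sd(reps[1, ]),
                 omega_per_l_se = stats::sd(reps[2, ]),
                 n_snapshots = n, n_boot = n_boot),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("Twist-stretch coupling (n = %d snapshots, %d bootstrap reps)\n",
              x$n_snapshots, x$n_boot))
  cat(sprintf("  l per omega: %+.4f +/- %.4f A/deg\n",
              x$l_per_omega, x$l_per_omega_se))
  cat(sprintf("  omega per l: %+.3f +/- %.3f deg/A\n",
              x$omega_per_l, x$omega_per_l_se))
  invisible(x)
}

#' Analytic per-step fluctuation estimates from elastic moduli
#'
#' Worm-like-chain-level estimates of thermal fluctuations per base-pair
#' step from the macroscopic elastic moduli: bend
#' `theta = sqrt(2 h / P)`, twist `tau = sqrt(h / (2 pi^2 C))` (both in
#' radians, reported in degrees), and rise `z = sqrt(kB T h / S)` with
#' kB T in pN nm. `P` and `C` are the bending and twisting persistence
#' lengths, `S` the stretch modulus, `h` the helical rise.
#'
#' @param P Bending persistence length (nm), e.g. ~50 for DNA, ~60 for RNA.
#' @param C_twist Twist persistence length (nm), ~109 (DNA), ~100 (RNA).
#' @param S Stretch modulus (pN), ~1000 (DNA), ~400 (RNA).
#' @param h Helical rise per step (nm), ~0.34 (DNA), ~0.28 (RNA).
#' @param temperature Temperature (K), default 300.
#' @return List `theta` (deg), `tau` (deg), `z` (Angstrom), plus the
#'   inputs, class `fluctuation_estimate`.
#' @examples
#' fluctuation_estimates(P = 50, C_twist = 109, S = 1000, h = 0.34)
#' @export
fluctuation_estimates <- function(P, C_twist, S, h, temperature = 300) {
  vals <- c(P = P, C_twist = C_twist, S = S, h = h, temperature = temperature)
  if (any(vals <= 0))
    stop("all inputs must be positive; offending: ",
         paste(names(vals)[vals <= 0], collapse = ", "), call. = FALSE)
  theta <- rad2deg(sqrt(2 * h / P))
  tau <- rad2deg(sqrt(h / (2 * pi^2 * C_twist)))
  z_nm <- sqrt(.kB_pN_nm * temperature * h / S)
  structure(list(theta = theta, tau = tau, z = 10 * z_nm,
                 P = P, C_twist = C_twist, S = S, h = h,
                 temperature = temperature),
            class = "fluctuation_estimate")
}

#' @export
print.fluctuation_estimate <- function(x, ...) {
  cat(sprintf(paste0("Per-step thermal fluctuation estimates ",
                     "(P = %g nm, C = %g nm, S = %g pN, h = %g nm, T = %g K):\n"),
              x$P, x$C_twist, x$S, x$h, x$temperature))
  cat(sprintf("  bend  theta = %.3f deg\n", x$theta))
  cat(sprintf("  twist tau   = %.3f deg\n", x$tau))
  cat(sprintf("  rise  z     = %.3f A\n", x$z))
  invisible(x)
}
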