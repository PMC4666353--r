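# Specification of a Gaussian helical-coordinate ensemble: per-step means
# and SDs of the six base-pair axis parameters, an intra-step correlation
# matrix, and a nearest-neighbour twist (optionally rise) correlation.

#' Specify a Gaussian helical-coordinate ensemble
#'
#' An `ensemble_spec` fully determines a multivariate Gaussian over the six
#' base-pair axis parameters (x-displacement, y-displacement, helical rise,
#' inclination, tip, helical twist) of every base pair of a duplex. Within a
#' step the six parameters share the correlation matrix
#' `intra_step_correlation`; across steps only helical twist (and, if
#' `neighbor_rise_correlation` is nonzero, helical rise) of nearest
#' neighbours is correlated. This is the statistical structure that
#' microsecond-scale duplex simulations display to a first approximation:
#' near-harmonic (Gaussian) fluctuations with short-ranged inter-step
#' coupling that falls off beyond nearest neighbours.
#'
#' Units are degrees for the angular parameters (inclination, tip, twist)
#' and Angstrom for the translational ones (x-disp, y-disp, rise).
#'
#' @param n_bp Number of base pairs.
#' @param n_snapshots Default number of snapshots drawn by
#'   [sample_ensemble()].
#' @param means,sds Named numeric vectors over
#'   `c("x_disp","y_disp","h_rise","incl","tip","h_twist")`; all SDs must be
#'   positive and the mean rise positive.
#' @param intra_step_correlation Symmetric positive-definite 6x6 correlation
#'   matrix with unit diagonal, rows/columns in the order above.
#' @param neighbor_twist_correlation Correlation between helical twist at
#'   adjacent steps, in (-1, 1). Duplex twist fluctuations are
#'   anti-correlated between neighbouring steps, so realistic values are
#'   negative (presets use -0.3).
#' @param neighbor_rise_correlation Optional analogous nearest-neighbour
#'   correlation for helical rise (default 0).
#' @param seed Integer seed consumed by [sample_ensemble()]; `NULL` uses the
#'   session RNG stream.
#' @param label Free-text label carried through series files and results.
#' @return An object of class `ensemble_spec`.
#' @seealso [duplex_preset()], [plant_coupling()],
#'   [analytic_segment_covariance()], [sample_ensemble()]
#' @export
ensemble_spec <- function(n_bp, n_snapshots, means, sds,
                          intra_step_correlation,
                          neighbor_twist_correlation = -0.3,
                          neighbor_rise_correlation = 0,
                          seed = NULL, label = "custom") {
  stopifnot(n_bp >= 2, n_snapshots >= 1)
  means <- means[.param_names]
  sds <- sds[.param_names]
  if (anyNA(means) || anyNA(sds))
    stop("`means` and `sds` must be named over: ",
         paste(.param_names, collapse = ", "), call. = FALSE)
  if (any(sds <= 0)) stop("all SDs must be > 0", call. = FALSE)
  if (means[["h_rise"]] <= 0) stop("mean rise must be > 0", call. = FALSE)
  R <- as.matrix(intra_step_correlation)
  dimnames(R) <- list(.param_names, .param_names)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-12)))
    stop("intra_step_correlation must be symmetric", call. = FALSE)
  if (!isTRUE(all.equal(unname(diag(R)), rep(1, 6), tolerance = 1e-12)))
    stop("intra_step_correlation must have unit diagonal", call. = FALSE)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("intra_step_correlation must be positive definite", call. = FALSE)
  for (rho in c(neighbor_twist_correlation, neighbor_rise_correlation))
    if (abs(rho) >= 1)
      stop("neighbor correlations must lie in (-1, 1)", call. = FALSE)
  spec <- structure(
    list(label = label, n_bp = as.integer(n_bp),
         n_snapshots = as.integer(n_snapshots),
         means = means, sds = sds, intra_step_correlation = R,
         neighbor_twist_correlation = neighbor_twist_correlation,
         neighbor_rise_correlation = neighbor_rise_correlation,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "ensemble_spec")
  # The assembled joint covariance must itself be positive definite; the
  # per-block checks above do not guarantee it for strong neighbor terms.
  tryCatch(chol(assemble_covariance(spec)),
           error = function(e) stop("assembled ", 6 * n_bp, "-dimensional ",
                                    "covariance is not positive definite ",
                                    "(neighbor terms too strong for the ",
                                    "intra-step block)", call. = FALSE))
  spec
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("Helical-coordinate ensemble spec:", x$label, "\n")
  cat(sprintf("  %d bp, %d snapshots (default), seed %s\n", x$n_bp,
              x$n_snapshots, if (is.null(x$seed)) "<session>" else x$seed))
  m <- rbind(mean = x$means, sd = x$sds)
  print(round(m, 3))
  cat(sprintf("  neighbor twist correlation: %.3g, rise: %.3g\n",
              x$neighbor_twist_correlation, x$neighbor_rise_correlation))
  invisible(x)
}

#' DNA-like and RNA-like ensemble presets
#'
#' Ready-made [ensemble_spec()]s encoding the fluctuation statistics of
#' B-form DNA and A-form RNA 16-mers: mean twist 32.0 deg (DNA) / 31.5 deg
#' (RNA), twist SD 1.1 / 0.9 deg, rise SD 0.11 / 0.15 Angstrom, and coupling
#' signs that reproduce the opposite twist-stretch behaviour of the two
#' duplexes -- DNA twist fluctuations correlate positively with rise
#' (overtwisting lengthens), RNA negatively (overtwisting shortens). The
#' RNA preset places base pairs at x-disp -4.4 Angstrom with inclination
#' 17.5 deg, the displaced, inclined geometry characteristic of the A-form
#' helix. Intra-step correlation magnitudes default to |r| = 0.3; they set
#' the coupling signs, and [plant_coupling()] can pin the coupling
#' coefficient to an exact value.
#'
#' @param name `"dna"` or `"rna"`.
#' @param n_snapshots Number of snapshots the spec asks for (default 1e5).
#' @param seed Optional integer seed stored in the spec.
#' @return An `ensemble_spec`.
#' @examples
#' duplex_preset("dna")
#' @export
duplex_preset <- function(name = c("dna", "rna"), n_snapshots = 100000,
                          seed = NULL) {
  if (!is.character(name) || length(name) != 1 ||
      !(name %in% c("dna", "rna")))
    stop("unknown preset ", deparse(substitute(name)),
         "; valid presets: \"dna\", \"rna\"", call. = FALSE)
  R <- diag(6)
  dimnames(R) <- list(.param_names, .param_names)
  r <- 0.3
  if (name == "dna") {
    means <- c(x_disp = -0.7, y_disp = 0, h_rise = 3.3, incl = 2.0,
               tip = 0, h_twist = 32.0)
    sds <- c(x_disp = 0.5, y_disp = 0.4, h_rise = 0.11, incl = 3.0,
             tip = 3.0, h_twist = 1.1)
    R["h_twist", "h_rise"] <- R["h_rise", "h_twist"] <- +r
    R["h_twist", "incl"] <- R["incl", "h_twist"] <- -r
    R["h_twist", "x_disp"] <- R["x_disp", "h_twist"] <- +r
  } else {
    means <- c(x_disp = -4.4, y_disp = 0, h_rise = 2.67, incl = 17.5,
               tip = 0, h_twist = 31.5)
    sds <- c(x_disp = 0.5, y_disp = 0.4, h_rise = 0.15, incl = 3.0,
             tip = 3.0, h_twist = 0.9)
    R["h_twist", "h_rise"] <- R["h_rise", "h_twist"] <- -r
    R["h_twist", "incl"] <- R["incl", "h_twist"] <- +r
    R["h_twist", "x_disp"] <- R["x_disp", "h_twist"] <- +r
  }
  ensemble_spec(n_bp = 16, n_snapshots = n_snapshots, means = means,
                sds = sds, intra_step_correlation = R,
                neighbor_twist_correlation = -0.3, seed = seed,
                label = name)
}

# Joint covariance of the 6*n_bp coordinate vector, bp-major ordering
# (bp 1 parameters 1..6, then bp 2, ...). Intra-step blocks D R D plus
# tridiagonal nearest-neighbour terms for twist (and optionally rise).
assemble_covariance <- function(spec) {
  n <- spec$n_bp
  d <- 6L * n
  D <- diag(spec$sds)
  block <- D %*% spec$intra_step_correlation %*% D
  S <- matrix(0, d, d)
  for (i in seq_len(n)) {
    idx <- (i - 1L) * 6L + 1:6
    S[idx, idx] <- block
  }
  itw <- which(.param_names == "h_twist")
  iri <- which(.param_names == "h_rise")
  stw <- spec$sds[["h_twist"]]
  sri <- spec$sds[["h_rise"]]
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * 6L + itw
    b <- i * 6L + itw
    S[a, b] <- S[b, a] <- spec$neighbor_twist_correlation * stw^2
    if (spec$neighbor_rise_correlation != 0) {
      a <- (i - 1L) * 6L + iri
      b <- i * 6L + iri
      S[a, b] <- S[b, a] <- spec$neighbor_rise_correlation * sri^2
    }
  }
  S
}

#' Closed-form covariance of total twist and length over a window
#'
#' Exact covariance of the global coordinates (total twist `omega = sum of
#' step twists`, length `l = sum of rises`) over a contiguous window of `m`
#' steps, implied by an [ensemble_spec()]. With per-step twist variance
#' `s^2` and neighbour correlation `rho`,
#' `Var(omega) = m s^2 + 2 rho s^2 (m - 1)` (tridiagonal sum), and
#' analogously for rise; the cross term is `m` times the intra-step
#' twist-rise covariance (there is no cross-step twist-rise coupling in the
#' model). Serves as the analytic oracle for the sampled estimators.
#'
#' @param spec An `ensemble_spec`.
#' @param window Contiguous 1-based step indices; default the central 10.
#' @return A [cov2()] object (fields `c11` deg^2, `c12` deg*Angstrom,
#'   `c22` Angstrom^2).
#' @examples
#' sp <- duplex_preset("dna")
#' analytic_segment_covariance(sp, inner_window(16))
#' @export
analytic_segment_covariance <- function(spec, window = NULL) {
  if (is.null(window)) window <- inner_window(spec$n_bp)
  window <- check_window(window, spec$n_bp)
  m <- length(window)
  stw <- spec$sds[["h_twist"]]
  sri <- spec$sds[["h_rise"]]
  r_tr <- spec$intra_step_correlation["h_twist", "h_rise"]
  c11 <- m * stw^2 + 2 * spec$neighbor_twist_correlation * stw^2 * (m - 1)
  c22 <- m * sri^2 + 2 * spec$neighbor_rise_correlation * sri^2 * (m - 1)
  c12 <- m * r_tr * stw * sri
  cov2(c11, c12, c22)
}

#' Plant an exact twist-stretch coupling in an ensemble spec
#'
#' Adjusts the intra-step twist-rise correlation of `spec` so that the
#' analytic segment covariance over a window of `m` steps satisfies
#' `c12 / c11 = target_l_per_omega` exactly. Used to build ground-truth
#' ensembles for recovery tests: sampling the returned spec and running any
#' of the coupling estimators should return `target_l_per_omega` up to
#' sampling error.
#'
#' @param spec An `ensemble_spec`.
#' @param target_l_per_omega Desired coupling coefficient in
#'   Angstrom/degree (the slope of length change per unit change of total
#'   twist; +0.032 is DNA-like, -0.037 RNA-like).
#' @param m Window length the target refers to (default 10; the planted
#'   `c12/c11` is window-length dependent through the neighbour terms).
#' @return A modified `ensemble_spec` (label suffixed with the target).
#' @examples
#' sp <- plant_coupling(duplex_preset("dna"), 0.032)
#' cv <- analytic_segment_covariance(sp, inner_window(16))
#' cv$c12 / cv$c11  # 0.032
#' @export
plant_coupling <- function(spec, target_l_per_omega, m = 10) {
  stopifnot(inherits(spec, "ensemble_spec"), m >= 1, m <= spec$n_bp)
  stw <- spec$sds[["h_twist"]]
  sri <- spec$sds[["h_rise"]]
  rho <- spec$neighbor_twist_correlation
  c11 <- m * stw^2 + 2 * rho * stw^2 * (m - 1)
  r_needed <- target_l_per_omega * c11 / (m * stw * sri)
  r_max <- .max_feasible_twist_rise_corr(spec)
  if (abs(r_needed) >= r_max) {
    b_max <- r_max * m * stw * sri / c11
    stop(sprintf(paste0("planted coupling %.4g A/deg infeasible: the ",
                        "assembled covariance loses positive definiteness; ",
                        "feasible interval is (%.4g, %.4g) A/deg"),
                 target_l_per_omega, -b_max, b_max), call. = FALSE)
  }
  R <- spec$intra_step_correlation
  R["h_twist", "h_rise"] <- R["h_rise", "h_twist"] <- r_needed
  ensemble_spec(n_bp = spec$n_bp, n_snapshots = spec$n_snapshots,
                means = spec$means, sds = spec$sds,
                intra_step_correlation = R,
                neighbor_twist_correlation = rho,
                neighbor_rise_correlation = spec$neighbor_rise_correlation,
                seed = spec$seed,
                label = sprintf("%s+coupling=%.4g", spec$label,
                                target_l_per_omega))
}

# Largest |twist-rise correlation| keeping the assembled covariance SPD,
# all other correlations held fixed. Bisection against chol().
.max_feasible_twist_rise_corr <- function(spec, tol = 1e-6) {
  feasible <- function(r) {
    R <- spec$intra_step_correlation
    R["h_twist", "h_rise"] <- R["h_rise", "h_twist"] <- r
    ok <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 0
    if (!ok) return(FALSE)
    sp <- spec
    sp$intra_step_correlation <- R
    !inherits(tryCatch(chol(assemble_covariance(sp)),
                       error = function(e) e), "error")
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid) && feasible(-mid)) lo <- mid else hi <- mid
  }
  lo
}
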