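# Draw Gaussian helical-coordinate ensembles and the series container that
# carries them between the generator, the analyses and file I/O.

#' Helical-coordinate series container
#'
#' A `helical_series` holds a rectangular snapshots x base-pairs x
#' parameters array of helical base-pair axis coordinates. Core parameters
#' are always present in the order `x_disp, y_disp, h_rise, incl, tip,
#' h_twist`; extra named parameters (e.g. `roll`, `propeller`) may follow.
#'
#' @param params Numeric 3-d array `[snapshot, bp, parameter]` with
#'   parameter names on the third dimension, the six core names first.
#' @param label Free-text provenance label.
#' @param snapshot_spacing Spacing between snapshots, metadata only
#'   (arbitrary time units; the analyses treat snapshots as exchangeable).
#' @return An object of class `helical_series`.
#' @export
helical_series <- function(params, label = "", snapshot_spacing = 1) {
  stopifnot(is.array(params), length(dim(params)) == 3)
  pn <- dimnames(params)[[3]]
  if (is.null(pn) || !identical(pn[1:6], .param_names))
    stop("third dimension must be named, starting with: ",
         paste(.param_names, collapse = ", "), call. = FALSE)
  if (anyNA(params) || any(!is.finite(params)))
    stop("series contains missing or non-finite values", call. = FALSE)
  structure(list(params = params, label = label,
                 snapshot_spacing = snapshot_spacing),
            class = "helical_series")
}

#' @export
print.helical_series <- function(x, ...) {
  d <- dim(x$params)
  cat(sprintf("Helical-coordinate series '%s': %d snapshots x %d bp x %d parameters\n",
              x$label, d[1], d[2], d[3]))
  cat("  parameters:", paste(dimnames(x$params)[[3]], collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.helical_series <- function(x) dim(x$params)

#' Sample a helical-coordinate ensemble
#'
#' Draws `n_snapshots` independent snapshots from the `6 * n_bp`-dimensional
#' Gaussian assembled from an [ensemble_spec()]: intra-step 6x6 covariance
#' blocks plus nearest-neighbour twist (and optionally rise) coupling.
#' Snapshots are i.i.d. -- the generator reproduces stationary moments, not
#' the autocorrelation of a dynamical trajectory, which is irrelevant to
#' every moment-based analysis in this package.
#'
#' Deterministic for a given seed: the same spec and seed yield a
#' bit-identical series.
#'
#' @param spec An `ensemble_spec`.
#' @param n_snapshots Number of snapshots; defaults to `spec$n_snapshots`.
#' @param seed Integer seed; defaults to `spec$seed`. `NULL` draws from the
#'   session RNG stream.
#' @return A [helical_series()].
#' @examples
#' s <- sample_ensemble(duplex_preset("dna", seed = 1), n_snapshots = 100)
#' dim(s)
#' @export
sample_ensemble <- function(spec, n_snapshots = spec$n_snapshots,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "ensemble_spec"), n_snapshots >= 1)
  S <- assemble_covariance(spec)
  L <- tryCatch(chol(S), error = function(e)
    stop("assembled covariance is not positive definite; offending spec: ",
         spec$label, call. = FALSE))
  d <- ncol(S)
  mu <- rep(spec$means, times = spec$n_bp)
  Z <- with_seed(seed, matrix(stats::rnorm(n_snapshots * d), n_snapshots, d))
  X <- Z %*% L + matrix(mu, n_snapshots, d, byrow = TRUE)
  params <- array(X, dim = c(n_snapshots, 6L, spec$n_bp))
  # X is bp-major: reorder [snapshot, parameter, bp] -> [snapshot, bp, param]
  params <- aperm(params, c(1, 3, 2))
  dimnames(params) <- list(NULL, NULL, .param_names)
  helical_series(params, label = spec$label)
}

#' Cross-step correlation profile of a helical parameter
#'
#' Lag-k correlations (k = 0..`max_lag`) of one helical parameter between
#' base-pair steps, pooled over snapshots and step pairs, together with the
#' segment-to-step variance ratio `Var(mean over m steps) * m / Var(single
#' step)`. For a tridiagonal neighbour structure with lag-1 correlation
#' `rho` the ratio is `1 + 2 rho (m - 1) / m`; with `rho < 0` it drops
#' below 1 -- twist fluctuates less over a segment than at a single step,
#' the hallmark of nearest-neighbour twist anti-correlation.
#'
#' @param series A `helical_series`.
#' @param parameter Parameter name (default `"h_twist"`).
#' @param window Contiguous step window (default all).
#' @param max_lag Largest lag reported (default 3).
#' @return List with `lag` (0..max_lag), `correlation`, `m`, and
#'   `variance_ratio`.
#' @export
step_correlation_profile <- function(series, parameter = "h_twist",
                                     window = NULL, max_lag = 3) {
  stopifnot(inherits(series, "helical_series"))
  pn <- dimnames(series$params)[[3]]
  if (!(parameter %in% pn))
    stop("unknown parameter '", parameter, "'; available: ",
         paste(pn, collapse = ", "), call. = FALSE)
  n_bp <- dim(series$params)[2]
  if (is.null(window)) window <- seq_len(n_bp)
  window <- check_window(window, n_bp, min_len = 2)
  X <- series$params[, window, parameter, drop = TRUE]
  Xc <- sweep(X, 2, colMeans(X))
  m <- ncol(Xc)
  v <- colMeans(Xc^2)
  cors <- vapply(0:max_lag, function(k) {
    if (k >= m) return(NA_real_)
    num <- mean(Xc[, seq_len(m - k)] * Xc[, seq_len(m - k) + k])
    den <- sqrt(mean(v[seq_len(m - k)]) * mean(v[seq_len(m - k) + k]))
    num / den
  }, numeric(1))
  seg_var <- stats::var(rowMeans(X))
  step_var <- mean(apply(X, 2, stats::var))
  list(lag = 0:max_lag, correlation = cors, m = m,
       variance_ratio = seg_var * m / step_var)
}
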