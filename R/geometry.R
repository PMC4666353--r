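# Rigid base-pair helicoidal geometry: build 3D duplex models from helical
# axis parameters, invert the construction, and measure extension, radius
# and groove widths.
#
# Convention (fixed for exact round-tripping): global helical axis = +z.
# Base pair i carries cumulative phase phi_i = sum of step twists and
# height z_i = sum of rises, with the first base pair anchored at
# phi = 0, z = 0 (its own twist/rise are step parameters with no
# preceding step and are defined as 0 on extraction). Orientation
# O_i = Rz(phi_i) Rx(incl_i) Ry(tip_i); origin = (0, 0, z_i) +
# Rz(phi_i) (x_disp, y_disp, 0).

#' Backbone proxy geometry
#'
#' Positions of one phosphate-like proxy point per strand, expressed in
#' the base-pair frame, plus the radius correction subtracted from
#' proxy-proxy distances when reporting groove widths. The defaults
#' (+/- 8.8 Angstrom along the base-pair y axis, -3.0 along x, correction
#' 5.8 Angstrom, the standard phosphate-to-phosphate convention) are
#' calibrated so that a canonical B-form build (twist 36 deg, rise 3.4
#' Angstrom) yields distinct grooves of about 5.8 (minor) and 11.8 (major)
#' Angstrom.
#'
#' @param strand1_p,strand2_p Length-3 numeric, proxy position in the bp
#'   frame (Angstrom).
#' @param phosphate_radius_correction Subtracted from raw distances
#'   (Angstrom, >= 0).
#' @return Object of class `backbone_geometry`.
#' @export
backbone_geometry <- function(strand1_p = c(-3.0, 8.8, 0),
                              strand2_p = c(-3.0, -8.8, 0),
                              phosphate_radius_correction = 5.8) {
  stopifnot(length(strand1_p) == 3, length(strand2_p) == 3,
            phosphate_radius_correction >= 0)
  if (all(strand1_p == 0) || all(strand2_p == 0))
    stop("backbone proxy points must be nonzero", call. = FALSE)
  structure(list(strand1_p = as.numeric(strand1_p),
                 strand2_p = as.numeric(strand2_p),
                 phosphate_radius_correction = phosphate_radius_correction),
            class = "backbone_geometry")
}

#' Build a rigid base-pair duplex model
#'
#' Stacks base-pair frames along the +z helical axis from a table of
#' helical axis parameters (one row per base pair): helical twist and rise
#' accumulate into phase and height, inclination and tip rotate the pair
#' out of the perpendicular plane, and x/y-displacement offset its origin
#' from the axis in the rotated frame. The first base pair anchors the
#' model at phase 0, height 0.
#'
#' @param params Data frame with columns `x_disp, y_disp, h_rise, incl,
#'   tip, h_twist` (Angstrom / degrees), one row per base pair (>= 2).
#'   `|incl|` and `|tip|` must be < 90 deg (Euler degeneracy).
#' @param backbone A [backbone_geometry()].
#' @param labels Optional per-bp labels.
#' @return Object of class `duplex_model`: `origins` (n x 3),
#'   `orientations` (3 x 3 x n, columns = bp x/y/z axes), `backbone`,
#'   `labels`.
#' @examples
#' p <- uniform_params(11, h_twist = 36, h_rise = 3.4)
#' m <- build_duplex(p)
#' duplex_extent(m)   # 34 Angstrom
#' @export
build_duplex <- function(params, backbone = backbone_geometry(),
                         labels = NULL) {
  params <- as.data.frame(params)
  miss <- setdiff(.param_names, names(params))
  if (length(miss))
    stop("params missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(params)
  if (n < 2) stop("need at least 2 base pairs", call. = FALSE)
  if (any(abs(params$incl) >= 90) || any(abs(params$tip) >= 90))
    stop("|inclination| and |tip| must be < 90 deg (Euler degeneracy)",
         call. = FALSE)
  if (any(params$h_rise[-1] <= 0))
    stop("helical rise must be positive", call. = FALSE)
  phi <- cumsum(c(0, params$h_twist[-1]))
  z <- cumsum(c(0, params$h_rise[-1]))
  origins <- matrix(0, n, 3)
  orientations <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    Rz <- rot_z(phi[i])
    orientations[, , i] <- Rz %*% rot_x(params$incl[i]) %*% rot_y(params$tip[i])
    origins[i, ] <- c(0, 0, z[i]) +
      Rz %*% c(params$x_disp[i], params$y_disp[i], 0)
  }
  if (is.null(labels)) labels <- sprintf("bp%02d", seq_len(n))
  structure(list(origins = origins, orientations = orientations,
                 backbone = backbone, labels = labels),
            class = "duplex_model")
}

#' Uniform helical parameter table
#'
#' Convenience constructor for `n_bp` identical base pairs; the common
#' starting point for regular A- or B-form models.
#'
#' @param n_bp Number of base pairs.
#' @param x_disp,y_disp,h_rise,incl,tip,h_twist Parameter values.
#' @return A data frame usable by [build_duplex()].
#' @export
uniform_params <- function(n_bp, x_disp = 0, y_disp = 0, h_rise = 3.4,
                           incl = 0, tip = 0, h_twist = 36) {
  data.frame(x_disp = rep(x_disp, n_bp), y_disp = y_disp, h_rise = h_rise,
             incl = incl, tip = tip, h_twist = h_twist)
}

#' @export
print.duplex_model <- function(x, ...) {
  n <- nrow(x$origins)
  cat(sprintf("Rigid base-pair duplex model: %d bp, z extent %.2f A, mean radius %.2f A\n",
              n, x$origins[n, 3] - x$origins[1, 3], helix_radius(x)))
  invisible(x)
}

#' Extract helical parameters from a duplex model
#'
#' Exact inverse of [build_duplex()] on models satisfying its convention:
#' each orientation is decomposed as `Rz(phi) Rx(incl) Ry(tip)` (z-x-y
#' Euler order), step twists are successive phase differences unwrapped to
#' (-180, 180], rises are successive height differences, and displacements
#' are the in-plane components of `Rz(-phi) (origin - (0,0,z))`. The first
#' base pair's twist and rise are reported as 0 (no preceding step).
#'
#' @param model A `duplex_model`.
#' @return Data frame of helical parameters, one row per base pair.
#' @export
extract_params <- function(model) {
  stopifnot(inherits(model, "duplex_model"))
  n <- nrow(model$origins)
  phi <- numeric(n); incl <- numeric(n); tip <- numeric(n)
  xd <- numeric(n); yd <- numeric(n)
  for (i in seq_len(n)) {
    O <- model$orientations[, , i]
    if (max(abs(crossprod(O) - diag(3))) > 1e-8 || det(O) < 0)
      stop("orientation ", i, " is not right-handed orthonormal",
           call. = FALSE)
    # y column of Rz(phi) Rx(incl) Ry(tip) is (-sin(phi) cos(incl),
    # cos(phi) cos(incl), sin(incl)); x row of Rz(-phi) O gives tip.
    incl[i] <- rad2deg(asin(max(-1, min(1, O[3, 2]))))
    if (abs(abs(incl[i]) - 90) < 1e-9)
      stop("degenerate decomposition: |inclination| = 90 deg", call. = FALSE)
    phi[i] <- rad2deg(atan2(-O[1, 2], O[2, 2]))
    N <- rot_z(-phi[i]) %*% O
    tip[i] <- rad2deg(atan2(N[1, 3], N[1, 1]))
    v <- rot_z(-phi[i]) %*% c(model$origins[i, 1], model$origins[i, 2], 0)
    xd[i] <- v[1]; yd[i] <- v[2]
  }
  z <- model$origins[, 3]
  data.frame(x_disp = xd, y_disp = yd,
             h_rise = c(0, diff(z)),
             incl = incl, tip = tip,
             h_twist = c(0, wrap_angle(diff(phi))))
}

#' Extent of a duplex model along the helical axis
#'
#' Height difference `z_last - z_first` over the window, which under the
#' build convention equals the sum of the window's helical rises. The
#' end-to-end origin distance is attached as attribute `end_to_end`.
#'
#' @param model A `duplex_model`.
#' @param window Contiguous bp indices (>= 2; default all).
#' @return Length in Angstrom with attribute `end_to_end`.
#' @export
duplex_extent <- function(model, window = NULL) {
  stopifnot(inherits(model, "duplex_model"))
  n <- nrow(model$origins)
  if (is.null(window)) window <- seq_len(n)
  window <- check_window(window, n, min_len = 2)
  a <- min(window); b <- max(window)
  ext <- model$origins[b, 3] - model$origins[a, 3]
  attr(ext, "end_to_end") <-
    sqrt(sum((model$origins[b, ] - model$origins[a, ])^2))
  ext
}

#' Mean helix radius of a duplex model
#'
#' Mean radial distance of the base-pair origins from the z (helical)
#' axis; |x-displacement| for a regular build with zero y-displacement.
#'
#' @param model A `duplex_model`.
#' @return Radius in Angstrom.
#' @export
helix_radius <- function(model) {
  stopifnot(inherits(model, "duplex_model"))
  mean(sqrt(model$origins[, 1]^2 + model$origins[, 2]^2))
}

# Backbone proxy coordinates: list of n x 3 matrices, one per strand.
backbone_points <- function(model) {
  n <- nrow(model$origins)
  p1 <- matrix(0, n, 3); p2 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    O <- model$orientations[, , i]
    p1[i, ] <- model$origins[i, ] + O %*% model$backbone$strand1_p
    p2[i, ] <- model$origins[i, ] + O %*% model$backbone$strand2_p
  }
  list(strand1 = p1, strand2 = p2)
}

#' Groove widths of a duplex model
#'
#' For each interior base pair, the minimal cross-strand proxy-proxy
#' distance over register offsets `j - i` in `[-max_off, -2]` (minor
#' groove) and `[+2, +max_off]` (major groove), minus the phosphate
#' radius correction, floored at 0 -- the standard closest
#' phosphate-across-the-groove convention. The search reaches almost a
#' full turn on each side (`max_off = round(360 / mean step twist) - 2`)
#' so that the nearest cross-strand approach is captured even when it
#' falls slightly past the nominal half turn; this keeps the metric
#' continuous across families of structures whose twist straddles an
#' integer half-turn register. The minor/major assignment follows the
#' B-form calibration of the default [backbone_geometry()] (the negative
#' register direction is the narrow groove of the canonical B build) and
#' is fixed thereafter.
#'
#' @param model A `duplex_model` spanning at least `2 * max_off + 1` base
#'   pairs (about two helical turns).
#' @return A `groove_widths` data frame: `position` (bp index), `minor`,
#'   `major` (Angstrom).
#' @export
groove_widths <- function(model) {
  stopifnot(inherits(model, "duplex_model"))
  n <- nrow(model$origins)
  pars <- extract_params(model)
  mean_twist <- mean(abs(pars$h_twist[-1]))
  if (mean_twist <= 0) stop("untwisted model has no grooves", call. = FALSE)
  ht <- max(3L, as.integer(round(360 / mean_twist)) - 2L)
  need <- 2L * ht + 1L
  if (n < need)
    stop(sprintf(paste0("model too short for groove measurement: need >= ",
                        "%d bp (about two turns at %.1f deg/step), have %d"),
                 need, mean_twist, n), call. = FALSE)
  bp <- backbone_points(model)
  corr <- model$backbone$phosphate_radius_correction
  pos <- seq.int(ht + 1L, n - ht)
  dist_min <- function(i, offs) {
    j <- i + offs
    min(sqrt(rowSums((bp$strand2[j, , drop = FALSE] -
                      matrix(bp$strand1[i, ], length(j), 3,
                             byrow = TRUE))^2)))
  }
  minor <- vapply(pos, function(i) dist_min(i, -(2:ht)), numeric(1))
  major <- vapply(pos, function(i) dist_min(i, 2:ht), numeric(1))
  structure(data.frame(position = pos,
                       minor = pmax(minor - corr, 0),
                       major = pmax(major - corr, 0)),
            class = c("groove_widths", "data.frame"))
}

#' Helical rise consistent with a fixed stacking distance
#'
#' Solves for the helical rise `h` at which the inter-origin vector of two
#' consecutive base pairs (built with uniform parameters) has a component
#' of magnitude `stack_distance` along the mean base-normal direction.
#' This encodes the geometric mechanism of twist-stretch coupling: with
#' inclined, displaced base pairs the stacking distance is shared between
#' rise, the in-plane chord set by twist and x-displacement, and the
#' projection set by inclination, so rise must fall as inclination or the
#' chord grows at fixed stacking.
#'
#' Solved by 1-D root finding (tolerance 1e-10 Angstrom) against the 3D
#' two-frame build itself.
#'
#' @param stack_distance Target stacking distance (Angstrom, > 0).
#' @param inclination,tip Base-pair plane rotations (deg, |.| < 90).
#' @param x_disp,y_disp Displacements (Angstrom).
#' @param twist Step twist (deg).
#' @return Rise in Angstrom.
#' @examples
#' stack_to_rise(3.4, inclination = 0, x_disp = 0, twist = 36)  # 3.4
#' @export
stack_to_rise <- function(stack_distance, inclination = 0, x_disp = 0,
                          twist = 34, y_disp = 0, tip = 0) {
  stopifnot(stack_distance > 0, abs(inclination) < 90, abs(tip) < 90)
  proj <- function(h) {
    m <- build_duplex(uniform_params(2, x_disp = x_disp, y_disp = y_disp,
                                     h_rise = h, incl = inclination,
                                     tip = tip, h_twist = twist))
    nrm <- m$orientations[, 3, 1] + m$orientations[, 3, 2]
    nrm <- nrm / sqrt(sum(nrm^2))
    sum((m$origins[2, ] - m$origins[1, ]) * nrm)
  }
  eps <- 1e-9
  base <- proj(eps)                # in-plane chord contribution at h -> 0
  nz <- (proj(1 + eps) - base)     # d proj / d h (> 0 for |incl|,|tip| < 90)
  if (base >= stack_distance)
    stop(sprintf(paste0("no rise achieves stacking distance %.4g A; ",
                        "minimum feasible stack distance is %.4g A"),
                 stack_distance, base), call. = FALSE)
  hi <- (stack_distance - base) / nz * 2 + 1
  stats::uniroot(function(h) proj(h) - stack_distance,
                 interval = c(eps, hi), tol = 1e-12)$root
}
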