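# Internal helpers: constants, rotations, angle bookkeeping, RNG discipline.

# Boltzmann constant in the unit systems used throughout.
.kB_kcal <- 0.0019872   # kcal mol^-1 K^-1
.kB_pN_nm <- 0.0138065  # pN nm K^-1

.param_names <- c("x_disp", "y_disp", "h_rise", "incl", "tip", "h_twist")

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(x) {
  w <- x - 360 * floor(x / 360 + 0.5)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

rot_x <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Validate a window of step indices: integer, 1-based, contiguous, within n.
check_window <- function(window, n, min_len = 1) {
  if (length(window) == 0) stop("window is empty", call. = FALSE)
  window <- as.integer(window)
  if (any(window < 1L) || any(window > n))
    stop(sprintf("window indices must lie in [1, %d]", n), call. = FALSE)
  if (length(window) > 1 && !all(diff(window) == 1L))
    stop("window must be a contiguous range of step indices", call. = FALSE)
  if (length(window) < min_len)
    stop(sprintf("window must span at least %d steps", min_len), call. = FALSE)
  window
}

#' Central analysis window of a duplex
#'
#' Index range of the `m` central base-pair steps of an `n_bp` duplex,
#' mirroring the usual practice of excluding the sterically less restricted
#' termini from helical-parameter analysis (the central 10 of a 16-bp
#' duplex, by default).
#'
#' @param n_bp Number of base pairs in the duplex.
#' @param m Number of central steps to keep (default 10).
#' @return Integer vector of 1-based step indices, contiguous and centered.
#' @examples
#' inner_window(16)      # steps 4..13
#' inner_window(16, 12)  # steps 3..14
#' @export
inner_window <- function(n_bp, m = 10) {
  stopifnot(n_bp >= m, m >= 1)
  lo <- floor((n_bp - m) / 2) + 1L
  seq.int(lo, lo + m - 1L)
}

is_spd2 <- function(c11, c12, c22) {
  c11 > 0 && c22 > 0 && (c11 * c22 - c12^2) > 0
}
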