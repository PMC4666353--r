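# Binned correlation analysis: per-snapshot window means, fixed-width
# binning of y against x with SEMs, a weighted linear fit restricted to a
# window around the mean, block-averaged errors, and an occupancy-based
# free-energy surface.

#' Per-snapshot window mean of one helical parameter
#'
#' Arithmetic mean of `parameter` over the step window for every snapshot;
#' the x/y variables of the binned correlation plots.
#'
#' @param series A [helical_series()].
#' @param parameter Parameter name, e.g. `"h_twist"`.
#' @param window Contiguous step window (default the central 10).
#' @return Numeric vector, one value per snapshot.
#' @export
snapshot_means <- function(series, parameter, window = NULL) {
  stopifnot(inherits(series, "helical_series"))
  pn <- dimnames(series$params)[[3]]
  if (!(parameter %in% pn))
    stop("unknown parameter '", parameter, "'; available: ",
         paste(pn, collapse = ", "), call. = FALSE)
  n_bp <- dim(series$params)[2]
  if (is.null(window)) window <- inner_window(n_bp, min(10, n_bp))
  window <- check_window(window, n_bp)
  rowMeans(series$params[, window, parameter, drop = FALSE], dims = 1)
}

#' Bin y against x in fixed-width x intervals
#'
#' Groups the paired values into contiguous x bins of width `bin_width`
#' anchored at multiples of the width, and records the per-bin means of x
#' and y with their standard errors SD/sqrt(count), and the count (both
#' coordinates are averaged within an interval, so both carry error
#' bars). Bins holding fewer than `min_count` points are dropped. The
#' default 0.2 deg width is the conventional resolution for
#' twist-conditioned averages of helical parameters.
#'
#' @param x,y Equal-length numeric vectors (e.g. per-snapshot mean twist
#'   and mean rise).
#' @param bin_width Bin width in x units (default 0.2).
#' @param min_count Minimum points per retained bin (default 50).
#' @param x_name,y_name Labels carried into the result.
#' @return A `binned_series`: data frame with columns `center` (bin
#'   midpoint), `x_mean`, `x_sem`, `mean`, `sem`, `count`; attributes
#'   `bin_width`, `global_mean_x`, `min_count`, `x_name`, `y_name`.
#' @export
bin_xy <- function(x, y, bin_width = 0.2, min_count = 50,
                   x_name = "x", y_name = "y") {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(x) == length(y), bin_width > 0)
  bin <- floor(x / bin_width)
  n <- tapply(y, bin, length)
  centers <- (as.numeric(names(n)) + 0.5) * bin_width
  out <- data.frame(center = centers,
                    x_mean = as.numeric(tapply(x, bin, mean)),
                    x_sem = as.numeric(tapply(x, bin, stats::sd)) /
                      sqrt(as.numeric(n)),
                    mean = as.numeric(tapply(y, bin, mean)),
                    sem = as.numeric(tapply(y, bin, stats::sd)) /
                      sqrt(as.numeric(n)),
                    count = as.numeric(n))
  out$sem[is.na(out$sem)] <- 0   # single-point bin
  out$x_sem[is.na(out$x_sem)] <- 0
  keep <- out$count >= min_count | length(x) < min_count
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$center), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("binned_series", "data.frame"),
            bin_width = bin_width, global_mean_x = mean(x),
            min_count = min_count, x_name = x_name, y_name = y_name)
}

#' Weighted linear fit of binned means around the global mean
#'
#' Weighted least squares of the bin means of y against the bin means of
#' x, restricted to bins whose center lies within `fit_halfwidth` of the
#' global mean x (the conventional +/- 1.5 deg window around the average
#' twist). Weights are 1/SEM^2 (`weighted = FALSE` gives the unweighted
#' fit).
#'
#' @param b A [bin_xy()] result.
#' @param fit_halfwidth Half-width of the fitting window in x units.
#' @param weighted Use 1/SEM^2 weights (default TRUE).
#' @return A `linear_fit`: list with `slope`, `intercept`, `slope_se`,
#'   `fit_halfwidth`, `n_bins_used`.
#' @export
fit_slope <- function(b, fit_halfwidth = 1.5, weighted = TRUE) {
  stopifnot(inherits(b, "binned_series"), fit_halfwidth > 0)
  x0 <- attr(b, "global_mean_x")
  use <- abs(b$center - x0) <= fit_halfwidth
  if (sum(use) < 3)
    stop(sprintf(paste0("only %d bins within +/- %g of the mean; ",
                        "need >= 3 (widen fit_halfwidth?)"),
                 sum(use), fit_halfwidth), call. = FALSE)
  d <- b[use, , drop = FALSE]
  w <- if (weighted) {
    sem <- pmax(d$sem, max(d$sem) * 1e-8, .Machine$double.eps)
    1 / sem^2
  } else rep(1, nrow(d))
  fit <- stats::lm(mean ~ x_mean, data = d, weights = w)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = unname(sqrt(diag(stats::vcov(fit)))[2]),
                 fit_halfwidth = fit_halfwidth, n_bins_used = nrow(d),
                 weighted = weighted,
                 x_name = attr(b, "x_name"), y_name = attr(b, "y_name")),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit of %s vs %s (+/- %g window, %d bins%s):\n",
              x$y_name, x$x_name, x$fit_halfwidth, x$n_bins_used,
              if (x$weighted) ", 1/SEM^2 weights" else ""))
  cat(sprintf("  slope = %+.5g +/- %.3g, intercept = %.5g\n",
              x$slope, x$slope_se, x$intercept))
  invisible(x)
}

#' Block-averaged mean and error
#'
#' Splits a series into `n_blocks` contiguous blocks (remainder to the
#' last), and reports the overall mean together with the SD of the block
#' means as the error estimate -- the standard error bar for trajectory
#' averages.
#'
#' @param values Numeric series.
#' @param n_blocks Number of blocks (>= 2, default 5).
#' @return List `mean`, `error` (SD over block means), `block_means`.
#' @export
block_errors <- function(values, n_blocks = 5) {
  stopifnot(n_blocks >= 2)
  n <- length(values)
  if (n < n_blocks)
    stop(sprintf("series length %d shorter than n_blocks = %d", n, n_blocks),
         call. = FALSE)
  size <- n %/% n_blocks
  starts <- (seq_len(n_blocks) - 1L) * size + 1L
  ends <- c(starts[-1] - 1L, n)
  bm <- vapply(seq_len(n_blocks),
               function(b) mean(values[starts[b]:ends[b]]), numeric(1))
  list(mean = mean(values), error = stats::sd(bm), block_means = bm)
}

#' Occupancy-based free-energy surface
#'
#' Two-dimensional histogram of `(x, y)` converted to a potential of mean
#' force, `-kB T ln(count / max_count)` (kcal/mol), so the most populated
#' cell sits at 0. Cells with fewer than `min_count` points are masked
#' (`NA`); values are capped at `cap` kcal/mol. For jointly Gaussian input
#' the surface is the quadratic form `1/2 kB T d' C^-1 d` up to sampling
#' noise, and the orientation of its low-energy valley displays the sign
#' of the x-y coupling.
#'
#' @param x,y Equal-length numeric vectors.
#' @param x_bin,y_bin Bin widths.
#' @param temperature Temperature in K (default 300).
#' @param min_count Mask threshold (default 10 points per cell).
#' @param cap Upper cap of reported values, kcal/mol (default 35).
#' @return A `pmf_surface`: list with `x_edges`, `y_edges`, `value`
#'   (matrix, NA where masked), `count`, `temperature`, `cap`.
#' @export
pmf_surface <- function(x, y, x_bin = 0.2, y_bin = 0.02, temperature = 300,
                        min_count = 10, cap = 35) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(x) == length(y), x_bin > 0, y_bin > 0)
  ix <- floor(x / x_bin); iy <- floor(y / y_bin)
  xr <- range(ix); yr <- range(iy)
  counts <- matrix(0, xr[2] - xr[1] + 1L, yr[2] - yr[1] + 1L)
  tb <- table(factor(ix, levels = xr[1]:xr[2]),
              factor(iy, levels = yr[1]:yr[2]))
  counts[] <- as.numeric(tb)
  kT <- .kB_kcal * temperature
  val <- -kT * log(counts / max(counts))
  val[counts < min_count] <- NA
  val[!is.na(val) & val > cap] <- cap
  structure(list(x_edges = (xr[1]:(xr[2] + 1L)) * x_bin,
                 y_edges = (yr[1]:(yr[2] + 1L)) * y_bin,
                 value = val, count = counts,
                 temperature = temperature, cap = cap),
            class = "pmf_surface")
}

#' @export
print.pmf_surface <- function(x, ...) {
  cat(sprintf("Occupancy free-energy surface: %d x %d cells, %d occupied\n",
              nrow(x$value), ncol(x$value), sum(!is.na(x$value))))
  cat(sprintf("  range 0..%.2f kcal/mol (cap %g)\n",
              max(x$value, na.rm = TRUE), x$cap))
  invisible(x)
}

#' @export
plot.pmf_surface <- function(x, ...) {
  xc <- (x$x_edges[-1] + x$x_edges[-length(x$x_edges)]) / 2
  yc <- (x$y_edges[-1] + x$y_edges[-length(x$y_edges)]) / 2
  graphics::image(xc, yc, x$value, col = grDevices::hcl.colors(50, "viridis"),
                  xlab = "x", ylab = "y", ...)
  invisible(x)
}

# Principal-axis slope of the low-energy valley: sign of the covariance of
# cell coordinates weighted by occupancy. Used by the sign tests.
surface_tilt <- function(surface) {
  stopifnot(inherits(surface, "pmf_surface"))
  xc <- (surface$x_edges[-1] + surface$x_edges[-length(surface$x_edges)]) / 2
  yc <- (surface$y_edges[-1] + surface$y_edges[-length(surface$y_edges)]) / 2
  w <- surface$count
  W <- sum(w)
  mx <- sum(outer(xc, rep(1, length(yc))) * w) / W
  my <- sum(outer(rep(1, length(xc)), yc) * w) / W
  sxy <- sum((outer(xc, rep(1, length(yc))) - mx) *
             (outer(rep(1, length(xc)), yc) - my) * w) / W
  sxx <- sum((outer(xc, rep(1, length(yc))) - mx)^2 * w) / W
  sxy / sxx
}
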