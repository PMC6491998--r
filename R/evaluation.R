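# Error evaluation: normalized error maps against a reference B1 map and
# summary statistics (MAE, medAE, 99% quantile) over a region of interest,
# plus histogram / exceedance utilities and trial averaging for random
# sampling patterns.

#' Normalized B1 error map
#'
#' Pointwise `100 * |b1_ref - b1_rec| / b1_nom`, the error in percent of the
#' nominal B1 magnitude. The normalization makes the measure proportional to
#' the correction error of quantitative models using the map. All three
#' inputs must share units (e.g. microtesla).
#'
#' @param b1_rec,b1_ref Reconstructed and reference B1 maps (same grid).
#' @param b1_nom Nominal B1 magnitude (> 0), same units as the maps.
#' @return Real array of errors in percent.
#' @export
error_map <- function(b1_rec, b1_ref, b1_nom) {
  if (!identical(dim(.as_vol(b1_rec)), dim(.as_vol(b1_ref))))
    stop("b1_rec and b1_ref grids differ")
  if (b1_nom <= 0) stop("b1_nom must be positive")
  100 * abs(b1_ref - b1_rec) / b1_nom
}

#' Summary statistics of an error map over an ROI
#'
#' Mean absolute error (MAE), its median (medAE) and the 99% quantile (q99,
#' linear interpolation between order statistics) of the error values inside
#' the region of interest.
#'
#' @param err Error map in percent (from [error_map()]).
#' @param roi Logical mask of the same grid; `NULL` uses all voxels.
#' @return Named numeric vector `c(mae, medae, q99)` with attribute
#'   `n_roi`.
#' @export
summarize_error <- function(err, roi = NULL) {
  v <- if (is.null(roi)) as.numeric(err) else {
    if (!identical(dim(.as_vol(err)), dim(.as_vol(roi))))
      stop("roi grid differs from error map")
    as.numeric(err[roi > 0])
  }
  if (length(v) == 0) stop("empty ROI")
  out <- c(mae = mean(v), medae = stats::median(v),
           q99 = unname(stats::quantile(v, 0.99, type = 7)))
  attr(out, "n_roi") <- length(v)
  out
}

#' Error histogram and exceedance fraction
#'
#' `error_histogram()` bins the ROI error values with a fixed bin width
#' starting at 0 (counts sum to the ROI size); `exceedance_fraction()`
#' returns the percentage of ROI voxels whose error exceeds a limit, e.g.
#' the fraction above a 2.5% error budget.
#'
#' @param err Error map in percent.
#' @param roi Logical ROI mask (`NULL`: all voxels).
#' @param bin_width Histogram bin width in percent (> 0).
#' @param limit Error limit in percent.
#' @return `error_histogram()`: list with `breaks`, `counts`, `mids`;
#'   `exceedance_fraction()`: scalar percentage.
#' @export
error_histogram <- function(err, roi = NULL, bin_width = 0.25) {
  if (bin_width <= 0) stop("bin width must be positive")
  v <- if (is.null(roi)) as.numeric(err) else as.numeric(err[roi > 0])
  if (length(v) == 0) stop("empty ROI")
  breaks <- seq(0, max(v) + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids)
}

#' @rdname error_histogram
#' @export
exceedance_fraction <- function(err, roi = NULL, limit = 2.5) {
  v <- if (is.null(roi)) as.numeric(err) else as.numeric(err[roi > 0])
  if (length(v) == 0) stop("empty ROI")
  100 * mean(v > limit)
}

#' Average error statistics across independent trials
#'
#' Arithmetic mean of each statistic across trials, the convention used to
#' report random-pattern results (each trial evaluated first, then
#' averaged).
#'
#' @param trials A list of `c(mae, medae, q99)` vectors from
#'   [summarize_error()].
#' @return Named numeric vector of averaged statistics.
#' @export
trial_average <- function(trials) {
  if (length(trials) < 1) stop("at least one trial is required")
  m <- do.call(rbind, lapply(trials, function(t) t[c("mae", "medae", "q99")]))
  colMeans(m)
}

#' One-call evaluation of a reconstruction against a reference
#'
#' Convenience wrapper building the error map and its ROI statistics.
#'
#' @param b1_rec,b1_ref B1 maps in the same units.
#' @param b1_nom Nominal B1 in the same units.
#' @param roi Logical ROI mask (`NULL`: all voxels).
#' @return List with `error_map`, `stats` and `exceed_2.5`.
#' @export
evaluate_b1 <- function(b1_rec, b1_ref, b1_nom, roi = NULL) {
  em <- error_map(b1_rec, b1_ref, b1_nom)
  list(error_map = em, stats = summarize_error(em, roi),
       exceed_2.5 = exceedance_fraction(em, roi, 2.5))
}
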