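# Cartesian phase-encode subsampling patterns on the (ky, kz) plane.
# The readout axis kx is always fully sampled, so a pattern is a binary
# (Ny, Nz) matrix; the DC encode sits at (floor(Ny/2)+1, floor(Nz/2)+1).

#' @noRd
.dc_index <- function(n) floor(n / 2) + 1L

#' Centered block sampling pattern
#'
#' A contiguous n-by-m rectangle of Cartesian encodes around the k-space
#' center: along an axis of length N the block occupies the (1-based) indices
#' `floor(N/2)+1-floor(n/2) ... floor(N/2)+ceil(n/2)`, which always contains
#' the DC index. This is the pattern family used for prospective
#' acquisitions, exploiting that the B1+ information lives at low spatial
#' frequencies.
#'
#' @param ny,nz Size of the phase-encode plane.
#' @param n,m Block extent along ky and kz.
#' @return Binary (ny, nz) matrix of class `bs_pattern`.
#' @examples
#' p <- block_pattern(128, 32, 12, 4)
#' acceleration_factor(p)  # 85.3
#' @export
block_pattern <- function(ny, nz, n, m) {
  if (n < 1 || m < 1 || n > ny || m > nz)
    stop("block size ", n, "x", m, " does not fit the ", ny, "x", nz, " grid")
  mask <- matrix(0L, ny, nz)
  yi <- .dc_index(ny) - floor(n / 2) + seq_len(n) - 1L
  zi <- .dc_index(nz) - floor(m / 2) + seq_len(m) - 1L
  mask[yi, zi] <- 1L
  structure(mask, class = c("bs_pattern", "matrix"))
}

#' @noRd
.density_pattern <- function(ny, nz, weights, target_r, seed) {
  if (target_r < 1) stop("target acceleration must be >= 1")
  count <- round(ny * nz / target_r)
  if (count < 1) stop("target acceleration leaves no samples")
  dc <- c(.dc_index(ny), .dc_index(nz))
  dc_lin <- (dc[2] - 1L) * ny + dc[1]
  w <- as.numeric(weights)
  w[dc_lin] <- 0  # DC is force-included, draw the remaining count-1
  pos <- which(w > 0)
  if (count - 1L > length(pos))
    stop("requested ", count, " encodes but only ", length(pos) + 1L,
         " have positive density")
  if (!is.null(seed)) set.seed(seed)
  picked <- if (count > 1L)
    sample(pos, count - 1L, replace = FALSE, prob = w[pos]) else integer(0)
  mask <- matrix(0L, ny, nz)
  mask[c(dc_lin, picked)] <- 1L
  structure(mask, class = c("bs_pattern", "matrix"))
}

#' Variable-density random sampling patterns
#'
#' `poly_density_pattern()` draws encodes without replacement from a radially
#' decaying density `(1 - r)^p`, where `r` is the elliptically normalized
#' k-space radius (r = 1 at the edge of the encode plane); larger `p` spreads
#' samples more towards the center. `gauss_density_pattern()` uses a
#' separable Gaussian density centered at DC with standard deviations
#' `sigma_y`, `sigma_z` in encode units, which concentrates the samples even
#' more densely around the k-space center. Both force-include the DC encode
#' and draw exactly `round(ny*nz/target_r)` encodes in total, so the realized
#' acceleration matches the request; masks are reproducible for a fixed seed.
#'
#' @param ny,nz Size of the phase-encode plane.
#' @param p Polynomial degree of the density (> 0).
#' @param sigma_y,sigma_z Gaussian density standard deviations (> 0).
#' @param target_r Desired acceleration factor (>= 1).
#' @param seed RNG seed (integer) for a reproducible mask; `NULL` uses the
#'   current RNG state.
#' @return Binary (ny, nz) matrix of class `bs_pattern`.
#' @export
poly_density_pattern <- function(ny, nz, p, target_r, seed = NULL) {
  if (p <= 0) stop("polynomial degree must be positive")
  dy <- (seq_len(ny) - .dc_index(ny)) / max(abs(seq_len(ny) - .dc_index(ny)), 1)
  dz <- (seq_len(nz) - .dc_index(nz)) / max(abs(seq_len(nz) - .dc_index(nz)), 1)
  r <- sqrt(outer(dy^2, dz^2, `+`))
  w <- pmax(1 - pmin(r, 1), 0)^p
  .density_pattern(ny, nz, w, target_r, seed)
}

#' @rdname poly_density_pattern
#' @export
gauss_density_pattern <- function(ny, nz, sigma_y, sigma_z, target_r,
                                  seed = NULL) {
  if (sigma_y <= 0 || sigma_z <= 0) stop("sigma_y and sigma_z must be positive")
  dy <- seq_len(ny) - .dc_index(ny)
  dz <- seq_len(nz) - .dc_index(nz)
  w <- outer(exp(-dy^2 / (2 * sigma_y^2)), exp(-dz^2 / (2 * sigma_z^2)))
  .density_pattern(ny, nz, w, target_r, seed)
}

#' Acceleration factor of a sampling pattern
#'
#' The ratio of the full Cartesian phase-encode count to the number of
#' acquired encodes, `R = ny*nz / #sampled`.
#'
#' @param mask Binary (ny, nz) sampling pattern.
#' @return Scalar acceleration factor.
#' @export
acceleration_factor <- function(mask) {
  mask <- as.matrix(mask)
  ns <- sum(mask != 0)
  if (ns == 0) stop("empty sampling pattern")
  length(mask) / ns
}
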