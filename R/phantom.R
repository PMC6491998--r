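# Synthetic ground truth and multi-coil Bloch-Siegert acquisition simulator.
# The phantom carries the statistical structure the reconstruction assumes:
# piecewise-constant-per-ellipsoid magnetization magnitude (morphology with
# edges), a smooth low-order polynomial background phase, a smooth B1+ field
# (nominal value plus a wide Gaussian bump), and smooth complex coil
# sensitivity lobes placed on a circle around the field of view.

# default ellipsoid set: Shepp-Logan-like head section, normalized
# coordinates in [-1, 1]; columns: cx, cy, cz, ax, ay, az, theta (deg,
# rotation in the x-y plane), amplitude (later rows overwrite earlier)
#' @noRd
.default_ellipses <- function() {
  rbind(
    c( 0.00,  0.00, 0.00, 0.72, 0.90, 0.88,   0, 1.00),
    c( 0.00, -0.02, 0.00, 0.66, 0.83, 0.80,   0, 0.80),
    c( 0.22,  0.00, 0.00, 0.11, 0.31, 0.60, -18, 0.55),
    c(-0.22,  0.00, 0.00, 0.16, 0.41, 0.60,  18, 0.65),
    c( 0.00,  0.35, 0.00, 0.21, 0.25, 0.50,   0, 0.95),
    c( 0.00,  0.10, 0.15, 0.046, 0.046, 0.25, 0, 0.45),
    c( 0.00, -0.10, -0.15, 0.046, 0.046, 0.25, 0, 0.95),
    c(-0.08, -0.605, 0.00, 0.046, 0.023, 0.35, 0, 0.30),
    c( 0.06, -0.605, 0.00, 0.023, 0.046, 0.35, 0, 0.90))
}

#' Generate a ground-truth phantom for Bloch-Siegert simulations
#'
#' Builds a piecewise-constant magnetization magnitude from a list of
#' ellipsoids (later ellipsoids overwrite earlier ones), a smooth background
#' phase from low-order polynomial coefficients, a smooth B1+ field
#' `b1_nom * (1 + bump_amp * Gaussian bump)`, and `n_coils` complex
#' Gaussian-profile receive sensitivities on a circle around the field of
#' view. Everything is deterministic given `seed` (used only for the random
#' ingredients of the coil phases when `jitter_coils = TRUE`).
#'
#' @param grid Integer vector (Nx, Ny, Nz); default `c(64, 64, 8)`.
#' @param ellipses Matrix with columns (cx, cy, cz, ax, ay, az, theta_deg,
#'   amplitude) in normalized [-1, 1] coordinates; default a Shepp-Logan-like
#'   set.
#' @param phi0_coeffs Coefficients (a0, ax, ay, az, axx, ayy, azz) of the
#'   background phase polynomial in normalized coordinates, in radians.
#' @param b1_nom Nominal B1 peak magnitude in Gauss (default 0.106 G =
#'   10.6 uT, putting the single-sided Bloch-Siegert phase near 0.6 rad for
#'   the reference pulse constant).
#' @param bump_amp Relative amplitude of the Gaussian B1 bump (default 0.3).
#' @param bump_center,bump_width Center and width of the bump in normalized
#'   coordinates.
#' @param n_coils Number of receive coils (default 8).
#' @param coil_width Gaussian width of each coil lobe in normalized units.
#' @param seed Optional integer seed (coil phase jitter).
#' @return An object of class `bs_phantom`: list with `m_mag`, `phi0`,
#'   `b1_map` (Gauss), `coils`, `support`, `roi` (support eroded by one
#'   voxel), `b1_nom` and `grid`.
#' @export
make_phantom <- function(grid = c(64, 64, 8), ellipses = .default_ellipses(),
                         phi0_coeffs = c(0.3, 0.6, -0.4, 0.2, -0.3, 0.25, 0.1),
                         b1_nom = 0.106, bump_amp = 0.3,
                         bump_center = c(0.25, -0.2, 0.1), bump_width = 0.7,
                         n_coils = 8, coil_width = 1.0, seed = NULL) {
  stopifnot(length(grid) == 3L, all(grid >= 1), n_coils >= 1)
  if (is.null(dim(ellipses)) || nrow(ellipses) == 0)
    stop("at least one ellipsoid is required")
  if (any(ellipses[, 8] < 0)) stop("ellipsoid amplitudes must be non-negative")
  if (b1_nom <= 0) stop("b1_nom must be positive")
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  cx <- if (nx > 1) (seq_len(nx) - (nx + 1) / 2) / (nx / 2) else 0
  cy <- if (ny > 1) (seq_len(ny) - (ny + 1) / 2) / (ny / 2) else 0
  cz <- if (nz > 1) (seq_len(nz) - (nz + 1) / 2) / (nz / 2) else 0
  X <- array(rep(cx, times = ny * nz), grid)
  Y <- array(rep(rep(cy, each = nx), times = nz), grid)
  Z <- array(rep(cz, each = nx * ny), grid)

  m_mag <- array(0, grid)
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    th <- e[7] * pi / 180
    xr <- (X - e[1]) * cos(th) + (Y - e[2]) * sin(th)
    yr <- -(X - e[1]) * sin(th) + (Y - e[2]) * cos(th)
    zr <- Z - e[3]
    inside <- (xr / e[4])^2 + (yr / e[5])^2 + (zr / e[6])^2 <= 1
    m_mag[inside] <- e[8]
  }

  a <- rep(0, 7); a[seq_along(phi0_coeffs)] <- phi0_coeffs
  phi0 <- a[1] + a[2] * X + a[3] * Y + a[4] * Z +
    a[5] * X^2 + a[6] * Y^2 + a[7] * Z^2

  r2 <- (X - bump_center[1])^2 + (Y - bump_center[2])^2 +
    (Z - bump_center[3])^2
  b1_map <- b1_nom * (1 + bump_amp * exp(-r2 / (2 * bump_width^2)))

  if (!is.null(seed)) set.seed(seed)
  jitter <- stats::runif(n_coils, -0.2, 0.2)
  coils <- array(0i, c(grid, n_coils))
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
  for (j in seq_len(n_coils)) {
    px <- 1.3 * cos(ang[j]); py <- 1.3 * sin(ang[j])
    dist2 <- (X - px)^2 + (Y - py)^2 + (0.5 * Z)^2
    magj <- exp(-dist2 / (2 * coil_width^2))
    # smooth per-coil phase: constant offset plus a gentle linear ramp
    phj <- ang[j] + jitter[j] + 0.4 * (cos(ang[j]) * X + sin(ang[j]) * Y)
    coils[, , , j] <- magj * exp(1i * phj)
  }

  support <- m_mag > 0
  structure(list(m_mag = m_mag, phi0 = phi0, b1_map = b1_map, coils = coils,
                 support = support, roi = erode_mask(support), b1_nom = b1_nom,
                 grid = grid),
            class = "bs_phantom")
}

#' Erode a 3D logical mask by one voxel
#'
#' Six-neighborhood erosion: a voxel stays in the mask only if it and all
#' face neighbors are inside (axes of length 1 are skipped, so single-slice
#' masks are eroded in-plane only). Used to build the evaluation ROI from
#' the phantom support, the synthetic analogue of excluding the low-signal
#' rim of an anatomical mask.
#'
#' @param mask Logical 3D array.
#' @param iterations Number of erosion passes (default 1).
#' @return Logical array of the same shape.
#' @export
erode_mask <- function(mask, iterations = 1) {
  m <- .as_vol(mask) > 0
  d <- dim(m)
  for (i in seq_len(iterations)) {
    out <- m
    if (d[1] > 1) {
      out <- out & m[c(1, seq_len(d[1] - 1)), , , drop = FALSE] &
        m[c(seq_len(d[1] - 1) + 1, d[1]), , , drop = FALSE]
      out[1, , ] <- FALSE; out[d[1], , ] <- FALSE
    }
    if (d[2] > 1) {
      out <- out & m[, c(1, seq_len(d[2] - 1)), , drop = FALSE] &
        m[, c(seq_len(d[2] - 1) + 1, d[2]), , drop = FALSE]
      out[, 1, ] <- FALSE; out[, d[2], ] <- FALSE
    }
    if (d[3] > 1) {
      out <- out & m[, , c(1, seq_len(d[3] - 1)), drop = FALSE] &
        m[, , c(seq_len(d[3] - 1) + 1, d[3]), drop = FALSE]
      out[, , 1] <- FALSE; out[, , d[3]] <- FALSE
    }
    m <- out
  }
  m
}

#' Simulate a paired Bloch-Siegert acquisition from a phantom
#'
#' Forms the two complex images
#' `I_pm = |M| exp(i (phi0 +/- K_BS B1^2))`, applies the multi-coil masked
#' Fourier forward model per offset, and adds complex white Gaussian noise on
#' the sampled encodes. With `noise_sd = NULL` the noise level is set from
#' `ksnr_db`, defined as `20*log10(rms of sampled noiseless k / noise_sd)`.
#' Noise is the only seeded randomness, so two seeds differ purely in the
#' noise realization.
#'
#' @param phantom A [make_phantom()] object.
#' @param kbs Pulse constant in rad/G^2 (default the reference value 53.4 of
#'   a 10 ms Gaussian pulse at 4 kHz offset), or a [bs_pulse()] object.
#' @param mask_pos,mask_neg Binary (Ny, Nz) sampling masks for the positive
#'   and negative offset scans (default fully sampled).
#' @param noise_sd Std of the complex noise per k-space sample; `NULL`
#'   derives it from `ksnr_db`.
#' @param ksnr_db Sampled k-space SNR in dB used when `noise_sd` is `NULL`
#'   (default 40); `Inf` gives noiseless data.
#' @param seed Integer seed for the noise realization.
#' @return An object of class `bs_acquisition`: list with `k_pos`, `k_neg`
#'   (complex (Nx, Ny, Nz, Nc), zero off-pattern), `mask_pos`, `mask_neg`,
#'   `kbs`, `b1_nom` (Gauss), `coils`, `noise_sd` and `grid`.
#' @export
simulate_bs_acquisition <- function(phantom, kbs = 53.4, mask_pos = NULL,
                                    mask_neg = NULL, noise_sd = NULL,
                                    ksnr_db = 40, seed = NULL) {
  stopifnot(inherits(phantom, "bs_phantom"))
  if (inherits(kbs, "bs_pulse")) kbs <- compute_kbs(kbs)
  if (kbs <= 0) stop("kbs must be positive")
  g <- phantom$grid
  if (is.null(mask_pos)) mask_pos <- matrix(1L, g[2], g[3])
  if (is.null(mask_neg)) mask_neg <- matrix(1L, g[2], g[3])

  phi_bs <- kbs * phantom$b1_map^2  # shared code path with b1_from_phase's inverse
  i_pos <- phantom$m_mag * exp(1i * (phantom$phi0 + phi_bs))
  i_neg <- phantom$m_mag * exp(1i * (phantom$phi0 - phi_bs))
  k_pos <- forward_op(i_pos, phantom$coils, mask_pos)
  k_neg <- forward_op(i_neg, phantom$coils, mask_neg)

  if (is.null(noise_sd)) {
    if (is.finite(ksnr_db)) {
      samp <- c(Mod(k_pos)[rep(.mask_volume(mask_pos, g[1]) > 0,
                               times = dim(k_pos)[4])],
                Mod(k_neg)[rep(.mask_volume(mask_neg, g[1]) > 0,
                               times = dim(k_neg)[4])])
      noise_sd <- sqrt(mean(samp^2)) * 10^(-ksnr_db / 20)
    } else noise_sd <- 0
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    add_noise <- function(k, mask) {
      n <- length(k)
      eps <- complex(real = stats::rnorm(n, sd = noise_sd / sqrt(2)),
                     imaginary = stats::rnorm(n, sd = noise_sd / sqrt(2)))
      dim(eps) <- dim(k)
      mv <- .mask_volume(mask, dim(k)[1])
      for (j in seq_len(dim(k)[4]))
        k[, , , j] <- .slice4(k, j) + .slice4(eps, j) * mv
      k
    }
    k_pos <- add_noise(k_pos, mask_pos)
    k_neg <- add_noise(k_neg, mask_neg)
  }

  structure(list(k_pos = k_pos, k_neg = k_neg, mask_pos = mask_pos,
                 mask_neg = mask_neg, kbs = kbs, b1_nom = phantom$b1_nom,
                 coils = phantom$coils, noise_sd = noise_sd, grid = g),
            class = "bs_acquisition")
}
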