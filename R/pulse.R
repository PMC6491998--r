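# Bloch-Siegert pulse physics: the pulse constant K_BS links the squared B1
# peak magnitude to the phase accrued during an off-resonant RF pulse,
# phi_BS = K_BS * B1_peak^2. B1 is carried internally in Gauss so that K_BS
# keeps its conventional rad/G^2 units; maps are reported in microtesla
# (1 G = 100 uT).

#' Gyromagnetic ratio of 1H in rad s^-1 G^-1
#' @noRd
.GAMMA_1H <- 2 * pi * 4257.7

#' Describe a Bloch-Siegert pulse
#'
#' Builds the sampled normalized envelope (peak value 1) of an off-resonant
#' pulse together with its duration and resonance offset. Supported shapes
#' are a constant (rectangular) envelope and a truncated Gaussian
#' `exp(-(t - T/2)^2 / (2 (sigma_fraction*T)^2))`, the shape commonly played
#' out on scanners. A custom envelope can be supplied directly.
#'
#' @param shape `"constant"`, `"gauss"`, or `"custom"`.
#' @param t_pulse_ms Pulse duration in milliseconds.
#' @param f_bs_khz Resonance offset in kHz (sign gives the offset side).
#' @param sigma_fraction Gaussian width as a fraction of the duration
#'   (default 0.2).
#' @param envelope Numeric vector of envelope samples for `shape = "custom"`;
#'   rescaled so its peak is 1.
#' @param n_samples Number of envelope samples (default 1000).
#' @param gamma Gyromagnetic ratio in rad s^-1 G^-1 (default 1H).
#' @return An object of class `bs_pulse` with fields `b1_norm`, `t` (s),
#'   `t_pulse` (s), `omega_bs` (rad/s) and `gamma`.
#' @examples
#' p <- bs_pulse("constant", t_pulse_ms = 10, f_bs_khz = 4)
#' compute_kbs(p)  # ~142.4 rad/G^2
#' @export
bs_pulse <- function(shape = c("gauss", "constant", "custom"),
                     t_pulse_ms = 10, f_bs_khz = 4, sigma_fraction = 0.2,
                     envelope = NULL, n_samples = 1000,
                     gamma = .GAMMA_1H) {
  shape <- match.arg(shape)
  if (t_pulse_ms <= 0) stop("pulse duration must be positive")
  if (f_bs_khz == 0) stop("resonance offset must be nonzero")
  t_pulse <- t_pulse_ms * 1e-3
  tt <- seq(0, t_pulse, length.out = n_samples)
  env <- switch(shape,
    constant = rep(1, n_samples),
    gauss = exp(-(tt - t_pulse / 2)^2 / (2 * (sigma_fraction * t_pulse)^2)),
    custom = {
      if (is.null(envelope)) stop("custom shape needs an envelope")
      ev <- as.numeric(envelope)
      tt <- seq(0, t_pulse, length.out = length(ev))
      ev / max(abs(ev))
    })
  # analytic shapes have peak 1 by construction (the Gaussian peaks between
  # samples for even n_samples; the samples are not rescaled, so quadrature
  # follows the true envelope)
  structure(list(b1_norm = env, t = tt, t_pulse = t_pulse,
                 omega_bs = 2 * pi * f_bs_khz * 1e3, gamma = gamma,
                 shape = shape),
            class = "bs_pulse")
}

#' Pulse constant of the Bloch-Siegert phase shift
#'
#' Computes `K_BS = integral_0^T gamma^2 b1_norm(t)^2 / (2 omega_BS(t)) dt`
#' by the composite trapezoid rule on the stored envelope samples. For a
#' constant offset this reduces in closed form to
#' `gamma^2 * integral(b1_norm^2) / (2 omega_BS)`, and K_BS scales inversely
#' with the offset. The magnitude of the offset is used, so both offset
#' signs give the same positive constant.
#'
#' @param pulse A [bs_pulse()] object. `omega_bs` may also be a vector
#'   sampled over the pulse (time-varying offset).
#' @return Pulse constant in rad/G^2.
#' @export
compute_kbs <- function(pulse) {
  stopifnot(inherits(pulse, "bs_pulse"))
  omega <- abs(pulse$omega_bs)
  if (any(omega == 0)) stop("resonance offset crosses zero: K_BS undefined")
  if (length(omega) == 1L) omega <- rep(omega, length(pulse$b1_norm))
  integrand <- pulse$gamma^2 * pulse$b1_norm^2 / (2 * omega)
  dt <- diff(pulse$t)
  sum(dt * (integrand[-1] + integrand[-length(integrand)]) / 2)
}

#' Convert a Bloch-Siegert phase map to a B1 magnitude map
#'
#' Inverts `phi_BS = K_BS * B1^2` pointwise: `B1 = sqrt(phi_BS / K_BS)`.
#' Negative phases (noise in near-zero-B1 voxels) are clipped to zero; the
#' number of clipped voxels is attached as attribute `n_negative` and
#' reported in a warning.
#'
#' @param phi_bs Single-sided Bloch-Siegert phase (rad), any array shape.
#' @param kbs Pulse constant in rad/G^2 (> 0).
#' @param warn Emit a warning when voxels are clipped (default `TRUE`);
#'   callers that report the count themselves pass `FALSE`.
#' @return B1 magnitude in Gauss, same shape as `phi_bs` (multiply by 100
#'   for microtesla).
#' @export
b1_from_phase <- function(phi_bs, kbs, warn = TRUE) {
  if (kbs <= 0) stop("K_BS must be positive")
  neg <- sum(phi_bs < 0)
  if (neg > 0 && warn)
    warning(neg, " voxel(s) with negative Bloch-Siegert phase clipped to 0")
  out <- sqrt(pmax(phi_bs, 0) / kbs)
  attr(out, "n_negative") <- neg
  out
}
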