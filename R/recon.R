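# The user-facing fitting function: two-step variational reconstruction of a
# B1+ map from a paired subsampled Bloch-Siegert acquisition, returning a
# classed object with print/summary/plot/residuals methods.

#' Two-step variational B1+ reconstruction
#'
#' Fits the two-step model to a paired Bloch-Siegert acquisition: after
#' normalization, step 1 recovers the morphology-bearing complex image
#' `u_hat` from the positive-offset data under TGV2 regularization
#' ([solve_step1()]); step 2, holding `u_hat` fixed, recovers the smooth
#' field `v_hat ~ exp(-2i phi_BS)` from the negative-offset data under H1
#' regularization ([solve_step2()]). The B1 map follows from the principal
#' branch of the phase, `B1 = sqrt(-Arg(v_hat) / (2 K_BS))`; a warning is
#' raised when `|Arg(v_hat)|` approaches pi (phase-wrap risk — no
#' unwrapping is attempted) and negative-phase voxels are clipped to 0 and
#' counted.
#'
#' The tuned defaults `lambda = 64` and `mu = 5e-4` assume data scaled by
#' [normalize_data()] (done internally unless `normalize = FALSE`). Using
#' different sampling patterns for the two offsets is supported but
#' discouraged: suppression of subsampling artifacts works best when both
#' acquisitions encode the identical k-space lines, so a note is emitted.
#'
#' @param acq A `bs_acquisition` (measured or from
#'   [simulate_bs_acquisition()]).
#' @param lambda Data weight of the TGV2 step (default 64).
#' @param mu Data weight of the H1 step (default 5e-4).
#' @param coils Coil sensitivities; default the maps stored in the
#'   acquisition, falling back to Walsh estimation from the subsampled
#'   positive-offset data (flagged, since a prescan calibration is the
#'   recommended practice at high acceleration).
#' @param normalize Scale the data by the Hamming-filtered low-resolution
#'   maximum first (default `TRUE`).
#' @param tgv Named list of extra arguments passed to [solve_step1()]
#'   (e.g. `max_iters`, `tol`, `alpha_ratio`).
#' @param h1 Named list of extra arguments passed to [solve_step2()]
#'   (e.g. `cg_tol`, `cg_max_iters`).
#' @return An object of class `bs_recon`: list with `b1_map` (microtesla),
#'   `u_hat`, `v_hat`, `scale`, `lambda`, `mu`, `kbs`, `b1_nom` (Gauss),
#'   `step1` and `step2` solver logs, `n_negative`, `masks`, and the call.
#' @examples
#' \donttest{
#' ph <- make_phantom(grid = c(32, 32, 4), n_coils = 4, seed = 1)
#' acq <- simulate_bs_acquisition(ph, mask_pos = block_pattern(32, 4, 6, 2),
#'                                mask_neg = block_pattern(32, 4, 6, 2),
#'                                ksnr_db = 40, seed = 2)
#' fit <- bs_reconstruct(acq, tgv = list(max_iters = 200))
#' print(fit)
#' }
#' @export
bs_reconstruct <- function(acq, lambda = 64, mu = 5e-4, coils = NULL,
                           normalize = TRUE, tgv = list(), h1 = list()) {
  stopifnot(inherits(acq, "bs_acquisition"))
  coils <- .resolve_coils(acq, coils)
  if (!identical(as.matrix(acq$mask_pos) != 0, as.matrix(acq$mask_neg) != 0))
    message("note: the two offsets use different sampling patterns; ",
            "identical patterns for both acquisitions give the most ",
            "reliable B1 maps")
  scale <- 1
  if (normalize) {
    nm <- normalize_data(acq)
    acq <- nm$acq
    scale <- nm$scale
  }
  s1 <- do.call(solve_step1,
                c(list(k = acq$k_pos, coils = coils, mask = acq$mask_pos,
                       lambda = lambda), tgv))
  s2 <- do.call(solve_step2,
                c(list(k = acq$k_neg, u_hat = s1$u, coils = coils,
                       mask = acq$mask_neg, mu = mu), h1))
  argv <- Arg(s2$v)
  if (any(abs(argv) > 0.95 * pi))
    warning("|Arg(v_hat)| approaches pi in ", sum(abs(argv) > 0.95 * pi),
            " voxel(s): the doubled Bloch-Siegert phase may be wrapping; ",
            "B1 values there are unreliable")
  phi_bs <- -argv / 2
  b1_g <- b1_from_phase(phi_bs, acq$kbs, warn = FALSE)
  structure(list(b1_map = 100 * b1_g, u_hat = s1$u, v_hat = s2$v,
                 scale = scale, lambda = lambda, mu = mu, kbs = acq$kbs,
                 b1_nom = acq$b1_nom, step1 = s1, step2 = s2,
                 n_negative = attr(b1_g, "n_negative"),
                 masks = list(pos = acq$mask_pos, neg = acq$mask_neg),
                 grid = acq$grid, call = match.call()),
            class = "bs_recon")
}

#' @export
print.bs_recon <- function(x, ...) {
  cat("Two-step variational Bloch-Siegert B1+ reconstruction\n")
  cat(sprintf("  grid: %s, acceleration R+ = %.1f, R- = %.1f\n",
              paste(x$grid, collapse = " x "),
              acceleration_factor(x$masks$pos),
              acceleration_factor(x$masks$neg)))
  cat(sprintf("  lambda = %g, mu = %g, K_BS = %g rad/G^2\n",
              x$lambda, x$mu, x$kbs))
  cat(sprintf("  step 1 (TGV2, primal-dual): %d iterations%s\n",
              x$step1$iters,
              if (x$step1$converged) " (converged)" else ""))
  cat(sprintf("  step 2 (H1, CG): %d iterations, rel. residual %.2e\n",
              x$step2$iters, x$step2$resid))
  cat(sprintf("  B1 map range: [%.2f, %.2f] uT (%d negative-phase voxel(s) clipped)\n",
              min(x$b1_map), max(x$b1_map), x$n_negative))
  invisible(x)
}

#' @export
summary.bs_recon <- function(object, ...) {
  b1 <- object$b1_map
  nz <- b1[b1 > 0]
  out <- list(recon = object,
              b1_quartiles = stats::quantile(nz, c(0.25, 0.5, 0.75)),
              b1_nom_ut = 100 * object$b1_nom,
              frac_nonzero = mean(b1 > 0))
  class(out) <- "summary.bs_recon"
  out
}

#' @export
print.summary.bs_recon <- function(x, ...) {
  print(x$recon)
  cat(sprintf("  nominal B1: %.2f uT; nonzero voxels: %.1f%%\n",
              x$b1_nom_ut, 100 * x$frac_nonzero))
  cat("  B1 quartiles over nonzero voxels (uT):\n")
  print(round(x$b1_quartiles, 3))
  invisible(x)
}

#' Plot method for two-step reconstructions
#'
#' Displays the central transverse slice of the reconstructed B1 map (and
#' optionally the morphology magnitude `|u_hat|`) with base graphics.
#'
#' @param x A `bs_recon` object.
#' @param slice Slice index along z (default the central slice).
#' @param what `"b1"`, `"morphology"` or `"both"`.
#' @param ... Passed on to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.bs_recon <- function(x, slice = NULL,
                          what = c("both", "b1", "morphology"), ...) {
  what <- match.arg(what)
  if (is.null(slice)) slice <- floor(x$grid[3] / 2) + 1
  panels <- if (what == "both") 2L else 1L
  op <- graphics::par(mfrow = c(1, panels), mar = c(2, 2, 3, 1))
  on.exit(graphics::par(op))
  gray <- grDevices::gray.colors(128, start = 0, end = 1)
  if (what %in% c("both", "morphology"))
    graphics::image(Mod(x$u_hat[, , slice]), col = gray, asp = 1,
                    axes = FALSE, main = sprintf("|u| (slice %d)", slice), ...)
  if (what %in% c("both", "b1"))
    graphics::image(x$b1_map[, , slice], col = grDevices::hcl.colors(128),
                    asp = 1, axes = FALSE,
                    main = sprintf("B1+ map, uT (slice %d)", slice), ...)
  invisible(x)
}

#' k-space residuals of a two-step reconstruction
#'
#' Returns the data-consistency residuals of either step on the normalized
#' scale: `A u_hat - k_pos` for step 1, `K v_hat - k_neg` for step 2.
#' Residuals are computed against the acquisition that was fitted, so the
#' acquisition must be passed again (the fit does not retain the raw data).
#'
#' @param object A `bs_recon` object.
#' @param acq The acquisition that was fitted.
#' @param step 1 or 2.
#' @param coils Sensitivities used at fit time (defaults to those in `acq`).
#' @param ... Unused.
#' @return Complex k-space residual array (Nx, Ny, Nz, Nc).
#' @export
residuals.bs_recon <- function(object, acq, step = 1, coils = NULL, ...) {
  stopifnot(inherits(acq, "bs_acquisition"))
  coils <- .resolve_coils(acq, coils)
  kp <- acq$k_pos / object$scale
  kn <- acq$k_neg / object$scale
  if (step == 1)
    forward_op(object$u_hat, coils, acq$mask_pos) - kp
  else
    step2_op(object$v_hat, object$u_hat, coils, acq$mask_neg) - kn
}

#' Export a B1 map to NIfTI
#'
#' Writes the reconstructed B1 map (microtesla) to a NIfTI file via RNifti,
#' carrying the voxel size if supplied.
#'
#' @param x A `bs_recon` object or a 3D numeric B1 map.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Optional numeric length-3 voxel size.
#' @return The path, invisibly.
#' @export
write_b1_nifti <- function(x, path, voxel_size_mm = NULL) {
  b1 <- if (inherits(x, "bs_recon")) x$b1_map else x
  img <- RNifti::asNifti(b1)
  if (!is.null(voxel_size_mm))
    RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
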